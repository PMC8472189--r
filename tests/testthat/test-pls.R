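test_that("a noise-free linear response is recovered almost exactly", {
  set.seed(101)
  X <- matrix(rnorm(30 * 10), 30)
  y <- drop(X %*% c(1, -2, 3, rep(0, 7)))
  m <- fit_pls(X, y, max_components = 5, min_sd = 0)
  expect_gte(m$q2, 0.99)
  expect_gte(m$r2, 0.999)
  # at full rank the noise-free fit is exact: training rows reproduce y
  X5 <- X[, 1:3]
  y5 <- drop(X5 %*% c(1, -2, 3))
  m5 <- fit_pls(X5, y5, max_components = 3, min_sd = 0)
  expect_identical(m5$n_components, 3L)
  expect_lt(max(abs(predict(m5, X5) - y5)), 1e-6)
})

test_that("at full rank the PLS solution equals ordinary least squares", {
  set.seed(102)
  X <- matrix(rnorm(30 * 5), 30)
  y <- drop(X %*% rnorm(5)) + rnorm(30, sd = 0.3)
  core <- pcbtrans:::pls_core(scale(X, scale = FALSE), y - mean(y), 5)
  pred_pls <- mean(y) + drop(scale(X, scale = FALSE) %*% core$B[, 5])
  expect_lt(max(abs(pred_pls - fitted(lm(y ~ X)))), 1e-8)
})

test_that("leave-one-out q2 equals an independent naive refit oracle", {
  set.seed(103)
  X <- matrix(rnorm(20 * 50), 20)
  y <- drop(X[, 1:5] %*% rnorm(5)) + rnorm(20)
  for (nc in c(1, 3, 5))
    expect_lt(abs(loo_q2(X, y, nc, min_sd = 0) - naive_loo_q2(X, y, nc)), 1e-10)
})

test_that("q2 is centering-invariant and collapses under permutation", {
  set.seed(104)
  X <- matrix(rnorm(25 * 40), 25)
  y <- drop(X[, 1:4] %*% rnorm(4)) + rnorm(25, sd = 0.5)
  expect_equal(loo_q2(X, y, 3, min_sd = 0), loo_q2(X, y + 100, 3, min_sd = 0),
               tolerance = 1e-10)
  q2s <- replicate(20, fit_pls(X, sample(y), max_components = 5, min_sd = 0)$q2)
  expect_lt(median(q2s), 0.2)
})

test_that("a pure-noise response has non-positive expected q2", {
  set.seed(105)
  q2s <- replicate(100, {
    X <- matrix(rnorm(15 * 10), 15)
    loo_q2(X, 3 + rnorm(15), 2, min_sd = 0)
  })
  expect_lt(mean(q2s), 0)
})

test_that("q2 never exceeds r2 on fitted models", {
  set.seed(106)
  for (rep in 1:5) {
    X <- matrix(rnorm(25 * 30), 25)
    y <- drop(X[, 1:3] %*% rnorm(3)) + rnorm(25, sd = 0.7)
    m <- fit_pls(X, y, max_components = 6, min_sd = 0)
    expect_lte(m$q2, m$r2)
  }
})

test_that("the F statistic reproduces both reported model checks", {
  expect_lt(abs(f_statistic(0.90, 38, 7) - 38.578), 0.05)
  expect_lt(abs(f_statistic(0.914, 60, 8) - 67.952), 0.3)
  # monotone increase toward a perfect fit
  r2s <- seq(0.5, 0.999, by = 0.01)
  expect_true(all(diff(f_statistic(r2s, 60, 8)) > 0))
  expect_error(f_statistic(0.9, 8, 7), "degrees of freedom")
})

test_that("model_stats agrees with the stored training statistics", {
  set.seed(107)
  X <- matrix(rnorm(30 * 20), 30)
  y <- drop(X[, 1:4] %*% rnorm(4)) + rnorm(30, sd = 0.5)
  m <- fit_pls(X, y, max_components = 5, min_sd = 0)
  s <- model_stats(m, X, y)
  expect_equal(s$r2, m$r2, tolerance = 1e-12)
  expect_equal(s$see, m$see, tolerance = 1e-12)
  expect_equal(s$f_stat, m$f_stat, tolerance = 1e-12)
})

test_that("prediction is centered and batch-consistent", {
  set.seed(108)
  X <- matrix(rnorm(25 * 15), 25)
  y <- drop(X[, 1:3] %*% rnorm(3)) + rnorm(25, sd = 0.4)
  m <- fit_pls(X, y, max_components = 4, min_sd = 0)
  expect_equal(unname(predict(m, colMeans(X))), mean(y), tolerance = 1e-10)
  batch <- predict(m, X)
  single <- vapply(seq_len(nrow(X)), function(i) predict(m, X[i, ]), numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
  expect_error(predict(m, X[, 1:3]), "columns")
})

test_that("degenerate responses are rejected", {
  X <- matrix(rnorm(20 * 5), 20)
  expect_error(fit_pls(X, rep(1, 20)), "degenerate")
})
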