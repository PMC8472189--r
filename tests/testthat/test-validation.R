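test_that("the two relative-error conventions match their source tables", {
  expect_equal(round(relative_error(75.426, 80.325, "obs_minus_est_over_obs"), 2), -6.50)
  expect_equal(round(relative_error(66.793, 55.05, "est_minus_ref_over_ref"), 2), -17.58)
  expect_identical(relative_error(3, 3, "est_minus_ref_over_ref"), 0)
  expect_error(relative_error(0, 1, "est_minus_ref_over_ref"), "reference")
})

test_that("every printed relative-error cell reproduces under its convention", {
  t2 <- load_fixture("table2")
  for (blk in list(c("phyto_obs", "phyto_est", "phyto_rel_err"),
                   c("estro_obs", "estro_est", "estro_rel_err"))) {
    i <- !is.na(t2[[blk[1]]])
    re <- relative_error(t2[[blk[1]]][i], t2[[blk[2]]][i], "obs_minus_est_over_obs")
    expect_lt(max(abs(re - t2[[blk[3]]][i])), 0.01)
  }
  t4 <- load_fixture("table4")
  for (blk in list(c("phyto_total", "phyto_est", "phyto_rel_err"),
                   c("estro_total", "estro_est", "estro_rel_err"))) {
    re <- relative_error(t4[[blk[1]]], t4[[blk[2]]], "est_minus_ref_over_ref")
    expect_lt(max(abs(re - t4[[blk[3]]])), 0.01)
  }
})

test_that("pearson_r matches a two-pass oracle and is affine-invariant", {
  set.seed(201)
  for (rep in 1:10) {
    x <- rnorm(20); y <- rnorm(20)
    expect_equal(pearson_r(x, y), twopass_r(x, y), tolerance = 1e-12)
    expect_equal(pearson_r(2 * x + 3, y), pearson_r(x, y), tolerance = 1e-12)
    expect_equal(pearson_r(x, -4 * y + 1), -pearson_r(x, y), tolerance = 1e-12)
  }
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "variance")
})

test_that("fit_line returns the OLS line with R = |r|", {
  set.seed(202)
  x <- rnorm(30); y <- -2 * x + rnorm(30)
  fl <- fit_line(x, y)
  expect_equal(fl$R, abs(pearson_r(x, y)), tolerance = 1e-12)
  expect_equal(fl$slope, unname(coef(lm(y ~ x))[2]), tolerance = 1e-12)
  exact <- fit_line(1:10, 3 * (1:10) - 2)
  expect_equal(exact$R, 1, tolerance = 1e-12)
  expect_equal(exact$slope, 3, tolerance = 1e-10)
})

test_that("threshold counting handles edge cases", {
  expect_identical(count_over(c(-12, 3, 11, 9.99), 10), list(count = 2L, fraction = 0.5))
  expect_identical(count_over(numeric(0), 10), list(count = 0L, fraction = 0))
  expect_error(count_over(1:3, 0))
})

test_that("critical r follows the t-quantile closed form", {
  r0 <- critical_r(0.05, 33)
  expect_equal(r0$r0, 0.344, tolerance = 0.001)
  expect_identical(r0$df, 31L)
  expect_lt(critical_r(0.9999, 33)$r0, 0.001)
  r3 <- critical_r(0.05, 3)
  expect_true(r3$r0 > 0 && r3$r0 < 1 && r3$df == 1L)
  expect_error(critical_r(1.5, 10), "alpha")
})

test_that("validation_report assembles the pieces coherently", {
  t4 <- load_fixture("table4")
  rep <- validation_report(t4$estro_total, t4$estro_est, labels = t4$molecule)
  expect_equal(rep$r, 0.547, tolerance = 0.005)
  expect_identical(rep$n_over_threshold, 11L)
  expect_equal(rep$fraction_over_threshold, 1 / 3, tolerance = 0.01)
  expect_equal(rep$fit_R, abs(rep$r), tolerance = 1e-12)
  expect_output(print(rep), "validation of 33 pairs")
})
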