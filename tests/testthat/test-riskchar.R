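test_that("change rates match printed chain-table cells", {
  expect_equal(round(change_rate(67.203, 90.708), 2), 34.98)
  expect_equal(round(change_rate(0.989, -0.831), 2), -184.02)
  expect_identical(change_rate(5, 5), 0)
  expect_error(change_rate(0, 1), "parent")
})

test_that("change_rate is direction-sensitive, not antisymmetric", {
  expect_false(isTRUE(all.equal(change_rate(2, 1), -change_rate(1, 2))))
})

test_that("improvement uses the inverse convention for migration", {
  expect_equal(round(improvement(69.928, 56.281, "estrogen_toxicity"), 2), 19.52)
  expect_equal(round(improvement(7.964, 10.965, "migration"), 2), 37.68)
  expect_identical(improvement(3, 3, "persistence"), 0)
  expect_error(improvement(0, 1, "migration"), "parent")
  expect_error(improvement(1, 2, "toxicity_of_unknown"), "arg")
})

test_that("risk direction inverts for migration only", {
  expect_identical(risk_direction("migration", 18.42), "risk_decreased")
  expect_identical(risk_direction("migration", -61.55), "risk_increased")
  expect_identical(risk_direction("phytotoxicity", 34.98), "risk_increased")
  expect_identical(risk_direction("persistence", 0), "unchanged")
  expect_error(risk_direction("odour", 1), "arg")
})

test_that("chain evaluation reproduces printed chain records", {
  rec <- chain_evaluate("PCB-52", paste0("52-", 1:4))
  expect_identical(nrow(rec), 20L)
  expect_equal(rec$change_pct[rec$molecule == "52-3" & rec$endpoint == "persistence"],
               11.43, tolerance = 0.005)
  p2 <- chain_evaluate("P2", paste0("P2-", 1:4))
  expect_equal(p2$change_pct[p2$molecule == "P2-4" & p2$endpoint == "migration"],
               117.32, tolerance = 0.005)
  expect_identical(nrow(chain_evaluate("PCB-52", character(0))), 0L)
  expect_error(chain_evaluate("PCB-52", "52-99"), "52-99")
})

test_that("summaries bound their member records", {
  chains <- fixture_chains()
  rec <- do.call(rbind, lapply(chains, function(ch) chain_evaluate(ch$parent, ch$chain)))
  s <- summarize_changes(rec)
  for (i in seq_len(nrow(s))) {
    v <- rec$change_pct[rec$endpoint == s$endpoint[i]]
    expect_true(all(v >= s$min_pct[i] & v <= s$max_pct[i]))
    expect_true(s$min_pct[i] %in% v && s$max_pct[i] %in% v)
  }
  one <- summarize_changes(rec[1, ])
  expect_identical(one$min_pct, one$max_pct)
  expect_warning(s0 <- summarize_changes(rec[0, ]), "empty")
  expect_identical(nrow(s0), 0L)
})

test_that("heat binning uses ten equal-width levels with the max on top", {
  expect_identical(heat_levels(42), 10L)
  expect_identical(heat_levels(seq(10, 100, by = 10)), c(1:9, 10L))
  expect_identical(heat_levels(c(0, 0, 0)), c(1L, 1L, 1L))
  # pathway ranges: a 421.71 % cell against cells below 62 % pins level 10
  scores <- c(plant = 421.71, aerobic = 37.71, anaerobic = 32.53,
              biometab = 42.10, photo = 60.70)
  lv <- heat_levels(scores)
  expect_identical(unname(lv["plant"]), 10L)
  expect_true(all(lv[-1] <= 2L))
  m <- matrix(c(10, 421.71, 5, 62), 2)
  expect_identical(dim(heat_levels(m)), dim(m))
})
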