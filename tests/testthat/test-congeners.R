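test_that("canonicalization is idempotent and constant on each symmetry orbit", {
  reps <- character(0)
  for (a in all_patterns) for (b in all_patterns) {
    k <- canonicalize_rings(a, b)
    # idempotent
    k2 <- canonicalize_rings(k$ring_a, k$ring_b)
    expect_identical(k, k2)
    # constant on the brute-force orbit
    expect_identical(pair_key(k$ring_a, k$ring_b), orbit_rep(a, b))
    reps <- c(reps, pair_key(k$ring_a, k$ring_b))
  }
  expect_identical(length(unique(reps)), 210L)
})

test_that("orbit examples collapse as expected", {
  expect_identical(canonicalize_rings(c(4, 5), c(2, 5)),
                   canonicalize_rings(c(3, 4), c(2, 5)))
  expect_identical(canonicalize_rings(integer(0), integer(0)),
                   list(ring_a = integer(0), ring_b = integer(0)))
  expect_identical(canonicalize_rings(2, 2), canonicalize_rings(6, 6))
  expect_identical(canonicalize_rings(2, 2)$ring_a, 2L)
})

test_that("invalid ring positions are rejected", {
  expect_error(ring_pattern(c(1, 4)), "2")
  expect_error(canonicalize_rings(7, 2), "2")
  expect_error(congener_patterns(210), "0..209")
  expect_error(congener_patterns(-1), "0..209")
})

test_that("numbering round-trips over all 210 congeners", {
  for (n in 0:209) {
    p <- congener_patterns(n)
    expect_identical(congener_number(p$ring_a, p$ring_b), n)
  }
})

test_that("numbering matches reference assignments", {
  expect_identical(congener_number(c(2, 5), c(2, 5)), 52L)
  expect_identical(congener_number(integer(0), integer(0)), 0L)
  expect_identical(congener_number(2:6, 2:6), 209L)
  expect_identical(congener_patterns(15), list(ring_a = 4L, ring_b = 4L))
  tab <- congener_table()
  anchors <- c(`1` = "2", `28` = "2,4,4'", `33` = "2',3,4", `49` = "2,2',4,5'",
               `77` = "3,3',4,4'", `97` = "2,2',3',4,5", `101` = "2,2',4,5,5'",
               `107` = "2,3,3',4',5", `108` = "2,3,3',4,5'", `109` = "2,3,3',4,6",
               `118` = "2,3',4,4',5", `126` = "3,3',4,4',5", `138` = "2,2',3,4,4',5'",
               `153` = "2,2',4,4',5,5'", `169` = "3,3',4,4',5,5'",
               `180` = "2,2',3,4,4',5,5'", `189` = "2,3,3',4,4',5,5'",
               `194` = "2,2',3,3',4,4',5,5'", `199` = "2,2',3,3',4,5,5',6'",
               `209` = "2,2',3,3',4,4',5,5',6,6'")
  expect_identical(tab$name[match(as.integer(names(anchors)), tab$number)],
                   unname(anchors))
})

test_that("the shipped numbering table equals its first-principles derivation", {
  shipped <- congener_table()
  derived <- derive_bz_numbering()
  rownames(shipped) <- rownames(derived) <- NULL
  expect_identical(shipped, derived)
  expect_identical(shipped$n_cl,
                   nchar(shipped$ring_a) + nchar(shipped$ring_b))
})

test_that("congener constructor accepts numbers, patterns and labels", {
  x <- congener(52)
  expect_s3_class(x, "congener")
  expect_identical(x$n_cl, 4L)
  expect_identical(congener("25", "25")$number, 52L)
  expect_identical(pcbtrans:::as_congener("PCB-153")$number, 153L)
  expect_error(pcbtrans:::as_congener("CB-153"), "congener")
})
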