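# Independent oracles, written without reuse of the package internals.

# all eight symmetry images of a pattern pair, by explicit position maps
orbit_images <- function(a, b) {
  refl <- function(p) sort(c(`2` = 6L, `3` = 5L, `4` = 4L, `5` = 3L, `6` = 2L)[as.character(p)])
  imgs <- list()
  for (fa in list(identity, refl)) for (fb in list(identity, refl)) {
    ia <- unname(fa(a)); ib <- unname(fb(b))
    imgs <- c(imgs, list(list(ia, ib), list(ib, ia)))
  }
  imgs
}

pair_key <- function(a, b) paste(paste(a, collapse = ""), paste(b, collapse = ""), sep = "|")

# brute-force orbit representative: smallest pair key over all images;
# a space separator sorts below every digit, so string order on the joined
# key equals element-wise order on the locant sequence pair
orbit_rep <- function(a, b) {
  keys <- vapply(orbit_images(a, b), function(im) {
    k1 <- paste(im[[1]], collapse = ""); k2 <- paste(im[[2]], collapse = "")
    paste(sort(c(k1, k2)), collapse = " ")
  }, character(1))
  sub(" ", "|", min(keys), fixed = TRUE)
}

all_patterns <- lapply(0:31, function(m) (2:6)[bitwAnd(m, 2L^(0:4)) > 0L])

# naive leave-one-out PLS oracle built on mixOmics (independent NIPALS)
naive_loo_q2 <- function(X, y, ncomp) {
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  press <- 0
  for (i in seq_along(y)) {
    f <- mixOmics::pls(X[-i, , drop = FALSE], y[-i], ncomp = ncomp,
                       scale = FALSE, mode = "regression")
    p <- predict(f, X[i, , drop = FALSE])$predict[1, 1, ncomp]
    press <- press + (y[i] - p)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# two-pass product-moment correlation
twopass_r <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

count_cl <- function(smiles) lengths(regmatches(smiles, gregexpr("Cl", smiles)))
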