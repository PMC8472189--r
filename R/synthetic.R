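# Synthetic inputs with the statistical structure the field-QSAR analysis
# assumes: a descriptor matrix whose informative directions are spread over
# blocks of neighboring columns (mimicking smooth grid fields), a linear
# latent activity, and i.i.d. Gaussian noise; plus random congener samples
# for rule-engine property tests.

#' Generate a synthetic field-QSAR dataset
#'
#' Latent scores for \code{n_informative} directions are drawn i.i.d.
#' standard normal; each direction loads onto a block of neighboring
#' descriptor columns with a smooth (Gaussian bump) profile, and a small
#' idiosyncratic column noise is added, so the descriptor matrix has the
#' correlated-block character of grid interaction fields. The activity is
#' \code{y = X beta_true + eps}, \code{eps ~ N(0, sigma^2)} i.i.d. When
#' \code{sigma} is \code{NULL} it is set from \code{target_r2} so the
#' generative signal-to-total variance ratio equals the target.
#'
#' @param n_molecules,n_descriptors matrix size (defaults 60 x 120, the
#'   training-set scale of the toxicity models).
#' @param n_informative number of informative latent directions.
#' @param sigma activity noise standard deviation, or \code{NULL} to derive
#'   it from \code{target_r2}.
#' @param target_r2 generative R2 used when \code{sigma} is \code{NULL}
#'   (default 0.9, the fit quality the toxicity models report).
#' @param seed integer seed; the result is reproducible from it.
#' @return list with \code{X}, \code{y}, \code{beta_true}, \code{sigma},
#'   \code{generative_r2} (realized in-sample), \code{seed}.
#' @export
gen_qsar <- function(n_molecules = 60L, n_descriptors = 120L, n_informative = 4L,
                     sigma = NULL, target_r2 = 0.9, seed = 1L) {
  if (n_informative > n_descriptors) stop("n_informative > n_descriptors", call. = FALSE)
  if (!is.null(sigma) && sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  stopifnot(n_molecules >= 4L, n_descriptors >= 1L, n_informative >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  scores <- matrix(stats::rnorm(n_molecules * n_informative), n_molecules)
  centers <- seq(1, n_descriptors, length.out = n_informative + 2L)[-c(1L, n_informative + 2L)]
  width <- max(2, n_descriptors / (4 * n_informative))
  L <- t(vapply(seq_len(n_informative), function(k)
    exp(-((seq_len(n_descriptors) - centers[k])^2) / (2 * width^2)),
    numeric(n_descriptors)))
  X <- scores %*% L + 0.05 * matrix(stats::rnorm(n_molecules * n_descriptors), n_molecules)
  beta_true <- colSums(L * stats::rnorm(n_informative, sd = 1))
  signal <- drop(X %*% beta_true)
  if (is.null(sigma)) {
    sv <- stats::sd(signal)
    sigma <- sv * sqrt((1 - target_r2) / target_r2)
  }
  eps <- stats::rnorm(n_molecules, sd = sigma)
  y <- signal + eps
  vs <- stats::var(signal)
  list(X = X, y = y, beta_true = beta_true, sigma = sigma,
       generative_r2 = vs / (vs + sigma^2), seed = seed)
}

#' Sample congeners uniformly without replacement
#'
#' @param n number of congeners, 1..210.
#' @param seed integer seed.
#' @return list of \code{congener} objects.
#' @export
gen_congeners <- function(n, seed = 1L) {
  if (n < 1L || n > 210L) stop("n must lie in 1..210", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nums <- sample(0:209, n)
  lapply(nums, congener)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
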