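# Validation arithmetic: relative errors under the two printed-table
# conventions, Pearson correlation, linear-fit R, threshold counting, and
# the critical correlation value.

#' Relative error between a reference and an estimate
#'
#' Two conventions are in use in the packaged tables and must be named
#' explicitly: the congener estimate table reports
#' \code{100 * (obs - est) / obs} while the metabolite validation table
#' reports \code{100 * (est - ref) / ref}. The convention is a required
#' argument and is never inferred from the data.
#'
#' @param reference observed/reference values (nonzero).
#' @param estimate estimated values.
#' @param convention \code{"obs_minus_est_over_obs"} or
#'   \code{"est_minus_ref_over_ref"}.
#' @return relative errors in percent.
#' @examples
#' relative_error(75.426, 80.325, "obs_minus_est_over_obs") # -6.50
#' @export
relative_error <- function(reference, estimate,
                           convention = c("obs_minus_est_over_obs",
                                          "est_minus_ref_over_ref")) {
  convention <- match.arg(convention)
  if (any(reference == 0)) stop("relative error undefined for reference 0", call. = FALSE)
  if (convention == "obs_minus_est_over_obs") 100 * (reference - estimate) / reference
  else 100 * (estimate - reference) / reference
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation coefficient r.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input", call. = FALSE)
  stats::cor(x, y)
}

#' Ordinary least-squares line and its fit R
#'
#' @inheritParams pearson_r
#' @return list with \code{slope}, \code{intercept}, \code{R}
#'   (\code{R = |r|}).
#' @export
fit_line <- function(x, y) {
  r <- pearson_r(x, y)
  co <- stats::coef(stats::lm(y ~ x))
  list(slope = unname(co[2]), intercept = unname(co[1]), R = abs(r))
}

#' Count relative errors beyond a threshold
#'
#' @param errors relative errors in percent.
#' @param threshold_pct positive threshold.
#' @return list with \code{count} of \code{|error| > threshold} and its
#'   \code{fraction} of the total (0 for an empty vector).
#' @export
count_over <- function(errors, threshold_pct) {
  stopifnot(threshold_pct > 0)
  n <- length(errors)
  cnt <- sum(abs(errors) > threshold_pct)
  list(count = cnt, fraction = if (n == 0L) 0 else cnt / n)
}

#' Critical value of the correlation coefficient
#'
#' \code{r0 = t / sqrt(t^2 + df)} with \code{df = n - 2} and \code{t} the
#' Student quantile for the stated alpha and tails. Published r0 lookup
#' tables sometimes use other df conventions; the convention used is
#' recorded in the result.
#'
#' @param alpha significance level in (0, 1).
#' @param n sample size (>= 3).
#' @param tails 1 or 2.
#' @return list with \code{r0}, \code{df}, \code{convention}.
#' @examples
#' critical_r(0.05, 33)$r0 # about 0.344
#' @export
critical_r <- function(alpha, n, tails = 2L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  stopifnot(n >= 3L, tails %in% c(1L, 2L))
  df <- as.integer(n) - 2L
  tcrit <- stats::qt(1 - alpha / tails, df)
  list(r0 = tcrit / sqrt(tcrit^2 + df), df = df,
       convention = sprintf("t-quantile, df = n - 2, %d-tailed", tails))
}

#' Validation report for a paired reference/estimate series
#'
#' @param reference,estimate paired numeric vectors.
#' @param labels optional molecule labels.
#' @param convention relative-error convention, see [relative_error()].
#' @param threshold_pct threshold for [count_over()].
#' @param alpha,tails critical-r parameters.
#' @return list of class \code{validation_report}: r, fit R, relative
#'   errors, count over threshold, critical r0.
#' @export
validation_report <- function(reference, estimate, labels = NULL,
                              convention = "est_minus_ref_over_ref",
                              threshold_pct = 10, alpha = 0.001, tails = 2L) {
  stopifnot(length(reference) == length(estimate))
  fl <- fit_line(reference, estimate)
  re <- relative_error(reference, estimate, convention)
  ov <- count_over(re, threshold_pct)
  structure(list(
    n = length(reference), labels = labels,
    r = pearson_r(reference, estimate), fit_R = fl$R,
    slope = fl$slope, intercept = fl$intercept,
    relative_errors = re, convention = convention,
    threshold_pct = threshold_pct, n_over_threshold = ov$count,
    fraction_over_threshold = ov$fraction,
    r0 = critical_r(alpha, length(reference), tails)$r0, alpha = alpha
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation of %d pairs: r = %.3f (critical r0 = %.3f at alpha = %g)\n",
              x$n, x$r, x$r0, x$alpha))
  cat(sprintf("fit R = %.3f; |relative error| > %g%%: %d/%d\n",
              x$fit_R, x$threshold_pct, x$n_over_threshold, x$n))
  invisible(x)
}
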