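# Partial least squares (NIPALS PLS1) with leave-one-out validation, as used
# for field-descriptor QSAR: mean-centered by default (no autoscaling),
# near-constant columns dropped before fitting, number of latent variables
# chosen by maximum leave-one-out q2.

pls_core <- function(X, y, ncomp) {
  # NIPALS PLS1 on already centered/filtered data; returns coefficient
  # matrix B (p x ncomp): column a = regression vector using a components
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  Xa <- X; ya <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) { ncomp <- a - 1L; break }
    w <- w / nw
    t <- Xa %*% w
    tt <- sum(t^2)
    pl <- crossprod(Xa, t) / tt
    q <- sum(ya * t) / tt
    Xa <- Xa - tcrossprod(t, pl)
    ya <- ya - q * t
    W[, a] <- w; P[, a] <- pl; Q[a] <- q
  }
  if (ncomp == 0L) stop("degenerate response: no usable component", call. = FALSE)
  B <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    B[, a] <- Wa %*% solve(crossprod(Pa, Wa), Q[seq_len(a)])
  }
  list(B = B, W = W[, seq_len(ncomp), drop = FALSE],
       P = P[, seq_len(ncomp), drop = FALSE], Q = Q[seq_len(ncomp)], ncomp = ncomp)
}

prepare_xy <- function(X, y, min_sd, center, scale) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) stop("degenerate response: zero variance", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  keep <- which(sds > min_sd)
  if (length(keep) == 0L) stop("all descriptor columns near-constant", call. = FALSE)
  X <- X[, keep, drop = FALSE]
  x_mean <- if (center) colMeans(X) else rep(0, ncol(X))
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  y_mean <- if (center) mean(y) else 0
  list(X = sweep(sweep(X, 2, x_mean), 2, x_scale, "/"), y = y - y_mean,
       keep = keep, x_mean = x_mean, x_scale = x_scale, y_mean = y_mean)
}

# PRESS per component count from one leave-one-out pass
loo_press <- function(Xc, yc, max_comp) {
  n <- nrow(Xc)
  press <- numeric(max_comp)
  nc_min <- max_comp
  for (i in seq_len(n)) {
    fit <- pls_core(Xc[-i, , drop = FALSE] |> sweep(2, colMeans(Xc[-i, , drop = FALSE])),
                    yc[-i] - mean(yc[-i]), max_comp)
    nc_min <- min(nc_min, fit$ncomp)
    xi <- Xc[i, ] - colMeans(Xc[-i, , drop = FALSE])
    pred <- mean(yc[-i]) + drop(xi %*% fit$B)
    if (fit$ncomp < max_comp) pred <- c(pred, rep(pred[fit$ncomp], max_comp - fit$ncomp))
    press <- press + (yc[i] - pred)^2
  }
  list(press = press, ncomp_reached = nc_min)
}

#' Fit a PLS1 regression with leave-one-out model selection
#'
#' NIPALS PLS1 on mean-centered data. The number of latent variables is the
#' one maximizing leave-one-out q2 over 1..\code{max_components} (ties go to
#' the smaller model); r2, SEE and F are stored at that size.
#'
#' @param X descriptor matrix (rows = molecules).
#' @param y activity vector.
#' @param max_components largest model size tried (default 10).
#' @param min_sd columns with standard deviation at or below this are
#'   dropped before fitting (default 0.05, the usual field-value cutoff in
#'   kcal/mol).
#' @param center,scale mean-centering (default on) and unit-variance
#'   scaling (default off, the standard field-QSAR choice).
#' @return object of class \code{pls_model} with coefficients, kept
#'   columns, centering info, and statistics \code{n_components}, \code{q2},
#'   \code{r2}, \code{see}, \code{f_stat}, \code{press}, \code{q2_by_ncomp}.
#' @export
fit_pls <- function(X, y, max_components = 10L, min_sd = 0.05,
                    center = TRUE, scale = FALSE) {
  pr <- prepare_xy(X, y, min_sd, center, scale)
  n <- nrow(pr$X)
  max_components <- as.integer(min(max_components, n - 2L, ncol(pr$X)))
  stopifnot(max_components >= 1L)
  ss <- sum((pr$y - mean(pr$y))^2)
  lp <- loo_press(pr$X, pr$y, max_components)
  q2s <- 1 - lp$press / ss
  nc <- which.max(q2s)
  fit <- pls_core(pr$X, pr$y, nc)
  beta <- fit$B[, fit$ncomp]
  resid <- pr$y - drop(pr$X %*% beta)
  rss <- sum(resid^2)
  r2 <- 1 - rss / ss
  model <- structure(list(
    n_components = fit$ncomp, coefficients = beta,
    keep = pr$keep, x_mean = pr$x_mean, x_scale = pr$x_scale, y_mean = pr$y_mean,
    weights = fit$W, loadings = fit$P, y_loadings = fit$Q,
    n_train = n, q2 = q2s[nc], q2_by_ncomp = q2s, press = lp$press,
    r2 = r2, see = sqrt(rss / (n - fit$ncomp - 1)),
    f_stat = f_statistic(r2, n, fit$ncomp),
    center = center, scale = scale, min_sd = min_sd
  ), class = "pls_model")
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: n = %d, %d components, q2 = %.3f, r2 = %.3f, SEE = %.3f, F = %.3f\n",
              x$n_train, x$n_components, x$q2, x$r2, x$see, x$f_stat))
  invisible(x)
}

#' Leave-one-out cross-validated q2
#'
#' \code{q2 = 1 - PRESS / SS} with \code{PRESS = sum((y_i - yhat_(-i))^2)}
#' and \code{SS} the centered sum of squares of the full response. Each
#' held-out prediction comes from a model refitted on the remaining n - 1
#' samples.
#'
#' @inheritParams fit_pls
#' @param n_components model size used for every fold.
#' @return q2 (at most 1; negative when the model predicts worse than the
#'   mean).
#' @export
loo_q2 <- function(X, y, n_components, min_sd = 0.05, center = TRUE, scale = FALSE) {
  pr <- prepare_xy(X, y, min_sd, center, scale)
  ss <- sum((pr$y - mean(pr$y))^2)
  lp <- loo_press(pr$X, pr$y, as.integer(n_components))
  1 - lp$press[n_components] / ss
}

#' Regression F statistic from r2 and model size
#'
#' \code{F = (r2 / c) / ((1 - r2) / (N - c - 1))} for a model with
#' \code{c} components fitted to \code{N} training samples.
#'
#' @param r2 squared correlation of fitted vs observed.
#' @param n training-set size N.
#' @param ncomp number of components c.
#' @return F value.
#' @examples
#' f_statistic(0.914, 60, 8) # about 67.8
#' @export
f_statistic <- function(r2, n, ncomp) {
  if (n <= ncomp + 1) stop("no residual degrees of freedom", call. = FALSE)
  (r2 / ncomp) / ((1 - r2) / (n - ncomp - 1))
}

#' Model statistics on a dataset
#'
#' @param model fitted \code{pls_model}.
#' @param X,y data to evaluate on (typically the training data).
#' @return list with \code{r2}, \code{see}, \code{f_stat}.
#' @export
model_stats <- function(model, X, y) {
  pred <- predict(model, X)
  rss <- sum((y - pred)^2)
  ss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / ss
  n <- length(y); c <- model$n_components
  if (n <= c + 1) stop("no residual degrees of freedom", call. = FALSE)
  list(r2 = r2, see = sqrt(rss / (n - c - 1)), f_stat = f_statistic(r2, n, c))
}

#' Predict activities from a fitted PLS model
#'
#' @param object fitted \code{pls_model}.
#' @param newdata descriptor matrix with the columns the model was trained
#'   on (before column filtering).
#' @param ... unused.
#' @return predicted activities.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) == length(object$keep)) {
    # already filtered
  } else if (ncol(X) >= max(object$keep)) {
    X <- X[, object$keep, drop = FALSE]
  } else stop("descriptor columns do not match the fitted model", call. = FALSE)
  Xc <- sweep(sweep(X, 2, object$x_mean), 2, object$x_scale, "/")
  drop(object$y_mean + Xc %*% object$coefficients)
}
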