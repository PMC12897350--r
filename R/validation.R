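#' Calibration statistics of a fitted model
#'
#' \code{sd_error = sqrt(SS_res / (n - p - 1))}, \code{mae = mean(|y - y_fit|)}
#' and \code{r = cor(y, y_fit)}. A degenerate constant fit (zero-variance
#' fitted values) reports \code{r = 0} with the \code{r_degenerate} flag set
#' rather than failing, so pathological synthetic configurations do not abort
#' a pipeline run.
#'
#' @param y observed responses
#' @param y_fit fitted values
#' @param p number of predictors (excluding the intercept)
#' @return a \linkS4class{ModelStats} with the LOO fields unset
#' @export
calibrationStats <- function(y, y_fit, p) {
  n <- length(y)
  if (length(y_fit) != n) stop("'y' and 'y_fit' must have equal length")
  if (n <= p + 1L)
    stop(sprintf("need n > p + 1 (n = %d, p = %d)", n, p))
  res <- y - y_fit
  degenerate <- sd(y_fit) < 1e-12 * (abs(mean(y_fit)) + 1) || sd(y) == 0
  r <- if (degenerate) 0 else abs(cor(y, y_fit))
  new("ModelStats",
      sd_error = sqrt(sum(res^2) / (n - p - 1)),
      mae = mean(abs(res)), r = r,
      n = as.integer(n), p = as.integer(p), r_degenerate = degenerate)
}

loo_fold_refit <- function(X, y, idx, i) {
  # literal leave-one-out fold: refit autoscaling and OLS on the n-1 rows
  Xtr <- X[-i, idx, drop = FALSE]
  sc <- fitAutoscale(Xtr)
  keep <- !sc@flagged
  if (!any(keep))
    stop(sprintf("leave-one-out refit without row %d has no usable channel", i))
  D <- cbind(1, applyAutoscale(Xtr, sc)[, keep, drop = FALSE])
  fit <- lm.fit(D, y[-i])
  if (fit$rank < ncol(D))
    stop(sprintf("leave-one-out refit without row %d is rank deficient", i))
  xi <- (X[i, idx][keep] - sc@means[keep]) / sc@sds[keep]
  sum(c(1, xi) * fit$coefficients)
}

#' Leave-one-out cross-validation statistics
#'
#' For each row i the model is refit on the remaining n - 1 rows (same
#' selected channels) and row i is predicted; with
#' \code{d_i = y_i - yhat_(-i),i} and \code{PRESS = sum(d_i^2)}:
#' residual variance = \code{100 * PRESS / SS_tot},
#' explained variance = \code{100 -} residual variance (exactly, by
#' construction), residual SD = \code{sqrt(PRESS / (n - p - 1))}
#' (\code{loo_sd_denom = "n"} divides by n instead) and mean prediction
#' error = \code{mean(|d_i|)}. Calibration fields come from the full fit.
#'
#' @param X \emph{raw} predictor matrix (rows = samples); autoscaling is
#'   handled per fold according to \code{scaling_mode}
#' @param y response vector
#' @param indices selected 1-based channel indices
#' @param scaling_mode \code{"refit"} (default): autoscaling parameters are
#'   re-estimated inside every fold, so no information from the held-out row
#'   leaks into preprocessing; \code{"fixed"}: scaling is fit once on all rows
#'   and the exact hat-matrix shortcut \code{d_i = e_i / (1 - h_ii)} replaces
#'   the explicit refits. Because OLS predictions with an intercept are
#'   invariant to per-column affine rescaling, both modes agree to numerical
#'   precision on full-rank designs.
#' @param loo_sd_denom denominator convention for the LOO residual SD
#' @return a \linkS4class{ModelStats}
#' @export
looStats <- function(X, y, indices, scaling_mode = c("refit", "fixed"),
                     loo_sd_denom = c("n-p-1", "n")) {
  scaling_mode <- match.arg(scaling_mode)
  loo_sd_denom <- match.arg(loo_sd_denom)
  X <- as.matrix(X)
  idx <- as.integer(indices)
  n <- nrow(X); p <- length(idx)
  if (n <= p + 2L)
    stop(sprintf("leave-one-out needs n > p + 2 (n = %d, p = %d)", n, p))

  sc <- fitAutoscale(X)
  Xs <- applyAutoscale(X, sc)
  D <- cbind(1, Xs[, idx, drop = FALSE])
  fit <- lm.fit(D, y)
  if (fit$rank < p + 1L) stop("full fit is rank deficient on the selected channels")
  stats <- calibrationStats(y, fit$fitted.values, p)

  if (scaling_mode == "fixed") {
    qrD <- qr(D)
    h <- rowSums(qr.Q(qrD)[, seq_len(qrD$rank), drop = FALSE]^2)
    d <- fit$residuals / (1 - h)
  } else {
    d <- vapply(seq_len(n), function(i) y[i] - loo_fold_refit(X, y, idx, i), 0)
  }
  press <- sum(d^2)
  ss_tot <- sum((y - mean(y))^2)
  stats@loo_residual_variance_pct <- 100 * press / ss_tot
  stats@loo_explained_variance_pct <- 100 - stats@loo_residual_variance_pct
  stats@loo_residual_sd <-
    sqrt(press / if (loo_sd_denom == "n") n else (n - p - 1))
  stats@loo_mean_prediction_error <- mean(abs(d))
  stats
}

#' Choose the model size minimizing the LOO prediction error
#'
#' Evaluates the nested prefixes k = 1..length(trace) of a selection trace,
#' computes the leave-one-out mean prediction error for each, and returns the
#' smallest k attaining the minimum together with the full per-k curve.
#'
#' @param X raw predictor matrix
#' @param y response vector
#' @param trace a \linkS4class{SelectionTrace}
#' @param scaling_mode passed to [looStats()]; defaults to the exact
#'   hat-matrix path, which gives the same curve as per-fold refits (see
#'   [looStats()]) at a fraction of the cost
#' @return list with \code{k} (chosen size) and \code{curve}, a data.frame
#'   with columns k, loo_mean_prediction_error, loo_explained_variance_pct
#' @export
chooseModelSize <- function(X, y, trace, scaling_mode = "fixed") {
  kk <- seq_len(length(trace))
  rows <- lapply(kk, function(k) {
    s <- looStats(X, y, trace@predictor_index[seq_len(k)],
                  scaling_mode = scaling_mode)
    c(loo_mean_prediction_error = s@loo_mean_prediction_error,
      loo_explained_variance_pct = s@loo_explained_variance_pct)
  })
  curve <- data.frame(k = kk, do.call(rbind, rows))
  list(k = kk[which.min(curve$loo_mean_prediction_error)], curve = curve)
}

#' Seven report statistics as a named vector
#' @param x a \linkS4class{ModelStats}
#' @return named numeric vector in report order
#' @export
setMethod("statsTable", "ModelStats", function(x) statsVector(x))

setMethod("show", "ModelStats", function(object) {
  v <- statsVector(object)
  cat(sprintf("ModelStats (n = %d, p = %d)\n", object@n, object@p))
  for (i in seq_along(v)) cat(sprintf("  %s: %.4g\n", names(v)[i], v[i]))
  if (object@r_degenerate) cat("  [degenerate constant fit: R reported as 0]\n")
})
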