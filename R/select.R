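#' SELECT: stepwise selection with decorrelation
#'
#' Greedy wavelength selection for multivariate calibration. At each step the
#' unselected channel with the highest absolute Pearson correlation to the
#' (deflated) response is selected; every remaining channel and the response
#' are then decorrelated from it by Gram-Schmidt deflation
#' (\code{v <- v - (<v,u>/<u,u>) u}), so that later steps see only information
#' orthogonal to everything already selected. This removes redundant,
#' collinear channels: an exact duplicate of a selected channel has partial
#' correlation ~0 afterwards and is never selected.
#'
#' The recorded \emph{weight} of a step is the absolute partial correlation
#' at the moment of selection. Weights are not necessarily monotone
#' decreasing: a suppressor channel can become strongly informative only
#' after an earlier channel has been projected out.
#'
#' Stopping: after \code{k_max} steps, or when the best absolute partial
#' correlation drops below \code{r_min}, or when the residual response
#' variance falls below \code{tol_var} times the original response variance.
#'
#' @param Xs autoscaled predictor matrix (rows = samples); flagged or
#'   constant channels are skipped
#' @param y response vector
#' @param k_max maximum number of steps (default 30, the largest reported
#'   model size)
#' @param r_min minimum absolute partial correlation to continue (default 0.05)
#' @param tol_var residual-variance floor relative to var(y) (default 1e-6)
#' @param grid \linkS4class{WavelengthGrid} used to label selected channels
#' @param flagged optional logical vector marking channels to exclude
#'   (e.g. from \linkS4class{ScalingParams})
#'
#' @return a \linkS4class{SelectionTrace} in selection order
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 20, 10)
#' Xs <- applyAutoscale(X, fitAutoscale(X))
#' tr <- runSelect(Xs, Xs[, 3], grid = nirGrid(1100, 2, 10))
#' selectionTable(tr)  # picks channel 3 with weight 1
#' @export
runSelect <- function(Xs, y, k_max = 30L, r_min = 0.05, tol_var = 1e-6,
                      grid = nirGrid(), flagged = NULL) {
  Xs <- as.matrix(Xs)
  n <- nrow(Xs); p <- ncol(Xs)
  if (k_max < 1L) stop("'k_max' must be at least 1")
  if (length(y) != n) stop("length of 'y' must equal nrow(Xs)")
  if (n <= 2L) stop("SELECT needs more than 2 rows to estimate correlations")
  if (anyNA(Xs) || any(!is.finite(Xs)) || anyNA(y) || any(!is.finite(y)))
    stop("non-finite values in predictors or response")
  if (p != grid@n_channels)
    stop(sprintf("Xs has %d channels but the grid has %d", p, grid@n_channels))
  if (is.null(flagged)) flagged <- rep(FALSE, p)

  # work on centered copies; deflation preserves centering exactly
  X <- sweep(Xs, 2, colMeans(Xs), "-")
  yt <- y - mean(y)
  ss_y0 <- sum(yt^2)
  active <- !flagged & colSums(X^2) > 1e-10 * max(1, n - 1)
  if (!any(active)) stop("all channels are flagged or constant; nothing to select")

  ord <- integer(0); wts <- numeric(0)
  for (t in seq_len(min(k_max, sum(active)))) {
    ss_y <- sum(yt^2)
    if (ss_y < tol_var * ss_y0) break
    cn2 <- colSums(X[, active, drop = FALSE]^2)
    alive <- cn2 > 1e-10 * max(1, n - 1)  # deflated-to-zero (redundant) channels
    if (!any(alive)) break
    r <- rep(0, sum(active))
    r[alive] <- as.vector(crossprod(X[, active, drop = FALSE][, alive, drop = FALSE],
                                    yt)) / sqrt(cn2[alive] * ss_y)
    amax <- which.max(abs(r))  # first maximum = smallest channel index
    if (abs(r[amax]) < r_min) break
    k <- which(active)[amax]
    ord <- c(ord, k); wts <- c(wts, min(abs(r[amax]), 1))
    # deflate remaining channels and the response against the pivot
    u <- X[, k]
    uu <- sum(u^2)
    active[k] <- FALSE
    if (any(active)) {
      proj <- as.vector(crossprod(X[, active, drop = FALSE], u)) / uu
      X[, active] <- X[, active, drop = FALSE] - outer(u, proj)
    }
    yt <- yt - u * (sum(u * yt) / uu)
  }
  if (!length(ord)) stop("no channel reached the minimum correlation 'r_min'")
  new("SelectionTrace", order = seq_along(ord),
      predictor_index = as.integer(ord),
      wavelength_nm = indexToWavelength(ord, grid),
      weight = wts, grid = grid)
}

#' Selection trace as a data.frame
#'
#' Four columns mirroring the published report layout: order of selection,
#' 1-based predictor index, wavelength (nm) and weight.
#'
#' @param x a \linkS4class{SelectionTrace}
#' @return data.frame with one row per step
#' @export
setMethod("selectionTable", "SelectionTrace", function(x) {
  data.frame(order = x@order, predictor_index = x@predictor_index,
             wavelength_nm = x@wavelength_nm, weight = x@weight)
})

#' Number of steps in a trace
#' @param x a \linkS4class{SelectionTrace}
#' @export
setMethod("length", "SelectionTrace", function(x) length(x@order))

setMethod("show", "SelectionTrace", function(object) {
  cat(sprintf("SelectionTrace: %d channels selected\n", length(object)))
  print(utils::head(selectionTable(object), 10))
  if (length(object) > 10) cat("...\n")
})
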