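#' Fit column autoscaling parameters
#'
#' Computes per-column sample means and standard deviations (denominator
#' n - 1) of a predictor matrix. Columns whose standard deviation falls below
#' \code{floor * (|mean| + 1)} are flagged as (near-)zero-variance rather than
#' raising an error; variable selection skips flagged channels. The response
#' is never autoscaled here -- only the spectral predictors are column
#' autoscaled.
#'
#' @param X numeric matrix with at least 2 rows (rows = spectra)
#' @param floor relative zero-variance floor (default 1e-12)
#' @return a \linkS4class{ScalingParams}
#' @export
fitAutoscale <- function(X, floor = 1e-12) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("autoscaling needs at least 2 rows")
  if (anyNA(X) || any(!is.finite(X))) stop("X must be finite with no missing values")
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  flagged <- s < floor * (abs(m) + 1)
  s[flagged] <- 1  # neutral divisor; flagged channels are excluded downstream
  new("ScalingParams", means = as.numeric(m), sds = as.numeric(s),
      flagged = flagged, n_fit = nrow(X))
}

#' Apply or invert column autoscaling
#'
#' \code{applyAutoscale} maps column k to \code{(X[,k] - means[k]) / sds[k]};
#' \code{invertAutoscale} is its exact algebraic inverse. Applying parameters
#' fitted on the same matrix yields columns with mean 0 and sd 1 (unflagged
#' channels); applying training-fit parameters to new data generally does not.
#'
#' @param X numeric matrix whose column count matches \code{params}
#' @param params a \linkS4class{ScalingParams}
#' @return matrix of the same shape
#' @export
setMethod("applyAutoscale", signature(X = "matrix", params = "ScalingParams"),
  function(X, params) {
    p <- length(params@means)
    if (ncol(X) != p)
      stop(sprintf("X has %d columns but scaling parameters expect %d",
                   ncol(X), p))
    sweep(sweep(X, 2, params@means, "-"), 2, params@sds, "/")
  })

#' @rdname applyAutoscale
#' @export
setMethod("invertAutoscale", signature(X = "matrix", params = "ScalingParams"),
  function(X, params) {
    p <- length(params@means)
    if (ncol(X) != p)
      stop(sprintf("X has %d columns but scaling parameters expect %d",
                   ncol(X), p))
    sweep(sweep(X, 2, params@sds, "*"), 2, params@means, "+")
  })

setMethod("show", "ScalingParams", function(object) {
  cat(sprintf("ScalingParams: %d channels fitted on %d rows (%d flagged zero-variance)\n",
              length(object@means), object@n_fit, sum(object@flagged)))
})

#' Serialize scaling parameters to and from JSON text
#'
#' @param params a \linkS4class{ScalingParams}
#' @param path file path
#' @return \code{readScalingParams}: a \linkS4class{ScalingParams}
#' @export
writeScalingParams <- function(params, path) {
  jsonlite::write_json(
    list(means = params@means, sds = params@sds,
         flagged = params@flagged, n_fit = params@n_fit),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeScalingParams
#' @export
readScalingParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ScalingParams", means = as.numeric(x$means), sds = as.numeric(x$sds),
      flagged = as.logical(x$flagged), n_fit = as.integer(x$n_fit))
}
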