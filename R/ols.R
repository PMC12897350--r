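#' Ordinary least squares on selected channels
#'
#' Fits an intercept plus one coefficient per selected channel to the
#' \emph{original} autoscaled columns (not the deflated copies used during
#' selection), via a QR least-squares factorization. With highly collinear
#' neighboring wavelengths the coefficients can be large and of opposing
#' sign while predictions remain stable; that is a property of
#' correlated-predictor OLS, not an error.
#'
#' @param Xs autoscaled predictor matrix (rows = samples)
#' @param y response vector
#' @param trace a \linkS4class{SelectionTrace}, or an integer vector of
#'   1-based channel indices (a trace with unit weights is built on
#'   \code{grid})
#' @param scaling the \linkS4class{ScalingParams} used to produce \code{Xs};
#'   stored so the model can be applied to raw spectra
#' @param response_name marker label stored in the model
#' @param grid \linkS4class{WavelengthGrid}, used only when \code{trace} is a
#'   plain index vector
#'
#' @return an \linkS4class{OlsModel}
#' @export
fitOls <- function(Xs, y, trace, scaling, response_name = "y",
                   grid = nirGrid()) {
  Xs <- as.matrix(Xs)
  if (is.numeric(trace) && !is(trace, "SelectionTrace")) {
    idx <- as.integer(trace)
    trace <- new("SelectionTrace", order = seq_along(idx),
                 predictor_index = idx,
                 wavelength_nm = indexToWavelength(idx, grid),
                 weight = rep(1, length(idx)), grid = grid)
  }
  idx <- trace@predictor_index
  n <- nrow(Xs); p <- length(idx)
  if (length(y) != n) stop("length of 'y' must equal nrow(Xs)")
  if (n <= p + 1L)
    stop(sprintf("need more than p + 1 = %d rows to fit %d channels, got %d",
                 p + 1L, p, n))
  if (max(idx) > ncol(Xs)) stop("selected index exceeds the number of channels")
  D <- cbind(`(Intercept)` = 1, Xs[, idx, drop = FALSE])
  fit <- lm.fit(D, y)
  if (fit$rank < p + 1L) {
    dropped <- idx[is.na(fit$coefficients[-1])]
    stop(sprintf("rank-deficient design: channel(s) %s (%s nm) are linearly dependent",
                 paste(dropped, collapse = ", "),
                 paste(indexToWavelength(dropped, trace@grid), collapse = ", ")))
  }
  cf <- fit$coefficients
  new("OlsModel", trace = trace, coefficients = as.numeric(cf[-1]),
      intercept = as.numeric(cf[1]), scaling = scaling,
      response_name = response_name)
}

#' Predict marker values from raw spectra
#'
#' Applies the model's stored autoscaling to the raw absorbance matrix, takes
#' the selected channels and evaluates the linear model. Values at
#' unselected channels do not influence the prediction.
#'
#' @param object an \linkS4class{OlsModel}
#' @param newdata raw absorbance matrix (rows = spectra) on the model's grid,
#'   or a \linkS4class{SpectraSet}
#' @param ... ignored
#' @return numeric vector of predicted responses
#' @export
setMethod("predict", "OlsModel", function(object, newdata, ...) {
  if (is(newdata, "SpectraSet")) newdata <- absorbances(newdata)
  newdata <- as.matrix(newdata)
  p <- length(object@scaling@means)
  if (ncol(newdata) != p)
    stop(sprintf("spectra have %d channels but the model's grid has %d",
                 ncol(newdata), p))
  Xs <- applyAutoscale(newdata, object@scaling)
  idx <- object@trace@predictor_index
  as.numeric(Xs[, idx, drop = FALSE] %*% object@coefficients + object@intercept)
})

#' Coefficients in raw absorbance space
#'
#' Folds the autoscaling into the coefficients:
#' \code{b_raw[k] = b[k] / sd[k]} and
#' \code{intercept_raw = intercept - sum(b[k] * mean[k] / sd[k])}, so that
#' \code{A_raw \%*\% b_raw + intercept_raw} equals [predict()] exactly.
#'
#' @param object an \linkS4class{OlsModel}
#' @return list with \code{coefficients} (named by wavelength) and
#'   \code{intercept}
#' @export
setMethod("coefficientsRaw", "OlsModel", function(object) {
  idx <- object@trace@predictor_index
  s <- object@scaling@sds[idx]
  m <- object@scaling@means[idx]
  b <- object@coefficients / s
  list(coefficients = setNames(b, object@trace@wavelength_nm),
       intercept = object@intercept - sum(object@coefficients * m / s))
})

setMethod("show", "OlsModel", function(object) {
  cat(sprintf("OlsModel for '%s': %d selected channels, intercept %.4g\n",
              object@response_name, length(object@trace), object@intercept))
})

fmt_num <- function(x) vapply(x, function(v) format(v, digits = 15,
                                                    scientific = FALSE,
                                                    trim = TRUE), "")

.panelB_labels <- c(
  "Standard Deviation of the Error",
  "Mean Absolute Error (MAE)",
  "Multiple Correlation Coefficient (R)",
  "Leave-One-Out Residual Variance (%)",
  "Leave-One-Out Residual Standard Deviation",
  "Leave-One-Out Explained Variance (%)",
  "Leave-One-Out Mean Prediction Error")

statsVector <- function(s) {
  setNames(c(s@sd_error, s@mae, s@r, s@loo_residual_variance_pct,
             s@loo_residual_sd, s@loo_explained_variance_pct,
             s@loo_mean_prediction_error), .panelB_labels)
}

#' Render a model report (panels A and B)
#'
#' Emits the two-panel tab-delimited report used for published models: panel
#' A lists one selection step per row (order, predictor index, wavelength,
#' weight, coefficient) followed by the intercept; panel B lists the seven
#' model statistics. [parseModelReport()] inverts it and re-rendering a
#' parsed report is byte-identical.
#'
#' @param object an \linkS4class{OlsModel}
#' @param stats a \linkS4class{ModelStats} computed for the model
#' @return character vector of report lines
#' @export
setMethod("modelReport", signature(object = "OlsModel", stats = "ModelStats"),
  function(object, stats) {
    tab <- selectionTable(object@trace)
    lines <- c(
      "(A) SELECT-OLS Chemometric Modeling",
      "Order of Selection\tPredictor Index\tWavelength (nm)\tWeight\tCoefficient",
      sprintf("%d\t%d\t%s\t%s\t%s", tab$order, tab$predictor_index,
              fmt_num(tab$wavelength_nm), fmt_num(tab$weight),
              fmt_num(object@coefficients)),
      sprintf("Intercept\t%s", fmt_num(object@intercept)),
      "(B) Statistical Characteristics",
      sprintf("%s\t%s", .panelB_labels, fmt_num(statsVector(stats))))
    lines
  })

#' @rdname modelReport
#' @param lines character vector as produced by [modelReport()]
#' @return \code{parseModelReport}: list with \code{panelA} (data.frame:
#'   order, predictor_index, wavelength_nm, weight, coefficient),
#'   \code{intercept}, and \code{panelB} (named numeric vector)
#' @export
parseModelReport <- function(lines) {
  ia <- which(lines == "(A) SELECT-OLS Chemometric Modeling")
  ib <- which(lines == "(B) Statistical Characteristics")
  ii <- grep("^Intercept\t", lines)
  if (!length(ia) || !length(ib) || !length(ii))
    stop("not a model report: missing panel markers")
  rows <- lines[(ia + 2):(ii - 1)]
  parts <- do.call(rbind, strsplit(rows, "\t", fixed = TRUE))
  panelA <- data.frame(order = as.integer(parts[, 1]),
                       predictor_index = as.integer(parts[, 2]),
                       wavelength_nm = as.numeric(parts[, 3]),
                       weight = as.numeric(parts[, 4]),
                       coefficient = as.numeric(parts[, 5]))
  bparts <- strsplit(lines[(ib + 1):length(lines)], "\t", fixed = TRUE)
  panelB <- setNames(vapply(bparts, function(z) as.numeric(z[2]), 0),
                     vapply(bparts, `[`, "", 1))
  list(panelA = panelA,
       intercept = as.numeric(sub("^Intercept\t", "", lines[ii])),
       panelB = panelB)
}

#' Serialize a fitted model to JSON and back
#'
#' The artifact stores the response name, grid, selected indices with
#' wavelengths and weights, coefficients in both autoscaled and raw space,
#' the intercept and the full scaling parameters, at full precision.
#'
#' @param object an \linkS4class{OlsModel}
#' @param path file path
#' @return \code{readOlsModel}: an \linkS4class{OlsModel}
#' @export
writeOlsModel <- function(object, path) {
  g <- object@trace@grid
  raw <- coefficientsRaw(object)
  jsonlite::write_json(list(
    response_name = object@response_name,
    grid = list(start_nm = g@start_nm, step_nm = g@step_nm,
                n_channels = g@n_channels),
    predictor_index = object@trace@predictor_index,
    wavelength_nm = object@trace@wavelength_nm,
    weight = object@trace@weight,
    coefficients = object@coefficients,
    intercept = object@intercept,
    coefficients_raw = as.numeric(raw$coefficients),
    intercept_raw = raw$intercept,
    scaling = list(means = object@scaling@means, sds = object@scaling@sds,
                   flagged = object@scaling@flagged,
                   n_fit = object@scaling@n_fit)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeOlsModel
#' @export
readOlsModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- nirGrid(x$grid$start_nm, x$grid$step_nm, x$grid$n_channels)
  idx <- as.integer(x$predictor_index)
  trace <- new("SelectionTrace", order = seq_along(idx),
               predictor_index = idx,
               wavelength_nm = as.numeric(x$wavelength_nm),
               weight = as.numeric(x$weight), grid = grid)
  scaling <- new("ScalingParams", means = as.numeric(x$scaling$means),
                 sds = as.numeric(x$scaling$sds),
                 flagged = as.logical(x$scaling$flagged),
                 n_fit = as.integer(x$scaling$n_fit))
  new("OlsModel", trace = trace, coefficients = as.numeric(x$coefficients),
      intercept = as.numeric(x$intercept), scaling = scaling,
      response_name = x$response_name)
}
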