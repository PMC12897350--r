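#' @import methods
#' @importFrom stats cor sd var median setNames rnorm runif lm.fit
#'   complete.cases predict
#' @importFrom utils read.csv write.csv read.delim head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Regular wavelength grid of an NIR instrument
#'
#' A fixed, regularly spaced acquisition grid. The default instrument grid
#' covers 1100--2498 nm at a 2 nm step (700 channels), and predictor indices
#' are 1-based channel positions on this grid, so that
#' \code{nm = start_nm + step_nm * (i - 1)}.
#'
#' @slot start_nm first wavelength (nm)
#' @slot step_nm channel spacing (nm), strictly positive
#' @slot n_channels number of channels
#'
#' @seealso [nirGrid()], [indexToWavelength()], [wavelengthToIndex()]
#' @export
setClass("WavelengthGrid",
  representation(start_nm = "numeric", step_nm = "numeric",
                 n_channels = "integer"),
  prototype(start_nm = 1100, step_nm = 2, n_channels = 700L))

setValidity("WavelengthGrid", function(object) {
  msg <- character()
  if (length(object@start_nm) != 1L || !is.finite(object@start_nm))
    msg <- c(msg, "'start_nm' must be a single finite number")
  if (length(object@step_nm) != 1L || !is.finite(object@step_nm) ||
      object@step_nm <= 0)
    msg <- c(msg, "'step_nm' must be a single positive number")
  if (length(object@n_channels) != 1L || is.na(object@n_channels) ||
      object@n_channels < 1L)
    msg <- c(msg, "'n_channels' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Absorbance spectra on a fixed wavelength grid
#'
#' \code{SpectraSet} extends \linkS4class{SummarizedExperiment}: channels are
#' rows (with \code{wavelength_nm} in \code{rowData}), individual spectra are
#' columns (with \code{sample_id} and \code{replicate_id} in \code{colData}),
#' and the single assay \code{"absorbance"} holds absorbance units. The grid
#' is carried in \code{metadata(x)$grid}.
#'
#' User-facing accessors follow the tabular orientation of the exchange
#' format: [absorbances()] returns a spectra-by-channels matrix.
#'
#' @seealso [SpectraSet()], [readSpectra()], [averageReplicates()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- character()
  grid <- S4Vectors::metadata(object)$grid
  if (!is(grid, "WavelengthGrid"))
    return("metadata(x)$grid must be a WavelengthGrid")
  if (nrow(object) != grid@n_channels)
    msg <- c(msg, sprintf("number of channels (%d) must equal grid n_channels (%d)",
                          nrow(object), grid@n_channels))
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'absorbance' is required")
  else if (anyNA(SummarizedExperiment::assay(object, "absorbance")))
    msg <- c(msg, "absorbance matrix must not contain missing values")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "replicate_id") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'sample_id' and 'replicate_id'")
  else {
    key <- paste(cd$sample_id, cd$replicate_id, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "(sample_id, replicate_id) pairs must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Column autoscaling parameters
#'
#' Per-channel means and sample standard deviations (denominator n - 1)
#' estimated from a training matrix, stored so that a fitted model can be
#' applied to new raw spectra. Channels whose standard deviation falls below
#' the configured floor are flagged and must be skipped by variable selection.
#'
#' @slot means per-channel mean (absorbance units)
#' @slot sds per-channel standard deviation (absorbance units)
#' @slot flagged logical, TRUE for (near-)zero-variance channels
#' @slot n_fit number of rows the parameters were estimated from
#'
#' @seealso [fitAutoscale()], [applyAutoscale()], [invertAutoscale()]
#' @export
setClass("ScalingParams",
  representation(means = "numeric", sds = "numeric", flagged = "logical",
                 n_fit = "integer"))

setValidity("ScalingParams", function(object) {
  msg <- character()
  p <- length(object@means)
  if (length(object@sds) != p || length(object@flagged) != p)
    msg <- c(msg, "'means', 'sds' and 'flagged' must have equal length")
  if (any(!is.finite(object@means)) || any(!is.finite(object@sds)))
    msg <- c(msg, "means and sds must be finite")
  if (any(object@sds[!object@flagged] <= 0))
    msg <- c(msg, "unflagged channels must have sd > 0")
  if (length(msg)) msg else TRUE
})

#' Ordered record of SELECT steps
#'
#' One row per selection step: the 1-based step number, the 1-based predictor
#' (channel) index, the corresponding wavelength, and the weight, defined as
#' the absolute partial correlation between the deflated channel and the
#' deflated response at the moment of selection (in [0, 1]). Weights need not
#' decrease monotonically: a channel can become highly informative only after
#' earlier channels have been projected out.
#'
#' @slot order integer step numbers 1..k
#' @slot predictor_index 1-based channel indices, unique
#' @slot wavelength_nm wavelengths consistent with the grid map
#' @slot weight absolute partial correlations in [0, 1]
#' @slot grid the \linkS4class{WavelengthGrid} the indices refer to
#'
#' @seealso [runSelect()], [selectionTable()]
#' @export
setClass("SelectionTrace",
  representation(order = "integer", predictor_index = "integer",
                 wavelength_nm = "numeric", weight = "numeric",
                 grid = "WavelengthGrid"))

setValidity("SelectionTrace", function(object) {
  msg <- character()
  k <- length(object@order)
  if (length(object@predictor_index) != k || length(object@wavelength_nm) != k ||
      length(object@weight) != k)
    msg <- c(msg, "all step vectors must have equal length")
  if (k > 0) {
    if (anyDuplicated(object@predictor_index))
      msg <- c(msg, "predictor indices must be unique across steps")
    if (!identical(object@order, seq_len(k)))
      msg <- c(msg, "'order' must be 1..k")
    if (any(object@weight < 0 | object@weight > 1 + 1e-12))
      msg <- c(msg, "weights must lie in [0, 1]")
    expect_nm <- object@grid@start_nm +
      object@grid@step_nm * (object@predictor_index - 1L)
    if (any(abs(expect_nm - object@wavelength_nm) > 1e-9))
      msg <- c(msg, "wavelengths inconsistent with predictor indices on the grid")
  }
  if (length(msg)) msg else TRUE
})

#' Ordinary least squares model on selected channels
#'
#' Coefficients live in autoscaled-predictor space (response units per
#' autoscaled absorbance unit); [coefficientsRaw()] converts to raw
#' absorbance space. The stored \linkS4class{ScalingParams} make the model
#' applicable to new raw spectra via [predict()].
#'
#' @slot trace the \linkS4class{SelectionTrace} behind the model
#' @slot coefficients one per selected channel, in trace order
#' @slot intercept response units
#' @slot scaling \linkS4class{ScalingParams} fitted on the training spectra
#' @slot response_name marker label (e.g. "pv")
#'
#' @seealso [fitOls()], [predict()], [modelReport()]
#' @export
setClass("OlsModel",
  representation(trace = "SelectionTrace", coefficients = "numeric",
                 intercept = "numeric", scaling = "ScalingParams",
                 response_name = "character"))

setValidity("OlsModel", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@trace@predictor_index))
    msg <- c(msg, "coefficient count must equal the number of selected channels")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "'intercept' must be a single finite number")
  if (max(object@trace@predictor_index, 0L) > length(object@scaling@means))
    msg <- c(msg, "selected indices exceed the scaling parameter length")
  if (length(msg)) msg else TRUE
})

#' Calibration and leave-one-out statistics of an OLS model
#'
#' The seven model-report statistics: calibration residual standard deviation
#' (denominator n - p - 1), mean absolute calibration error, multiple
#' correlation coefficient R; and from leave-one-out cross-validation the
#' residual variance (100 * PRESS / SS_tot, %), residual standard deviation,
#' explained variance (100 - residual variance, may be negative for terrible
#' models and is reported unclipped) and mean absolute prediction error.
#'
#' @slot sd_error calibration residual SD (response units)
#' @slot mae mean absolute calibration error
#' @slot r multiple correlation coefficient in [0, 1]; 0 with
#'   \code{r_degenerate = TRUE} when the fit is constant
#' @slot loo_residual_variance_pct percent
#' @slot loo_residual_sd response units
#' @slot loo_explained_variance_pct percent; equals
#'   \code{100 - loo_residual_variance_pct} exactly
#' @slot loo_mean_prediction_error response units
#' @slot n,p training rows and number of predictors
#' @slot r_degenerate flag for a constant (degenerate) fit
#'
#' @seealso [calibrationStats()], [looStats()]
#' @export
setClass("ModelStats",
  representation(sd_error = "numeric", mae = "numeric", r = "numeric",
                 loo_residual_variance_pct = "numeric",
                 loo_residual_sd = "numeric",
                 loo_explained_variance_pct = "numeric",
                 loo_mean_prediction_error = "numeric",
                 n = "integer", p = "integer", r_degenerate = "logical"),
  prototype(loo_residual_variance_pct = NA_real_, loo_residual_sd = NA_real_,
            loo_explained_variance_pct = NA_real_,
            loo_mean_prediction_error = NA_real_, r_degenerate = FALSE))
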