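#' Published reference SELECT-OLS model reports
#'
#' The package ships the variable-selection panels and statistics of seven
#' published SELECT-OLS calibrations (one per oxidation marker) from a
#' 142-sample deep-frying study of olive and sunflower oils, as plain TSV
#' fixtures. They serve as a consistency surface: every
#' (predictor index, wavelength) pair must satisfy the grid convention
#' \code{nm = 1100 + 2 * (index - 1)}, and every residual/explained variance
#' pair must sum to 100.
#'
#' @return \code{referenceModels()}: data.frame with columns marker, order,
#'   predictor_index, wavelength_nm, weight, coefficient (175 rows);
#'   \code{referenceStats()}: data.frame with one row per marker holding the
#'   intercept and the seven report statistics.
#' @examples
#' ref <- referenceModels()
#' all(ref$wavelength_nm == 1100 + 2 * (ref$predictor_index - 1))  # TRUE
#' @export
referenceModels <- function() {
  read.delim(system.file("extdata", "reference_models_panelA.tsv",
                         package = "oxiNIR"))
}

#' @rdname referenceModels
#' @export
referenceStats <- function() {
  read.delim(system.file("extdata", "reference_models_panelB.tsv",
                         package = "oxiNIR"))
}
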