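#' Total oxidation index
#'
#' TOTOX combines primary (peroxide value) and secondary (anisidine value)
#' oxidation into a single index: \code{TOTOX = 2 * PV + AnV}. Vectorized.
#'
#' @param pv peroxide value, meq O2/kg, non-negative
#' @param anv p-anisidine value, dimensionless, non-negative
#' @return numeric, \code{2 * pv + anv}
#' @examples
#' totox(10, 5)  # 25
#' @export
totox <- function(pv, anv) {
  if (any(pv < 0, na.rm = TRUE) || any(anv < 0, na.rm = TRUE))
    stop("'pv' and 'anv' must be non-negative")
  2 * pv + anv
}

#' Specific extinction coefficient (Beer-Lambert)
#'
#' \code{K = A / (c * l)} for absorbance A, concentration c (g/100 mL) and
#' path length l (cm); used for the conjugated diene/triene indices K232 and
#' K270.
#'
#' @param A absorbance, non-negative
#' @param c concentration in g/100 mL, positive
#' @param l path length in cm, positive
#' @return specific extinction K
#' @export
specificExtinction <- function(A, c, l) {
  if (any(c <= 0) || any(l <= 0)) stop("'c' and 'l' must be positive")
  if (any(A < 0, na.rm = TRUE)) stop("'A' must be non-negative")
  A / (c * l)
}

#' Delta-K: deviation from the linear extinction baseline
#'
#' \code{delta_k = k270 - (k266 + k274) / 2}, the standard trade convention:
#' the deviation of the extinction at 270 nm from the straight line through
#' its neighbors at 266 and 274 nm. Any collinear triple gives exactly 0, and
#' the value is invariant under adding a straight line in wavelength to all
#' three extinctions.
#'
#' @param k266,k270,k274 specific extinctions at 266, 270 and 274 nm
#' @return delta-K (any sign)
#' @examples
#' deltaK(0.30, 0.50, 0.34)  # 0.18
#' @export
deltaK <- function(k266, k270, k274) {
  if (any(!is.finite(c(k266, k270, k274))))
    stop("extinctions must be finite")
  k270 - (k266 + k274) / 2
}

#' Pairwise Pearson correlations of the seven oxidation markers
#'
#' @param markers a marker table (see [validateMarkerTable()]) with at least
#'   3 samples and no missing marker values
#' @return 7 x 7 symmetric correlation matrix with unit diagonal; entries
#'   involving a constant marker are NA (with a warning) rather than an error
#' @export
markerCorrelations <- function(markers) {
  validateMarkerTable(markers)
  M <- as.matrix(markers[, markerNames()])
  if (nrow(M) < 3L) stop("need at least 3 samples to estimate correlations")
  if (anyNA(M)) stop("marker table contains missing values")
  const <- apply(M, 2, sd) == 0
  if (any(const))
    warning(sprintf("constant marker column(s): %s; correlations set to NA",
                    paste(markerNames()[const], collapse = ", ")))
  suppressWarnings(cor(M))
}
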