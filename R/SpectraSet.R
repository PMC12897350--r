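#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix, one row per spectrum, one column per
#'   channel in ascending wavelength order
#' @param sample_ids character vector, one per spectrum
#' @param replicate_ids vector (typically 1..3), one per spectrum
#' @param grid the \linkS4class{WavelengthGrid}; its channel count must match
#'   \code{ncol(absorbance)}
#' @param meta optional data.frame of per-spectrum metadata joined into
#'   \code{colData} (e.g. category, treatment)
#'
#' @return a \linkS4class{SpectraSet}
#' @export
SpectraSet <- function(absorbance, sample_ids, replicate_ids,
                       grid = nirGrid(), meta = NULL) {
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != grid@n_channels)
    stop(sprintf("absorbance has %d channels but the grid has %d (%g-%g nm)",
                 ncol(absorbance), grid@n_channels, grid@start_nm, gridEnd(grid)))
  n <- nrow(absorbance)
  if (length(sample_ids) != n || length(replicate_ids) != n)
    stop("'sample_ids' and 'replicate_ids' must have one entry per spectrum")
  cd <- S4Vectors::DataFrame(sample_id = as.character(sample_ids),
                             replicate_id = as.character(replicate_ids))
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    for (cn in setdiff(colnames(meta), colnames(cd))) cd[[cn]] <- meta[[cn]]
  }
  nm <- wavelengths(grid)
  a <- t(absorbance)
  dimnames(a) <- list(as.character(nm),
                      paste(cd$sample_id, cd$replicate_id, sep = "."))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = a),
    rowData = S4Vectors::DataFrame(wavelength_nm = nm),
    colData = cd)
  S4Vectors::metadata(se)$grid <- grid
  new("SpectraSet", se)
}

#' Accessors for SpectraSet
#'
#' \code{absorbances} returns the spectra-by-channels absorbance matrix
#' (rows = spectra, columns = channels in ascending wavelength), the
#' orientation the modeling functions consume. \code{sampleIds} and
#' \code{replicateIds} return the per-spectrum labels.
#'
#' @param x a \linkS4class{SpectraSet}
#' @return matrix or character vector
#' @export
setMethod("absorbances", "SpectraSet", function(x) {
  t(SummarizedExperiment::assay(x, "absorbance"))
})

#' @rdname absorbances
#' @export
setMethod("sampleIds", "SpectraSet", function(x) {
  SummarizedExperiment::colData(x)$sample_id
})

#' @rdname absorbances
#' @export
setMethod("replicateIds", "SpectraSet", function(x) {
  SummarizedExperiment::colData(x)$replicate_id
})

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraSet", function(x) {
  wavelengths(S4Vectors::metadata(x)$grid)
})

#' Grid of a SpectraSet
#' @param x a \linkS4class{SpectraSet}
#' @return the \linkS4class{WavelengthGrid}
#' @export
spectraGrid <- function(x) S4Vectors::metadata(x)$grid

setMethod("show", "SpectraSet", function(object) {
  g <- spectraGrid(object)
  cat(sprintf("SpectraSet: %d spectra from %d samples on %g-%g nm (%d channels)\n",
              ncol(object), length(unique(sampleIds(object))),
              g@start_nm, gridEnd(g), g@n_channels))
})

#' Average replicate spectra within each sample
#'
#' Returns one spectrum per \code{sample_id}, each channel the unweighted
#' arithmetic mean over that sample's replicates, mirroring the use of
#' triplicate means in the reference analyses. The replicate label is set to
#' the sentinel \code{"mean"}; sample order follows first appearance.
#'
#' @param x a \linkS4class{SpectraSet}
#' @return a \linkS4class{SpectraSet} with one row per sample
#' @export
setMethod("averageReplicates", "SpectraSet", function(x) {
  ids <- sampleIds(x)
  uid <- unique(ids)
  A <- absorbances(x)
  M <- matrix(0, length(uid), ncol(A))
  for (j in seq_along(uid)) {
    rows <- which(ids == uid[j])
    M[j, ] <- colMeans(A[rows, , drop = FALSE])
  }
  cd <- SummarizedExperiment::colData(x)
  extra <- setdiff(colnames(cd), c("sample_id", "replicate_id"))
  meta <- if (length(extra))
    as.data.frame(cd[match(uid, ids), extra, drop = FALSE]) else NULL
  SpectraSet(M, uid, rep("mean", length(uid)), grid = spectraGrid(x),
             meta = meta)
})

#' Read and write wide spectra CSV
#'
#' The exchange format is a wide CSV: columns \code{sample_id},
#' \code{replicate_id}, then one column per channel named by its wavelength in
#' nm in ascending order (\code{1100,1102,...,2498} on the default grid).
#' \code{writeSpectra} followed by \code{readSpectra} is the identity up to
#' numeric round-trip.
#'
#' @param path file path
#' @param grid expected \linkS4class{WavelengthGrid}; the header must match it
#'   exactly
#' @return \code{readSpectra}: a \linkS4class{SpectraSet};
#'   \code{writeSpectra}: \code{path}, invisibly
#' @export
readSpectra <- function(path, grid = nirGrid()) {
  df <- read.csv(path, check.names = FALSE, colClasses = NA)
  need <- c("sample_id", "replicate_id")
  if (!all(need %in% colnames(df)[1:2]))
    stop("spectra file must start with columns 'sample_id', 'replicate_id'")
  wlcols <- colnames(df)[-(1:2)]
  nm <- suppressWarnings(as.numeric(wlcols))
  if (anyNA(nm))
    stop(sprintf("non-numeric channel column header(s): %s",
                 paste(wlcols[is.na(nm)][1:3], collapse = ", ")))
  expect <- wavelengths(grid)
  if (length(nm) != length(expect) || any(abs(nm - expect) > 1e-9))
    stop(sprintf(
      "header/grid mismatch: file has %d channels (%g-%g nm), grid expects %d (%g-%g nm)",
      length(nm), min(nm), max(nm), grid@n_channels, grid@start_nm, gridEnd(grid)))
  A <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(A) || anyNA(A)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -(1:2)], 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric absorbance at row %d, column '%s'",
                 bad[1, 1], wlcols[bad[1, 2]]))
  }
  SpectraSet(A, df$sample_id, df$replicate_id, grid = grid)
}

#' @rdname readSpectra
#' @param x a \linkS4class{SpectraSet}
#' @export
writeSpectra <- function(x, path) {
  df <- data.frame(sample_id = sampleIds(x), replicate_id = replicateIds(x),
                   check.names = FALSE)
  A <- absorbances(x)
  colnames(A) <- as.character(wavelengths(x))
  write.csv(cbind(df, as.data.frame(A, check.names = FALSE)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Oxidation marker names handled by the pipeline
#' @return character vector of the seven marker column names
#' @export
markerNames <- function() {
  c("acidity", "k232", "k270", "delta_k", "pv", "anv", "totox")
}

#' Validate, read and write per-sample marker tables
#'
#' A marker table is a data.frame with a \code{sample_id} column and the
#' seven marker columns \code{acidity} (% oleic acid), \code{k232},
#' \code{k270}, \code{delta_k}, \code{pv} (meq O2/kg), \code{anv} and
#' \code{totox}. All markers must be non-negative except \code{delta_k}, and
#' \code{totox} must equal \code{2 * pv + anv} wherever both are present.
#'
#' @param x a data.frame
#' @param tol tolerance on the TOTOX identity
#' @return \code{x}, invisibly, or an error naming the violated constraint
#' @export
validateMarkerTable <- function(x, tol = 1e-8) {
  need <- c("sample_id", markerNames())
  miss <- setdiff(need, colnames(x))
  if (length(miss))
    stop(sprintf("marker table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(x$sample_id))
    stop("duplicated sample_id in marker table")
  for (m in setdiff(markerNames(), "delta_k"))
    if (any(x[[m]] < 0, na.rm = TRUE))
      stop(sprintf("marker '%s' must be non-negative", m))
  ok <- stats::complete.cases(x[, c("pv", "anv", "totox")])
  dev <- abs(x$totox[ok] - (2 * x$pv[ok] + x$anv[ok]))
  if (any(dev > tol * pmax(1, abs(x$totox[ok]))))
    stop("totox column violates totox = 2*pv + anv")
  invisible(x)
}

#' @rdname validateMarkerTable
#' @param path file path of the marker CSV
#' @export
readMarkerTable <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  validateMarkerTable(df)
  df
}

#' @rdname validateMarkerTable
#' @export
writeMarkerTable <- function(x, path) {
  validateMarkerTable(x)
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write sample metadata CSV
#'
#' Columns: \code{sample_id}, \code{category}, \code{class}
#' (olive/sunflower), \code{treatment}, \code{temperature_C},
#' \code{duration_h}, \code{supplemented}. Controls carry NA temperature and
#' duration; treatments E1--E4 are unsupplemented and E5--E8 supplemented.
#'
#' @param path file path
#' @param x a data.frame of sample metadata
#' @return a data.frame / \code{path} invisibly
#' @export
readSampleMeta <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  validateSampleMeta(df)
  df
}

#' @rdname readSampleMeta
#' @export
writeSampleMeta <- function(x, path) {
  validateSampleMeta(x)
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readSampleMeta
#' @export
validateSampleMeta <- function(x) {
  need <- c("sample_id", "category", "treatment", "temperature_C",
            "duration_h", "supplemented")
  miss <- setdiff(need, colnames(x))
  if (length(miss))
    stop(sprintf("sample metadata is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  ctrl <- x$treatment %in% c("C1", "C2", "S", "C")
  if (any(!is.na(x$temperature_C[ctrl])) || any(!is.na(x$duration_h[ctrl])))
    stop("control samples must not carry temperature or duration")
  uns <- x$treatment %in% paste0("E", 1:4)
  sup <- x$treatment %in% paste0("E", 5:8)
  if (any(x$supplemented[uns]))
    stop("treatments E1-E4 must be unsupplemented")
  if (any(!x$supplemented[sup]))
    stop("treatments E5-E8 must be supplemented")
  invisible(x)
}
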