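#' Fit a SELECT-OLS calibration for one marker
#'
#' The full per-marker workflow: column-autoscale the raw spectra, run
#' [runSelect()] to rank channels, choose the model size minimizing the
#' leave-one-out mean prediction error over nested prefixes of the trace
#' ([chooseModelSize()]), refit OLS on the chosen channels of the original
#' autoscaled matrix, and compute calibration and LOO statistics.
#'
#' @param X raw absorbance matrix (rows = samples) or a
#'   \linkS4class{SpectraSet} (replicates are averaged first when
#'   \code{replicates = "average"})
#' @param y response vector, aligned with the rows of \code{X}
#' @param response_name marker label
#' @param grid wavelength grid (taken from the SpectraSet when one is given)
#' @param k_max,r_min,tol_var selection settings, see [runSelect()]
#' @param scaling_mode LOO mode for model-size choice, see [looStats()]
#' @return list with \code{model} (\linkS4class{OlsModel}), \code{stats}
#'   (\linkS4class{ModelStats} at the chosen size), \code{trace} (the full
#'   trace), \code{k} (chosen size) and \code{loo_curve}
#' @export
fitMarkerModel <- function(X, y, response_name = "y", grid = nirGrid(),
                           k_max = 30L, r_min = 0.05, tol_var = 1e-6,
                           scaling_mode = "fixed") {
  if (is(X, "SpectraSet")) {
    grid <- spectraGrid(X)
    X <- absorbances(X)
  }
  X <- as.matrix(X)
  scaling <- fitAutoscale(X)
  Xs <- applyAutoscale(X, scaling)
  trace <- runSelect(Xs, y, k_max = k_max, r_min = r_min, tol_var = tol_var,
                     grid = grid, flagged = scaling@flagged)
  # cap k so LOO keeps n > p + 2
  kmax_loo <- min(length(trace), nrow(X) - 4L)
  sub <- new("SelectionTrace", order = seq_len(kmax_loo),
             predictor_index = trace@predictor_index[seq_len(kmax_loo)],
             wavelength_nm = trace@wavelength_nm[seq_len(kmax_loo)],
             weight = trace@weight[seq_len(kmax_loo)], grid = grid)
  choice <- chooseModelSize(X, y, sub, scaling_mode = scaling_mode)
  k <- choice$k
  final_trace <- new("SelectionTrace", order = seq_len(k),
                     predictor_index = trace@predictor_index[seq_len(k)],
                     wavelength_nm = trace@wavelength_nm[seq_len(k)],
                     weight = trace@weight[seq_len(k)], grid = grid)
  model <- fitOls(Xs, y, final_trace, scaling, response_name = response_name)
  stats <- looStats(X, y, final_trace@predictor_index,
                    scaling_mode = scaling_mode)
  list(model = model, stats = stats, trace = trace, k = k,
       loo_curve = choice$curve)
}

#' Run the full SELECT-OLS analysis for every marker
#'
#' For each of the seven oxidation markers: autoscale, select, choose the
#' model size by LOO, fit OLS, validate. Spectra and markers are joined on
#' \code{sample_id}; with \code{replicates = "average"} (the default)
#' replicate spectra are averaged to one spectrum per sample first, with
#' \code{"individual"} each replicate spectrum is paired with its sample's
#' marker values.
#'
#' @param spectra a \linkS4class{SpectraSet}
#' @param markers a marker table (see [validateMarkerTable()])
#' @param marker_names markers to model (default: all seven)
#' @param replicates \code{"average"} or \code{"individual"}
#' @param ... passed to [fitMarkerModel()] (k_max, r_min, tol_var,
#'   scaling_mode)
#' @return list of per-marker results (as from [fitMarkerModel()]) plus
#'   \code{summary}, a data.frame with one row per marker (marker, k,
#'   r, loo_explained_variance_pct, loo_residual_variance_pct,
#'   loo_mean_prediction_error)
#' @export
runStudy <- function(spectra, markers, marker_names = markerNames(),
                     replicates = c("average", "individual"), ...) {
  replicates <- match.arg(replicates)
  validateMarkerTable(markers)
  miss <- setdiff(marker_names, colnames(markers))
  if (length(miss))
    stop(sprintf("marker table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (replicates == "average") spectra <- averageReplicates(spectra)
  ids <- sampleIds(spectra)
  hit <- match(ids, markers$sample_id)
  if (anyNA(hit))
    stop(sprintf("spectra sample_id(s) missing from the marker table: %s",
                 paste(unique(ids[is.na(hit)])[1:3], collapse = ", ")))
  X <- absorbances(spectra)
  grid <- spectraGrid(spectra)
  results <- lapply(marker_names, function(m) {
    fitMarkerModel(X, markers[[m]][hit], response_name = m, grid = grid, ...)
  })
  names(results) <- marker_names
  results$summary <- data.frame(
    marker = marker_names,
    k = vapply(results[marker_names], `[[`, 0L, "k"),
    r = vapply(results[marker_names], function(z) z$stats@r, 0),
    loo_explained_variance_pct = vapply(results[marker_names],
      function(z) z$stats@loo_explained_variance_pct, 0),
    loo_residual_variance_pct = vapply(results[marker_names],
      function(z) z$stats@loo_residual_variance_pct, 0),
    loo_mean_prediction_error = vapply(results[marker_names],
      function(z) z$stats@loo_mean_prediction_error, 0))
  results
}

#' Write all artifacts of a study run
#'
#' Per marker: the model JSON, the two-panel report TSV and the per-k LOO
#' curve CSV; plus the run summary CSV. File names embed the marker name.
#'
#' @param results output of [runStudy()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeRunArtifacts <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in results$summary$marker) {
    res <- results[[m]]
    p1 <- file.path(dir, sprintf("model_%s.json", m))
    writeOlsModel(res$model, p1)
    p2 <- file.path(dir, sprintf("report_%s.tsv", m))
    writeLines(modelReport(res$model, res$stats), p2)
    p3 <- file.path(dir, sprintf("loo_curve_%s.csv", m))
    write.csv(res$loo_curve, p3, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p1, p2, p3)
  }
  p4 <- file.path(dir, "summary.csv")
  write.csv(results$summary, p4, row.names = FALSE, quote = FALSE)
  invisible(c(paths, p4))
}

#' Compare a study run against the generator's truth record
#'
#' For each modeled marker, reports the chosen model size, calibration R,
#' LOO explained variance, the distance (nm) from the nearest selected
#' wavelength to the marker's strongest generating band, and whether that
#' distance is within \code{tol_nm}.
#'
#' @param results output of [runStudy()] on a synthetic study
#' @param truth the \code{truth} element of [generateStudy()]
#' @param tol_nm recovery tolerance in nm (default 6, i.e. +/- 3 channels)
#' @return data.frame with one row per marker
#' @export
evaluateAgainstTruth <- function(results, truth, tol_nm = 6) {
  if (is.null(truth$primary_band_nm))
    stop("truth record is missing 'primary_band_nm'")
  do.call(rbind, lapply(results$summary$marker, function(m) {
    res <- results[[m]]
    sel_nm <- res$model@trace@wavelength_nm
    band <- truth$primary_band_nm[[m]]
    d <- min(abs(sel_nm - band))
    data.frame(marker = m, k = res$k, r = res$stats@r,
               loo_explained_variance_pct = res$stats@loo_explained_variance_pct,
               primary_band_nm = band, nearest_selected_nm = sel_nm[
                 which.min(abs(sel_nm - band))],
               band_distance_nm = d, recovered = d <= tol_nm)
  }))
}
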