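zero_noise_config <- function(seed = 1) {
  cfg <- defaultSimConfig(seed)
  cfg$marker_noise_sd[] <- 0
  cfg$replicate_noise_sd <- 0
  cfg
}

test_that("the default design replicates the study layout", {
  meta <- designSamples()
  expect_equal(nrow(meta), 142L)
  counts <- table(meta$category)
  expect_true(all(counts[c("SO", "SOHO")] == 5))
  expect_true(all(counts[setdiff(names(counts), c("SO", "SOHO"))] == 11))
  expect_equal(sum(meta$class == "olive"), 132L)
  expect_silent(validateSampleMeta(meta))
  # frying grid
  e4 <- meta[meta$treatment == "E4", ]
  expect_true(all(e4$temperature_C == 210 & e4$duration_h == 6))
  expect_true(all(meta$supplemented[meta$treatment %in% paste0("E", 5:8)]))
})

test_that("a default study yields 426 triplicate spectra that average to 142", {
  study <- generateStudy(defaultSimConfig(seed = 2))
  expect_equal(ncol(study$spectra), 426L)
  expect_equal(nrow(study$markers), 142L)
  avg <- averageReplicates(study$spectra)
  expect_equal(ncol(avg), 142L)
})

test_that("the same seed reproduces the study bit for bit; seeds differ in noise only", {
  s1 <- generateStudy(defaultSimConfig(seed = 5))
  s2 <- generateStudy(defaultSimConfig(seed = 5))
  expect_identical(absorbances(s1$spectra), absorbances(s2$spectra))
  expect_identical(s1$markers, s2$markers)
  s3 <- generateStudy(defaultSimConfig(seed = 6))
  expect_identical(s3$markers$sample_id, s1$markers$sample_id)
  expect_false(identical(s3$markers$pv, s1$markers$pv))
})

test_that("totox is computed exactly, never sampled", {
  study <- generateStudy(defaultSimConfig(seed = 7))
  expect_identical(study$markers$totox,
                   2 * study$markers$pv + study$markers$anv)
})

test_that("without noise, markers increase strictly with duration and frying dominates", {
  sim <- simulateMarkers(config = zero_noise_config())
  mk <- sim$markers
  meta <- sim$meta
  ol <- meta$class == "olive"  # aligned by category within each treatment
  for (m in setdiff(markerNames(), "totox")) {
    e1 <- mk[[m]][ol & meta$treatment == "E1"]  # 170 C, 3 h
    e2 <- mk[[m]][ol & meta$treatment == "E2"]  # 170 C, 6 h
    e3 <- mk[[m]][ol & meta$treatment == "E3"]  # 210 C, 3 h
    e4 <- mk[[m]][ol & meta$treatment == "E4"]  # 210 C, 6 h
    expect_true(all(e2 > e1) && all(e4 > e3))   # duration at fixed temperature
    expect_true(all(e3 > e1) && all(e4 > e2))   # temperature at fixed duration
    expect_true(all(e1 > mk[[m]][ol & meta$treatment == "C1"]))
  }
})

test_that("supplementation attenuates and suppl_factor = 1 collapses the groups", {
  sim <- simulateMarkers(config = zero_noise_config())
  ol <- sim$meta$class == "olive"  # supplementation exists only for olive
  for (m in markerNames()) {
    uns <- sim$markers[[m]][ol & sim$meta$treatment %in% paste0("E", 1:4)]
    sup <- sim$markers[[m]][ol & sim$meta$treatment %in% paste0("E", 5:8)]
    expect_true(all(sup < uns))
  }
  cfg <- zero_noise_config()
  cfg$suppl_factor <- 1
  sim1 <- simulateMarkers(config = cfg)
  expect_equal(sim1$markers$pv[ol & sim1$meta$treatment == "E5"],
               sim1$markers$pv[ol & sim1$meta$treatment == "E1"])
})

test_that("stressed group means exceed controls for every marker", {
  for (seed in 1:5) {
    sim <- simulateMarkers(config = defaultSimConfig(seed))
    ctrl <- sim$meta$treatment %in% c("C1", "C2", "S", "C")
    e4 <- sim$meta$treatment == "E4"
    uns <- sim$meta$treatment %in% paste0("E", 1:4)
    sup <- sim$meta$treatment %in% paste0("E", 5:8)
    for (m in markerNames()) {
      expect_gt(mean(sim$markers[[m]][e4]), mean(sim$markers[[m]][ctrl]))
      expect_gt(mean(sim$markers[[m]][uns]), mean(sim$markers[[m]][sup]))
    }
  }
})

test_that("simulated markers stay within realistic trade envelopes", {
  for (seed in 1:3) {
    mk <- simulateMarkers(config = defaultSimConfig(seed))$markers
    expect_true(all(mk$k232 > 0.7 & mk$k232 < 6))
    expect_true(all(mk$k270 < 3.5))
    expect_true(all(mk$delta_k > 0 & mk$delta_k < 0.45))
    expect_true(all(mk$pv < 40))
    expect_true(all(mk$anv < 95))
    expect_true(all(mk$acidity > 0.05 & mk$acidity < 1.8))
    # controls sit near trade base levels
    ctrl <- simulateMarkers(config = defaultSimConfig(seed))$meta$treatment %in%
      c("C1", "C2", "S", "C")
    expect_true(all(mk$pv[ctrl] > 3 & mk$pv[ctrl] < 13))
    expect_true(all(mk$anv[ctrl] < 6))
  }
})

test_that("with zero slopes and zero noise every spectrum equals its category baseline", {
  cfg <- zero_noise_config()
  cfg$band_table$slope <- 0
  sim <- simulateMarkers(config = cfg)
  sp <- simulateSpectra(sim, config = cfg)
  A <- absorbances(sp)
  ids <- sampleIds(sp)
  # replicates identical, and identical across samples of the same category
  meta <- sim$meta[match(ids, sim$meta$sample_id), ]
  for (categ in c("PC", "SOHO")) {
    rows <- A[meta$category == categ, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }
})

test_that("the baseline is positive and anchored near the printed envelopes", {
  cfg <- zero_noise_config()
  cfg$band_table$slope <- 0
  sim <- simulateMarkers(config = cfg)
  A <- absorbances(simulateSpectra(sim, config = cfg))
  nm <- wavelengths(nirGrid())
  expect_true(all(A > 0))
  expect_true(all(A[, nm == 1392] > 0.37 & A[, nm == 1392] < 0.42))
  expect_true(all(A[, nm == 2114] > 1.07 & A[, nm == 2114] < 1.14))
})

test_that("band signs reproduce the observed absorbance-marker directions", {
  study <- generateStudy(defaultSimConfig(seed = 11))
  A <- absorbances(averageReplicates(study$spectra))
  nm <- wavelengths(nirGrid())
  mk <- study$markers
  expect_lt(cor(A[, nm == 1392], mk$k232), 0)   # falls as K232 rises
  expect_gt(cor(A[, nm == 2114], mk$k270), 0)   # rises with K270
  expect_lt(cor(A[, nm == 1792], mk$acidity), 0)
  expect_gt(cor(A[, nm == 1970], mk$anv), 0)
})

test_that("replicate averaging cuts noise variance by about the replicate count", {
  cfg <- defaultSimConfig(seed = 12)
  noisefree_cfg <- cfg
  noisefree_cfg$replicate_noise_sd <- 0
  sim <- simulateMarkers(config = cfg)
  noisy <- simulateSpectra(sim, config = cfg)
  clean <- simulateSpectra(sim, config = noisefree_cfg)
  eps_single <- absorbances(noisy) - absorbances(clean)[, , drop = FALSE]
  eps_avg <- absorbances(averageReplicates(noisy)) -
    absorbances(averageReplicates(clean))
  ratio <- var(as.numeric(eps_avg)) / var(as.numeric(eps_single))
  expect_equal(ratio, 1 / 3, tolerance = 0.05)
})

test_that("invalid configurations and off-grid band centers are rejected", {
  cfg <- defaultSimConfig()
  cfg$suppl_factor <- 1.5
  expect_error(simulateMarkers(config = cfg), "suppl_factor")
  cfg2 <- defaultSimConfig()
  cfg2$band_table$center_nm[1] <- 1793
  sim <- simulateMarkers(config = defaultSimConfig())
  expect_error(simulateSpectra(sim, config = cfg2), "not on the grid")
  cfg3 <- defaultSimConfig()
  cfg3$replicate_noise_sd <- -1
  expect_error(simulateMarkers(config = cfg3), "non-negative")
})

test_that("a generated study round-trips through CSV into pipeline-ready inputs", {
  study <- generateStudy(defaultSimConfig(seed = 13))
  d <- withr::local_tempdir()
  writeSpectra(study$spectra, file.path(d, "spectra.csv"))
  writeMarkerTable(study$markers, file.path(d, "markers.csv"))
  writeSampleMeta(study$meta, file.path(d, "meta.csv"))
  sp <- readSpectra(file.path(d, "spectra.csv"))
  mk <- readMarkerTable(file.path(d, "markers.csv"))
  expect_equal(ncol(sp), 426L)
  expect_equal(absorbances(sp), absorbances(study$spectra),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(mk$totox, study$markers$totox, tolerance = 1e-9)
})
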