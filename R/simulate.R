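#' Default deep-frying study design
#'
#' Fourteen oil categories: twelve olive-oil categories (nine extra-virgin
#' cultivars, a pomace-oil blend and two refined blends), each with eleven
#' samples -- controls C1 (untreated), C2 (polyphenol-enriched blend) and S
#' (supplemented control) plus frying treatments E1--E8 -- and two sunflower
#' categories (SO, high-oleic SOHO) with five samples each (control C plus
#' E1--E4). Treatments cross temperature and duration: E1 = (170 C, 3 h),
#' E2 = (170 C, 6 h), E3 = (210 C, 3 h), E4 = (210 C, 6 h); E5--E8 repeat
#' the grid with polyphenol supplementation. Total: 12 x 11 + 2 x 5 = 142
#' samples, 426 spectra in triplicate.
#'
#' Each category carries a relative \code{stability} scalar (larger = faster
#' oxidation; regular sunflower oil degrades fastest, high-oleic sunflower
#' and the most stable cultivars slowest) and a \code{base_factor} scaling
#' its control-level marker values.
#'
#' @return list with \code{categories} (data.frame: category, class,
#'   stability, base_factor) and \code{treatments} (data.frame: treatment,
#'   class, temperature_C, duration_h, supplemented)
#' @export
defaultDesign <- function() {
  categories <- data.frame(
    category = c("PC", "CC", "EP", "AQ", "HB", "MZ", "RY", "OJ", "KN", "AS",
                 "O1", "O04", "SO", "SOHO"),
    class = c(rep("olive", 12), "sunflower", "sunflower"),
    stability = c(1.10, 1.00, 0.70, 0.90, 1.40, 1.00, 1.00, 1.10, 0.95, 0.75,
                  1.30, 1.20, 1.35, 0.60),
    base_factor = c(1.00, 0.95, 0.90, 1.00, 1.10, 1.05, 1.00, 1.15, 0.95,
                    0.90, 1.20, 1.15, 1.00, 0.60))
  grid4 <- data.frame(code = paste0("E", 1:4),
                      temperature_C = c(170, 170, 210, 210),
                      duration_h = c(3, 6, 3, 6))
  olive <- rbind(
    data.frame(treatment = c("C1", "C2", "S"), temperature_C = NA_real_,
               duration_h = NA_real_, supplemented = c(FALSE, TRUE, TRUE)),
    data.frame(treatment = grid4$code, temperature_C = grid4$temperature_C,
               duration_h = grid4$duration_h, supplemented = FALSE),
    data.frame(treatment = paste0("E", 5:8), temperature_C = grid4$temperature_C,
               duration_h = grid4$duration_h, supplemented = TRUE))
  sun <- rbind(
    data.frame(treatment = "C", temperature_C = NA_real_,
               duration_h = NA_real_, supplemented = FALSE),
    data.frame(treatment = grid4$code, temperature_C = grid4$temperature_C,
               duration_h = grid4$duration_h, supplemented = FALSE))
  treatments <- rbind(cbind(class = "olive", olive),
                      cbind(class = "sunflower", sun))
  list(categories = categories, treatments = treatments)
}

#' Expand a design into one row per sample
#'
#' @param design a design from [defaultDesign()]
#' @return sample metadata data.frame (sample_id = category_treatment,
#'   category, class, treatment, temperature_C, duration_h, supplemented)
#' @export
designSamples <- function(design = defaultDesign()) {
  out <- do.call(rbind, lapply(seq_len(nrow(design$categories)), function(i) {
    cat_ <- design$categories[i, ]
    tr <- design$treatments[design$treatments$class == cat_$class, ]
    data.frame(sample_id = paste(cat_$category, tr$treatment, sep = "_"),
               category = cat_$category, class = cat_$class,
               treatment = tr$treatment, temperature_C = tr$temperature_C,
               duration_h = tr$duration_h, supplemented = tr$supplemented)
  }))
  rownames(out) <- NULL
  out
}

#' Default simulation configuration
#'
#' All tunables of the synthetic study in one list. Control-level marker
#' bases and growth amplitudes are calibrated so that simulated markers fall
#' in realistic ranges: peroxide value ~7-10 meq O2/kg for controls (lower
#' for high-oleic sunflower) rising above 20 under the harshest frying,
#' anisidine value from ~2-4 up to ~67, K232 within ~1.3-4.7, K270 up to
#' ~2.7, delta-K up to ~0.32, acidity 0.1-1.2 % oleic. The marker growth law
#' is \code{g(T, t) = 1 + amp * stability * ((T - 160)/50)^temp_exponent *
#' (t/6)^time_exponent} (g = 1 for controls), multiplied by
#' \code{suppl_factor} for supplemented treatments E5-E8 and by lognormal
#' noise \code{exp(N(0, marker_noise_sd^2))}.
#'
#' Spectra are a smooth positive category baseline (quadratic through the
#' \code{baseline_anchors}, which pin absorbance near 1392 nm to ~0.38-0.41
#' and near 2114 nm to ~1.08-1.13) plus marker-linked Gaussian bands and
#' i.i.d. replicate noise. Band signs encode the observed directions:
#' absorbance falls with rising acidity at 1792 nm and with rising K232 at
#' 1392 nm, and rises with K270 at 2114 nm, with delta-K at 2118 nm and with
#' anisidine value at 1970 nm (minor anisidine bands at 2254 and 2362 nm).
#' The peroxide band sits at 1376 nm with negative slope. The 12 nm band
#' width spreads each marker's signal over several neighboring 2 nm channels,
#' creating the collinearity that stepwise decorrelation is designed to
#' handle.
#'
#' Randomness: all draws derive from the single root \code{seed} through a
#' fixed stream-splitting scheme -- marker noise uses \code{seed}, spectral
#' noise uses \code{seed + 1} -- so each module rerun is reproducible on its
#' own.
#'
#' @param seed integer root seed
#' @return a named list (class \code{"SimConfig"})
#' @export
defaultSimConfig <- function(seed = 1L) {
  mk <- markerNames()
  cfg <- list(
    seed = as.integer(seed),
    marker_base = list(
      olive = c(acidity = 0.30, k232 = 1.50, k270 = 0.16, delta_k = 0.012,
                pv = 8.5, anv = 3.0),
      sunflower = c(acidity = 0.12, k232 = 1.60, k270 = 0.22, delta_k = 0.015,
                    pv = 8.0, anv = 3.5)),
    growth_amp = c(acidity = 2.0, k232 = 1.3, k270 = 8, delta_k = 16,
                   pv = 1.4, anv = 14),
    temp_exponent = 0.5,
    time_exponent = 0.7,
    suppl_factor = 0.6,
    marker_noise_sd = c(acidity = 0.08, k232 = 0.08, k270 = 0.08,
                        delta_k = 0.08, pv = 0.08, anv = 0.08),
    band_table = data.frame(
      center_nm = c(1792, 1376, 1392, 2114, 2118, 1970, 2254, 2362),
      width_nm = 12,
      marker = c("acidity", "pv", "k232", "k270", "delta_k", "anv", "anv",
                 "anv"),
      slope = c(-0.05, -0.0015, -0.008, 0.018, 0.08, 8e-4, 3e-4, 2.5e-4)),
    baseline_anchors = data.frame(nm = c(1100, 1392, 2114),
                                  absorbance = c(0.32, 0.395, 1.105)),
    baseline_category_scale = 0.01,
    replicate_noise_sd = 0.005,
    n_replicates = 3L)
  stopifnot(all(names(cfg$growth_amp) == setdiff(mk, "totox")))
  class(cfg) <- "SimConfig"
  cfg
}

validateSimConfig <- function(config) {
  if (!is.list(config)) stop("config must be a SimConfig list")
  if (config$suppl_factor <= 0 || config$suppl_factor > 1)
    stop("'suppl_factor' must lie in (0, 1]")
  if (any(config$marker_noise_sd < 0) || config$replicate_noise_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (config$n_replicates < 1L) stop("'n_replicates' must be at least 1")
  invisible(config)
}

growth_factor <- function(config, stability, temperature_C, duration_h, amp) {
  ifelse(is.na(temperature_C), 1,
         1 + amp * stability *
           ((temperature_C - 160) / 50)^config$temp_exponent *
           (duration_h / 6)^config$time_exponent)
}

#' Simulate per-sample oxidation markers
#'
#' For sample s and marker m:
#' \code{m_s = base_m(category) * g(T, t) * s(supplemented) * exp(eps)},
#' with lognormal noise \code{eps ~ N(0, marker_noise_sd_m^2)};
#' \code{s = suppl_factor} for treatments E5--E8, otherwise 1. The
#' \code{totox} column is always computed exactly as \code{2 * pv + anv},
#' never sampled.
#'
#' @param design a design from [defaultDesign()]
#' @param config a \code{SimConfig} from [defaultSimConfig()]
#' @return list with \code{markers} (a valid marker table), \code{meta}
#'   (sample metadata) and \code{truth} (noise-free marker matrix plus the
#'   latent growth factors)
#' @export
simulateMarkers <- function(design = defaultDesign(),
                            config = defaultSimConfig()) {
  validateSimConfig(config)
  set.seed(config$seed)
  meta <- designSamples(design)
  cat_tab <- design$categories[match(meta$category, design$categories$category), ]
  mk <- setdiff(markerNames(), "totox")
  noisefree <- noisy <- matrix(0, nrow(meta), length(mk),
                               dimnames = list(meta$sample_id, mk))
  for (m in mk) {
    base <- vapply(seq_len(nrow(meta)),
                   function(i) config$marker_base[[meta$class[i]]][[m]], 0) *
      cat_tab$base_factor
    g <- growth_factor(config, cat_tab$stability, meta$temperature_C,
                       meta$duration_h, config$growth_amp[[m]])
    s <- ifelse(meta$treatment %in% paste0("E", 5:8), config$suppl_factor, 1)
    noisefree[, m] <- base * g * s
    noisy[, m] <- noisefree[, m] *
      exp(rnorm(nrow(meta), 0, config$marker_noise_sd[[m]]))
  }
  markers <- data.frame(sample_id = meta$sample_id, noisy)
  markers$totox <- totox(markers$pv, markers$anv)
  validateMarkerTable(markers)
  truth_markers <- cbind(noisefree,
                         totox = 2 * noisefree[, "pv"] + noisefree[, "anv"])
  list(markers = markers, meta = meta,
       truth = list(noisefree = truth_markers))
}

baseline_curve <- function(config, nm) {
  a <- config$baseline_anchors
  if (nrow(a) != 3L) stop("baseline_anchors must contain exactly 3 anchor points")
  u <- (nm - a$nm[1]) / 1000
  ua <- (a$nm - a$nm[1]) / 1000
  cf <- solve(cbind(1, ua, ua^2), a$absorbance)
  as.numeric(cf[1] + cf[2] * u + cf[3] * u^2)
}

#' Simulate NIR spectra from a marker table
#'
#' Forward model per replicate spectrum:
#' \deqn{A(l) = baseline_{cat}(l) + \sum_b slope_b (m_b - median(m_b))
#'   e^{-(l - center_b)^2 / (2 width_b^2)} + N(0, replicate\_noise\_sd^2)}
#' The baseline is a smooth positive quadratic through the configured anchor
#' points, shifted slightly per category; every band center must lie on the
#' grid.
#'
#' @param sim output of [simulateMarkers()] (markers + meta)
#' @param design the design the markers were generated from
#' @param config the same \code{SimConfig}
#' @param grid target \linkS4class{WavelengthGrid}
#' @return a \linkS4class{SpectraSet} with
#'   \code{n_replicates x nrow(markers)} spectra
#' @export
simulateSpectra <- function(sim, design = defaultDesign(),
                            config = defaultSimConfig(), grid = nirGrid()) {
  validateSimConfig(config)
  set.seed(config$seed + 1L)
  markers <- sim$markers; meta <- sim$meta
  nm <- wavelengths(grid)
  bt <- config$band_table
  wavelengthToIndex(bt$center_nm, grid)  # errors if any center is off-grid
  base <- baseline_curve(config, nm)
  cat_tab <- design$categories[match(meta$category, design$categories$category), ]
  offset <- config$baseline_category_scale * (cat_tab$base_factor - 1)

  shapes <- vapply(seq_len(nrow(bt)),
                   function(b) exp(-(nm - bt$center_nm[b])^2 /
                                     (2 * bt$width_nm[b]^2)),
                   numeric(length(nm)))
  centered <- vapply(seq_len(nrow(bt)), function(b) {
    m <- markers[[bt$marker[b]]]
    bt$slope[b] * (m - median(m))
  }, numeric(nrow(markers)))
  signal <- sweep(centered %*% t(shapes), 2, base, "+") + offset

  nrep <- config$n_replicates
  n <- nrow(markers)
  A <- signal[rep(seq_len(n), each = nrep), , drop = FALSE] +
    matrix(rnorm(n * nrep * length(nm), 0, config$replicate_noise_sd),
           n * nrep, length(nm))
  SpectraSet(A, rep(markers$sample_id, each = nrep),
             rep(seq_len(nrep), times = n), grid = grid,
             meta = meta[rep(seq_len(n), each = nrep),
                         c("category", "class", "treatment", "temperature_C",
                           "duration_h", "supplemented")])
}

#' Generate a complete synthetic study
#'
#' Composes [defaultDesign()], [simulateMarkers()] and [simulateSpectra()]
#' into a pipeline-ready study: spectra in triplicate, the marker table,
#' sample metadata and a truth record holding every latent quantity needed
#' for parameter-recovery evaluation (noise-free markers, the band table and
#' each marker's strongest generating band -- for the derived TOTOX index
#' this is the anisidine band at 1970 nm, which dominates its variance).
#'
#' @param config a \code{SimConfig}; [defaultSimConfig()] reproduces the
#'   142-sample / 426-spectrum study layout
#' @param design study design
#' @param grid wavelength grid
#' @return list with \code{spectra} (\linkS4class{SpectraSet}),
#'   \code{markers}, \code{meta} and \code{truth}
#' @export
generateStudy <- function(config = defaultSimConfig(),
                          design = defaultDesign(), grid = nirGrid()) {
  sim <- simulateMarkers(design, config)
  spectra <- simulateSpectra(sim, design, config, grid)
  bt <- config$band_table
  strongest <- vapply(setdiff(markerNames(), "totox"), function(m) {
    rows <- bt[bt$marker == m, ]
    rows$center_nm[which.max(abs(rows$slope) * sd(sim$markers[[m]]))]
  }, 0)
  strongest["totox"] <- strongest[["anv"]]
  list(spectra = spectra, markers = sim$markers, meta = sim$meta,
       truth = list(noisefree = sim$truth$noisefree, band_table = bt,
                    primary_band_nm = strongest, config = config))
}
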