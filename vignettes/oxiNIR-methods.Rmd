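---
title: "Methods: SELECT-OLS calibration of lipid-oxidation markers from NIR spectra"
author: "oxiNIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SELECT-OLS calibration of lipid-oxidation markers from NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxiNIR)
```

## The problem

Frying oils degrade by lipid oxidation. Routine quality control tracks that
degradation with wet-chemistry markers: free acidity (% oleic acid), the
specific UV extinctions K232 and K270 (conjugated dienes and trienes),
delta-K (the deviation of K270 from the straight line through its 266/274 nm
neighbors), peroxide value PV (meq O2/kg, primary oxidation), p-anisidine
value AnV (aldehydes, secondary oxidation) and the composite index
TOTOX = 2 PV + AnV. These assays are slow and consume reagents.
Near-infrared (NIR) absorbance spectra, by contrast, are acquired in
seconds, and oxidation chemistry leaves signatures in the C-H and O-H
overtone and combination bands. `oxiNIR` builds multivariate calibrations
that predict each marker from a spectrum on a fixed 1100--2498 nm grid
(2 nm step, 700 channels), where a predictor index *i* denotes the channel
at `1100 + 2*(i - 1)` nm.

## The SELECT algorithm

Neighboring NIR channels are almost perfectly collinear, which makes
full-spectrum ordinary least squares ill-posed and uninterpretable. SELECT
(stepwise decorrelation of variables) addresses this by greedy selection
with explicit orthogonalization. Working on the column-autoscaled predictor
matrix $X$ and centered response $y$:

1. compute the Pearson correlation $r_k$ of every unselected channel with
   the current (deflated) response;
2. select $k^* = \arg\max_k |r_k|$, breaking ties toward the smaller index,
   and record $|r_{k^*}|$ as the step's *weight*;
3. deflate every remaining channel $v$ and the response against the pivot
   $u$: $v \leftarrow v - \frac{\langle v, u\rangle}{\langle u,
   u\rangle}u$;
4. repeat until `k_max` steps, or $\max_k |r_k| <$ `r_min`, or the residual
   response variance falls below `tol_var` times its initial value.

The deflation is sequential Gram-Schmidt: after step $t$ all remaining
channels and the response are numerically orthogonal to every pivot, so an
exact duplicate of a selected channel can never be selected again, and each
new step contributes only information not already captured. The weight is
the absolute *partial* correlation at the moment of selection; it need not
decrease with step order, because a suppressor channel (one correlated with
noise in an earlier pivot rather than with the response) can become highly
informative only once that pivot has been projected out.

Defaults: `k_max = 30`, `r_min = 0.05`, `tol_var = 1e-6`. Published report
tables of this workflow span 16--30 selected wavelengths with late-step
weights down to 0.05--0.06, and the defaults bracket exactly that range.
Inputs with fewer than 3 rows are refused outright.

## OLS refit, autoscaling and prediction

The final model is refit by ordinary least squares **on the original
autoscaled columns** of the selected channels, not on the deflated copies.
The giveaway is in published coefficient tables: adjacent, strongly
collinear wavelengths carry huge coefficients of opposite sign (e.g. a
+1112 next to a -708 two channels away), the signature of
correlated-predictor OLS. Orthogonalized regressors would not show it.
Coefficient magnitudes are therefore not interpretable individually;
predictions are, and the package's stability test perturbs collinear
columns and asserts stable predictions rather than stable coefficients.

Autoscaling is per-column mean-centering and division by the sample
standard deviation (denominator $n-1$, the chemometrics convention; the
choice is invisible to selection order, which is scale-free, but fixes the
coefficient scale). Only the predictors are scaled: report intercepts of
the reference models sit on the response's natural scale (the acidity
intercept 0.39 lies inside the acidity range), which is what raw-response
fitting produces. Channels with standard deviation below
`1e-12 * (|mean| + 1)` are flagged rather than dropped, and selection skips
them; synthetic baselines can be locally flat and a hard error would be
hostile. The fitted `ScalingParams` travel with the model so it applies to
raw spectra; `coefficientsRaw()` folds the scaling into the coefficients
(`b/s`, intercept minus `sum(b*m/s)`) for instrument-side deployment.

The solver is base R's QR least squares (`lm.fit`); explicit
normal-equations inversion appears only as an independent test oracle,
because the selected channels are routinely collinear enough to make
$X^\top X$ ill-conditioned.

## Validation statistics

The seven report statistics per model are: calibration residual SD
$\sqrt{SS_{res}/(n-p-1)}$, mean absolute calibration error, multiple
correlation coefficient $R$ (reported as 0 with a flag for a degenerate
constant fit), and from leave-one-out cross-validation with
$d_i = y_i - \hat y_{(-i),i}$ and $PRESS = \sum d_i^2$: residual variance
$100 \cdot PRESS / SS_{tot}$, explained variance (its exact complement to
100, reported unclipped -- negative values are informative, they mean the
model predicts worse than the mean), residual SD
$\sqrt{PRESS/(n-p-1)}$ (the $n$ denominator is available behind
`loo_sd_denom = "n"`; the $n-p-1$ form mirrors the calibration SD) and mean
absolute prediction error.

Two LOO modes exist. `"refit"` re-estimates the autoscaling inside every
fold, so nothing about the held-out row leaks into preprocessing;
`"fixed"` scales once and uses the exact hat-matrix identity
$d_i = e_i/(1-h_{ii})$. Because OLS predictions with an intercept are
invariant to per-column affine rescaling of the predictors, the two modes
agree to numerical precision on full-rank designs -- the tests assert this
-- and `chooseModelSize()` therefore defaults to the hat-matrix path, which
turns the model-size search over nested prefixes of the selection trace
(smallest `k` at the minimal LOO mean prediction error) from $O(n)$ refits
per size into one QR per size.

Model-size choice by cross-validation argmin never drops true signal but
overselects by a spurious channel or two with non-vanishing probability;
that is a property of CV argmin itself, not of this implementation, and the
test suite asserts the mode-at-truth behavior rather than certainty.

## What the LOO statistics do and do not validate

One limitation deserves emphasis: wavelengths are selected **once, on all
samples**, and LOO then refits only the coefficients. The reported LOO
statistics therefore validate the coefficients given the wavelength set,
not the selection itself. With 700 candidate channels and ~142 samples,
the greedy argmax can capitalize on chance: rerunning the entire selection
on a response permuted to destroy any real association still yields a
substantially positive apparent LOO explained variance (a named test pins
this, and `scripts/acceptance.R` reports both numbers). The leakage-free
negative control holds the selected wavelength set fixed and permutes the
response; its LOO explained variance is at or below zero, as it should be.
Users comparing markers or instruments should rely on the fixed-set
permutation control, or on selection-frequency screening across validation
cycles, before reading predictive power into a LOO figure.

## The synthetic study generator

The generator emulates a deep-frying study: 12 olive-oil categories x 11
treatments (controls C1, C2, S; fryings E1--E8) plus 2 sunflower
categories x 5 treatments (control C; fryings E1--E4) = 142 samples,
measured in triplicate = 426 spectra. E1--E4 cross 170/210 degrees C with
3/6 h; E5--E8 repeat the grid with polyphenol supplementation. Markers
follow
$$m_s = \mathrm{base}_m(\mathrm{category}) \cdot
  \left(1 + a_m \,\sigma_{\mathrm{cat}}
  \left(\tfrac{T-160}{50}\right)^{0.5}
  \left(\tfrac{t}{6}\right)^{0.7}\right) \cdot s \cdot e^{\varepsilon},$$
with $s = 0.6$ for supplemented fryings and 1 otherwise,
$\varepsilon \sim N(0, 0.08^2)$, and per-category stability
$\sigma_{\mathrm{cat}}$ (regular sunflower oil fastest, high-oleic
sunflower and the most stable cultivars slowest). Any monotone growth law
satisfying the observed orderings (hotter/longer worse, supplementation
protective, 210 degrees C/6 h worst) would do; the power law is simply the
plainest such choice. Base levels and amplitudes are calibrated to trade
envelopes: control PV ~7--10 meq O2/kg (high-oleic sunflower lower),
stressed PV above 20; AnV from ~2--4 up to ~67; K232 ~1.3--4.7; K270 up to
~2.7; delta-K up to ~0.32. Acidity (0.1--1.2 % oleic) is an invented
range -- plausible trade values, not anchored to any published number.
TOTOX is always computed exactly as 2 PV + AnV, never sampled.

Spectra are a smooth positive quadratic baseline (anchored so absorbance
near 1392 nm sits in ~0.38--0.41 and near 2114 nm in ~1.08--1.13, with a
small per-category offset) plus marker-linked Gaussian bands (sd 12 nm,
wide enough to smear each signal over several 2 nm channels and create the
collinearity SELECT exists to handle) plus i.i.d. replicate noise
(sd 0.005 AU). Band signs encode the observed directions: absorbance falls
with acidity at 1792 nm and with K232 at 1392 nm, rises with K270 at
2114 nm, delta-K at 2118 nm and AnV at 1970 nm (minor AnV bands at 2254
and 2362 nm); PV gets a 1376 nm band with negative slope, matching the
first-selected wavelength of the published PV model. TOTOX has no band of
its own -- it is derived -- and its recovery target is the AnV band at
1970 nm, which dominates its variance.

All randomness derives from one root seed through a fixed split: marker
noise uses `seed`, spectral noise `seed + 1`, so each stage reruns
reproducibly on its own.

### What the generator does not emulate

Three honest gaps. First, the spectra are an exact function of the
*measured* marker values plus channel noise; real reference assays carry
their own error that the spectrum cannot see. Consequently synthetic LOO
explained variances run in the high 90s rather than the 72--94% of
published models on real oils -- passing recovery tests shows the pipeline
finds the right wavelengths and calibrates accurately under the generative
assumptions, not that real-data error levels are reproduced. Second, with
marker noise switched off all seven markers collapse onto a single latent
stress factor (pairwise correlations 0.99+), making their bands
statistically interchangeable; the marker noise is what identifies each
band, so "noise-free" recovery tests zero only the instrument noise.
Third, no physical radiative transfer: no scattering, no temperature band
shifts, no heteroscedastic instrument noise.

## Problem sizes used by the test suite

Unit oracles run on small random instances (n = 20--200, p = 4--12;
selection equivalence on 50 instances of 30 x 8). Recovery runs the full
142-sample, 426-spectrum study end to end over 20 seeds; replicate
averaging to one spectrum per sample is the default training path (the
triplicate-means policy of conventional assays, applied to spectra for
symmetry), with an `"individual"` mode training on all 426 spectra. These
sizes were chosen to exercise every code path at the study's native scale.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates a study at the
given seed, runs the full pipeline for all seven markers and writes design
counts, reference-report consistency counts, per-marker calibration R, LOO
explained variance, model size and band-recovery distance, the TOTOX
identity deviation, the minimum marker correlation and both permutation
controls as a flat JSON object.
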