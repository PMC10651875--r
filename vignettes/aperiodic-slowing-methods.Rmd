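---
title: "Methods: separating aperiodic activity from oscillations in EEG slowing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating aperiodic activity from oscillations in EEG slowing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specslow)
```

## The question

Resting-state EEG recorded after convulsive therapy (ECT or MST) looks
"slower": low-frequency band power rises. Two very different physiological
stories produce that observation:

1. **Oscillatory slowing** — delta/theta oscillations grow or newly emerge,
   adding narrow-band bumps to the spectrum.
2. **Broadband aperiodic change** — the 1/f-like background steepens (the
   aperiodic exponent increases), which raises low-frequency power and
   lowers high-frequency power with no oscillation involved.

Canonical band power integrates both contributions and cannot tell them
apart. This package implements the spectral-parameterization workflow that
can: every spectrum is decomposed into an aperiodic component plus Gaussian
peaks, and all downstream statistics are run on the separated quantities.

## Spectral model

In log10 power, a spectrum over frequencies $f$ is modeled as

$$ L(f) = b - \chi \log_{10} f + \sum_{k} h_k
   \exp\!\left(-\frac{(f - c_k)^2}{2 w_k^2}\right) $$

with offset $b$, aperiodic exponent $\chi$ (no knee; appropriate for the
0.5–30 Hz fit range used throughout), and peaks with center $c_k$ (Hz),
height $h_k$ (log10 units above the aperiodic component), and width $w_k$.
`spectrum_spec()` builds ground-truth parameterizations;
`spectrum_model_log10()` and `make_spectrum()` evaluate them.

## Estimation

`fit_spectrum()` follows the standard parameterization recipe:

* a robust initial aperiodic fit (OLS on log-log axes, refit on the bins
  whose flattened residual is at or below the 60th percentile, so peaks do
  not bias the slope);
* iterative peak extraction from the flattened spectrum — the largest
  residual seeds a bounded single-Gaussian fit which is subtracted, until
  the maximum residual falls below `max(peak_threshold, 2 sd)`;
* joint re-optimization of all Gaussians (L-BFGS-B with analytic
  gradients), alternated with aperiodic re-fits on the peak-subtracted
  spectrum;
* a final OLS aperiodic pass and $R^2$ against the observed log spectrum.

Defaults in `fit_settings()` follow common spectral-parameterization
conventions for resting-state EEG: fit range 0.5–30 Hz, peak threshold 0.05 log10 units, at most 12
peaks, Gaussian sd bounded to [0.5, 4] Hz (bandwidth 1–8 Hz). Electrodes
with $R^2 < 0.8$ at either timepoint are excluded *as pairs* by
`quality_filter()`, so pre/post comparisons always use the same montage per
patient.

Two numerical choices matter for speed and stability. The optimizer
receives analytic gradients (the Gaussian-sum Jacobian is cheap and exact),
making a full 0.5–30 Hz fit take ~20 ms. And peak parameters are bounded
rather than penalized, so degenerate zero-width or out-of-range peaks
cannot occur; peaks whose refit height falls at or below the threshold are
dropped.

## Features

For each patient and timepoint (`patient_features()`):

* **exponent** and **offset** — electrode averages of the aperiodic fit;
* **band power** — mean log10 power over delta (1–4 Hz), theta (4–7 Hz),
  alpha (7–12 Hz), inclusive of both edges (the "canonical" measure);
* **oscillation power** — height of the tallest fitted in-band peak,
  averaged over the electrodes that have one. Electrodes without a peak are
  *not* imputed as zeros; a patient without any peak-bearing electrode gets
  `NA`, and paired oscillation-power tests use only patients with a peak at
  both timepoints (the only patients for whom the comparison is defined);
* **abundance** — the fraction of retained electrodes exhibiting an
  in-band peak, which captures emergence: an oscillation that appears only
  after treatment moves abundance from 0 upward even though paired
  oscillation power is undefined.

Band membership of a peak is decided by its center using half-open
intervals `[lo, hi)` except alpha, which closes at 12 Hz. Change scores are
`pre - post` throughout, so a post-treatment increase appears as a negative
difference.

## Statistics

`paired_test()` gates on Shapiro–Wilk normality of the differences
(p ≥ 0.05 → paired t with Cohen's $d_z$; otherwise Wilcoxon signed-rank
with Cliff's $\delta$). The Wilcoxon statistic is W = the smaller of the
two signed-rank sums, with zeros dropped; p is exact (signed-rank
distribution) for n ≤ 25 without ties and a tie-corrected normal
approximation with continuity correction otherwise. Cliff's $\delta$ is
computed by sorted counting but is exactly the $O(n^2)$ definition; both
statistics are tested against brute-force oracles.

`eeg_feature_tests()` runs the eight-test family (exponent, delta band
power, delta/theta/alpha oscillation power and abundance) and applies the
Holm–Bonferroni step-down correction (`holm_bonferroni()`), whose rank-k
threshold is $\alpha / (m - k + 1)$ — e.g. 0.00625 … 0.05 for m = 8.

`band_power_regression()` asks what drives band-power change: band power
difference regressed on exponent, abundance, and oscillation-power
differences (all z-scored), Holm-corrected within the three main effects
(rank-1 threshold 0.0167).

`hc3_ols()` implements OLS with the HC3 sandwich covariance
$(X'X)^{-1} X' \mathrm{diag}(e_i^2/(1-h_{ii})^2) X (X'X)^{-1}$, the
recommended heteroskedasticity-consistent estimator for small samples; it
is validated against both a hand-computed toy design and an independent
reference implementation.

`exhaustive_outcome_search()` models normalized post-treatment HAM-D
(17-item scores divided by 52, 24-item by 76, via `normalize_hamd()`) on
two always-included fixed effects — normalized baseline HAM-D and treatment
type — plus candidates chosen by adjusted $R^2$. The default searches
single candidates only (`max_features = 1`): with seven candidates and
n = 33, larger subsets almost always add a spurious regressor that inflates
adjusted $R^2$, and outcome models in this literature typically carry
exactly one searched EEG effect (three predictors total). Set
`max_features` higher to search subsets.

## The synthetic cohort generator

No raw patient data are available, so validation uses `make_cohort()`,
whose defaults are fixed a priori at realistic study conditions and were
not tuned afterwards:

* 22 patients, 62 electrodes, spectra on 0.5–30 Hz at 0.25 Hz resolution;
* baseline exponent $\mathcal{N}(0.88, 0.21^2)$ for the ECT preset
  ($\mathcal{N}(0.98, 0.18^2)$ for MST) with per-electrode jitter 0.03;
* a post-treatment exponent shift $\mathcal{N}(0.37, 0.18^2)$ (ECT; 0.16 ±
  0.20 for MST) applied as a rotation about 20 Hz, so the offset co-varies
  with the shift the way a pivoted steepening requires;
* per-band peak presets (`band_peak_defaults()`): emergence probabilities
  and heights that increase for delta/theta and decrease slightly for
  alpha after treatment;
* log-normal observation noise (sd 0.05 log10 units) on each spectrum;
* HAM-D scores whose post value depends on baseline severity, a treatment
  effect, and (configurably) the baseline exponent.

The generator is deliberately a *statistical* emulation: it reproduces the
feature distributions the pipeline consumes, not biophysics. Known limits:
spectra are sampled independently across electrodes (no spatial
correlation, hence no realistic topography structure); noise is independent
across frequency bins, whereas Welch estimates have correlated errors; and
peak emergence is independent across bands. Time-domain synthesis
(`make_recording()`, inverse-FFT coloring) and Welch estimation
(`welch_psd()`, Hamming windows, 4 s segments with 2 s overlap) are
provided and verified — white-noise level, Parseval, and slope round-trips
— but the cohort-level studies work directly with model spectra because
fitting 5 000+ Welch spectra per replicate adds cost without changing what
is being validated.

## Validation design notes

* Property tests plant peaks with heights ≥ 0.15 log10 units: at noise sd
  0.05 the detection stop-rule (2 sd) sits near height 0.1, and the tests
  are about recovery accuracy, not threshold-straddling detection.
* A planted peak counts as recovered if a fitted center lies within 1 Hz
  (planted peaks are ≥ 3 Hz apart); broad peaks occasionally split into
  two adjacent Gaussians, which is benign for every downstream feature.
* Power studies use 4-electrode cohorts: features are electrode averages,
  so montage size mainly affects feature noise, and 50 replicates of the
  full 62-electrode montage would cost ~25x more compute for the same
  qualitative answer.

## Reproducing a full run

```{r, eval = FALSE}
cfg <- run_config(cohort_config("ECT", seed = 101), out_dir = "results/ect")
report <- run_pipeline(cfg)
print(report)
```

The numbered scripts under `analysis/` execute the same stages one at a
time (simulate, fit, featurize, test, outcome model), writing all tables
under `results/`, and `scripts/acceptance.R` recomputes the headline
quantities from a single seed.
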