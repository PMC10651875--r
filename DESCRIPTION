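Package: specslow
Title: Spectral Parameterization of EEG Slowing After Seizure Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to disentangle broadband aperiodic activity from
    narrowband oscillations in resting-state EEG power spectra, built
    around the question of whether post-treatment "clinical slowing"
    after electroconvulsive or magnetic seizure therapy reflects true
    delta oscillations or a steepening of the 1/f background. Provides
    Welch spectral estimation, an aperiodic-plus-Gaussian-peaks spectral
    model, per-patient slowing features (exponent, canonical band power,
    aperiodic-adjusted oscillation power, oscillation abundance), a
    paired-test battery with Holm-Bonferroni step-down correction and
    nonparametric effect sizes, heteroskedasticity-robust regression with
    exhaustive outcome-model search, and a synthetic-cohort generator
    with known ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
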