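#' Default per-band oscillation presets for a treatment cohort
#'
#' Per band (delta, theta, alpha): the probability that an electrode
#' exhibits a peak at each timepoint (`emergence_pre`/`emergence_post`),
#' the mean and sd of the peak height in log10 units, the peak center and
#' its across-electrode jitter in Hz, and the range of Gaussian widths.
#' These are the building blocks of [cohort_config()]'s `band_peaks`
#' argument; modify a copy to construct custom conditions (e.g. a null
#' cohort with identical pre and post presets).
#'
#' @param treatment `"ECT"` or `"MST"`.
#' @return Named list of per-band preset lists.
#' @export
band_peak_defaults <- function(treatment) {
  if (treatment == "ECT") {
    list(
      delta = list(emergence_pre = 0.05, emergence_post = 0.35,
                   height_pre = 0.25, height_post = 0.45, height_sd = 0.08,
                   center = 2.5, center_jitter = 0.5, sd_range = c(0.6, 1.5)),
      theta = list(emergence_pre = 0.30, emergence_post = 0.65,
                   height_pre = 0.30, height_post = 0.70, height_sd = 0.10,
                   center = 5.5, center_jitter = 0.6, sd_range = c(0.6, 1.5)),
      alpha = list(emergence_pre = 0.98, emergence_post = 0.95,
                   height_pre = 1.30, height_post = 1.00, height_sd = 0.30,
                   center = 10, center_jitter = 1.0, sd_range = c(0.8, 2)))
  } else {
    list(
      delta = list(emergence_pre = 0.04, emergence_post = 0.05,
                   height_pre = 0.20, height_post = 0.35, height_sd = 0.08,
                   center = 2.5, center_jitter = 0.5, sd_range = c(0.6, 1.5)),
      theta = list(emergence_pre = 0.40, emergence_post = 0.60,
                   height_pre = 0.35, height_post = 0.55, height_sd = 0.10,
                   center = 5.5, center_jitter = 0.6, sd_range = c(0.6, 1.5)),
      alpha = list(emergence_pre = 0.98, emergence_post = 0.97,
                   height_pre = 1.20, height_post = 1.10, height_sd = 0.30,
                   center = 10, center_jitter = 1.0, sd_range = c(0.8, 2)))
  }
}

#' Configuration for a synthetic pre/post treatment cohort
#'
#' Default parameters emulate a typical convulsive-therapy EEG study:
#' 22 patients,
#' 62-electrode montage, baseline aperiodic exponent about 0.9-1.0 with a
#' post-treatment increase (ECT preset 0.88 -> 1.25, i.e. shift 0.37 with
#' between-patient sd 0.18 corresponding to d_z near 2; MST preset
#' 0.98 -> 1.14), band-limited Gaussian peaks with per-band emergence
#' probabilities and height shifts, and HAM-D scores (17-item for ECT,
#' 24-item for MST) with a configurable dependence of outcome on baseline
#' exponent.
#'
#' @param treatment `"ECT"` or `"MST"` preset.
#' @param n_patients,n_channels Cohort and montage sizes.
#' @param pre_exponent_mean,pre_exponent_sd Baseline exponent distribution.
#' @param exponent_shift_mean,exponent_shift_sd Post-minus-pre exponent
#'   shift distribution (per patient).
#' @param channel_exponent_sd,channel_offset_sd Per-channel jitter around
#'   the patient-level aperiodic parameters.
#' @param offset_mean,offset_sd Baseline offset (log10 V^2/Hz at 1 Hz).
#' @param pivot_hz Frequency about which the exponent shift rotates the
#'   spectrum; the offset moves by `shift * log10(pivot_hz)` so low
#'   frequencies gain power while high frequencies lose it.
#' @param band_peaks Per-band peak parameters; see `band_peak_defaults`.
#' @param noise_sd Per-bin log10-power noise sd.
#' @param freq_lo,freq_hi,freq_step Spectrum grid (Hz).
#' @param hamd_version 17 or 24.
#' @param hamd_pre_mean,hamd_pre_sd,hamd_pre_range Baseline HAM-D
#'   distribution (integers, clipped to the range).
#' @param hamd_treatment_effect Mean post-treatment score reduction.
#' @param hamd_effect_on_baseline_exponent Points of post HAM-D per unit of
#'   (centered) baseline exponent.
#' @param hamd_noise_sd Residual sd of the post score.
#' @param n_treatments_range Range the number of treatments is drawn from.
#' @param seed Integer seed; a fixed seed makes [make_cohort()] byte-for-
#'   byte reproducible.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(treatment = c("ECT", "MST"),
                          n_patients = 22L, n_channels = 62L,
                          pre_exponent_mean = NULL, pre_exponent_sd = NULL,
                          exponent_shift_mean = NULL, exponent_shift_sd = NULL,
                          channel_exponent_sd = 0.03,
                          channel_offset_sd = 0.05,
                          offset_mean = -11.6, offset_sd = 0.2,
                          pivot_hz = 20,
                          band_peaks = NULL,
                          noise_sd = 0.05,
                          freq_lo = 0.5, freq_hi = 30, freq_step = 0.25,
                          hamd_version = NULL,
                          hamd_pre_mean = NULL, hamd_pre_sd = 2,
                          hamd_pre_range = NULL,
                          hamd_treatment_effect = NULL,
                          hamd_effect_on_baseline_exponent = 5,
                          hamd_noise_sd = 3,
                          n_treatments_range = NULL,
                          seed = 1L) {
  treatment <- match.arg(treatment)
  ect <- treatment == "ECT"
  cfg <- list(
    treatment = treatment,
    n_patients = as.integer(n_patients),
    n_channels = as.integer(n_channels),
    pre_exponent_mean = pre_exponent_mean %||% if (ect) 0.88 else 0.98,
    pre_exponent_sd = pre_exponent_sd %||% if (ect) 0.21 else 0.18,
    exponent_shift_mean = exponent_shift_mean %||% if (ect) 0.37 else 0.16,
    exponent_shift_sd = exponent_shift_sd %||% if (ect) 0.18 else 0.20,
    channel_exponent_sd = channel_exponent_sd,
    channel_offset_sd = channel_offset_sd,
    offset_mean = offset_mean, offset_sd = offset_sd, pivot_hz = pivot_hz,
    band_peaks = band_peaks %||% band_peak_defaults(treatment),
    noise_sd = noise_sd,
    freq_lo = freq_lo, freq_hi = freq_hi, freq_step = freq_step,
    hamd_version = as.integer(hamd_version %||% if (ect) 17L else 24L),
    hamd_pre_mean = hamd_pre_mean %||% if (ect) 23 else 26.5,
    hamd_pre_sd = hamd_pre_sd,
    hamd_pre_range = hamd_pre_range %||% if (ect) c(18, 30) else c(20, 34),
    hamd_treatment_effect = hamd_treatment_effect %||% if (ect) 13 else 6,
    hamd_effect_on_baseline_exponent = hamd_effect_on_baseline_exponent,
    hamd_noise_sd = hamd_noise_sd,
    n_treatments_range = n_treatments_range %||% if (ect) c(8L, 20L) else c(12L, 24L),
    seed = as.integer(seed))
  probs <- unlist(lapply(cfg$band_peaks,
                         function(b) c(b$emergence_pre, b$emergence_post)))
  if (any(probs < 0 | probs > 1)) {
    abort_field("band_peaks", "emergence probabilities must lie in [0, 1]")
  }
  if (cfg$n_patients < 2L) abort_field("n_patients", "must be >= 2")
  if (!cfg$hamd_version %in% c(17L, 24L)) {
    abort_field("hamd_version", "must be 17 or 24")
  }
  structure(cfg, class = "cohort_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hamd_max <- function(version) c(`17` = 52, `24` = 76)[[as.character(version)]]

# draw one channel's ground-truth spectrum spec for a patient/timepoint
draw_channel_spec <- function(cfg, exponent_pt, offset_pt, timepoint, bands) {
  expn <- max(0.05, exponent_pt + stats::rnorm(1, 0, cfg$channel_exponent_sd))
  offs <- offset_pt + stats::rnorm(1, 0, cfg$channel_offset_sd)
  pk <- list()
  for (bn in names(cfg$band_peaks)) {
    bp <- cfg$band_peaks[[bn]]
    b <- bands[bands$name == bn, ]
    prob <- if (timepoint == "pre") bp$emergence_pre else bp$emergence_post
    if (stats::runif(1) < prob) {
      hmean <- if (timepoint == "pre") bp$height_pre else bp$height_post
      h <- max(0.1, stats::rnorm(1, hmean, bp$height_sd))
      ctr <- min(max(stats::rnorm(1, bp$center, bp$center_jitter),
                     b$lo + 0.3), b$hi - 0.3)
      s <- stats::runif(1, bp$sd_range[1], bp$sd_range[2])
      pk[[length(pk) + 1L]] <- data.frame(center = ctr, height = h, sd = s)
    }
  }
  peaks <- if (length(pk)) do.call(rbind, pk) else
    data.frame(center = numeric(), height = numeric(), sd = numeric())
  spectrum_spec(offset = offs, exponent = expn, peaks = peaks,
                noise_sd = cfg$noise_sd, freq_lo = cfg$freq_lo,
                freq_hi = cfg$freq_hi, freq_step = cfg$freq_step)
}

#' Generate a synthetic pre/post cohort with known ground truth
#'
#' Draws per-patient aperiodic parameters and their post-treatment shift,
#' per-channel ground-truth spectrum specifications for both timepoints,
#' the corresponding noisy power spectra, and a clinical table (pre/post
#' HAM-D, version, treatment count). The post HAM-D is the baseline score
#' minus the mean treatment effect plus
#' `hamd_effect_on_baseline_exponent * (baseline exponent - its mean)` plus
#' noise, rounded and clipped to the scale. Every generated spectrum's
#' ground truth is retained.
#'
#' @param config A [cohort_config()].
#' @return An object of class `"synthetic_cohort"`: `patients` (list with
#'   `id`, `truth_pre`, `truth_post` (per-channel [spectrum_spec()] lists),
#'   `spectra_pre`, `spectra_post` ([power_spectrum()])), `clinical` (data
#'   frame), `config`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  bands <- band_definitions()
  with_seed(config$seed, function() {
    chans <- sprintf("E%02d", seq_len(config$n_channels))
    patients <- vector("list", config$n_patients)
    clinical <- vector("list", config$n_patients)
    mx <- hamd_max(config$hamd_version)
    for (p in seq_len(config$n_patients)) {
      id <- sprintf("P%02d", p)
      expo_pre <- stats::rnorm(1, config$pre_exponent_mean,
                               config$pre_exponent_sd)
      shift <- stats::rnorm(1, config$exponent_shift_mean,
                            config$exponent_shift_sd)
      off_pre <- stats::rnorm(1, config$offset_mean, config$offset_sd)
      off_post <- off_pre + shift * log10(config$pivot_hz)
      truth <- list(pre = list(), post = list())
      pw <- list(pre = NULL, post = NULL)
      for (tp in c("pre", "post")) {
        e_pt <- if (tp == "pre") expo_pre else expo_pre + shift
        o_pt <- if (tp == "pre") off_pre else off_post
        specs <- lapply(chans, function(ch) {
          draw_channel_spec(config, e_pt, o_pt, tp, bands)
        })
        names(specs) <- chans
        freqs <- seq(config$freq_lo, config$freq_hi, by = config$freq_step)
        mat <- t(vapply(specs, function(s) {
          base <- spectrum_model_log10(freqs, s)
          10^(base + stats::rnorm(length(freqs), 0, s$noise_sd))
        }, numeric(length(freqs))))
        truth[[tp]] <- specs
        pw[[tp]] <- power_spectrum(freqs, mat, channels = chans,
                                   patient = id, timepoint = tp)
      }
      hamd_pre <- round(min(max(stats::rnorm(1, config$hamd_pre_mean,
                                             config$hamd_pre_sd),
                                config$hamd_pre_range[1]),
                            config$hamd_pre_range[2]))
      hamd_post <- round(hamd_pre - config$hamd_treatment_effect +
                           config$hamd_effect_on_baseline_exponent *
                             (expo_pre - config$pre_exponent_mean) +
                           stats::rnorm(1, 0, config$hamd_noise_sd))
      hamd_post <- min(max(hamd_post, 0), mx)
      clinical[[p]] <- data.frame(
        patient = id, treatment = config$treatment,
        hamd_pre = hamd_pre, hamd_post = hamd_post,
        hamd_version = config$hamd_version,
        n_treatments = sample(seq(config$n_treatments_range[1],
                                  config$n_treatments_range[2]), 1L),
        exponent_pre_true = expo_pre, exponent_shift_true = shift,
        stringsAsFactors = FALSE)
      patients[[p]] <- list(id = id, truth_pre = truth$pre,
                            truth_post = truth$post,
                            spectra_pre = pw$pre, spectra_post = pw$post)
    }
    structure(list(patients = patients,
                   clinical = do.call(rbind, clinical),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %s: %d patients x %d channels, seed %d\n",
              x$config$treatment, length(x$patients),
              x$config$n_channels, x$config$seed))
  invisible(x)
}

#' Fit every spectrum of a cohort
#'
#' @param cohort A [make_cohort()] result.
#' @param settings A [fit_settings()].
#' @return Named list per patient: `list(pre = <fits>, post = <fits>)`,
#'   each a named-by-electrode list of [fit_spectrum()] results.
#' @export
fit_cohort <- function(cohort, settings = fit_settings()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  out <- lapply(cohort$patients, function(pat) {
    fit_tp <- function(ps) {
      fits <- lapply(seq_along(ps$channels), function(ch) {
        fit_spectrum(ps, settings, channel = ch)
      })
      names(fits) <- ps$channels
      fits
    }
    list(pre = fit_tp(pat$spectra_pre), post = fit_tp(pat$spectra_post))
  })
  names(out) <- vapply(cohort$patients, `[[`, character(1), "id")
  out
}

#' Per-patient feature table for a whole cohort
#'
#' Applies the paired quality filter and electrode averaging per patient and
#' joins the clinical table. Patients with no surviving electrode are
#' dropped with a message.
#'
#' @param cohort A [make_cohort()] result.
#' @param fits A [fit_cohort()] result.
#' @param bands Band definitions.
#' @param r2_min Quality threshold.
#' @return Data frame, one row per retained patient.
#' @export
cohort_features <- function(cohort, fits, bands = band_definitions(),
                            r2_min = 0.8) {
  rows <- list()
  for (pat in cohort$patients) {
    f <- fits[[pat$id]]
    row <- patient_features(f$pre, f$post, pat$spectra_pre, pat$spectra_post,
                            bands = bands, r2_min = r2_min)
    if (is.null(row)) {
      message("dropping patient ", pat$id, ": no electrode with R^2 >= ",
              r2_min, " at both timepoints")
      next
    }
    rows[[length(rows) + 1L]] <- cbind(data.frame(patient = pat$id), row)
  }
  if (!length(rows)) abort_field("cohort", "no patient survived quality filtering")
  merge(cohort$clinical, do.call(rbind, rows), by = "patient")
}

#' Ground-truth feature table of a synthetic cohort
#'
#' The same per-patient feature columns as [cohort_features()], computed
#' from the stored generating parameters instead of spectral fits: exponent
#' is the electrode average of the true aperiodic exponents, abundance the
#' true fraction of electrodes given a band peak, oscillation power the
#' average true height of the highest in-band peak over peak-bearing
#' electrodes.
#'
#' @param cohort A [make_cohort()] result.
#' @return Data frame, one row per patient, joined with the clinical table.
#' @export
ground_truth_features <- function(cohort) {
  bands <- band_definitions()
  rows <- lapply(cohort$patients, function(pat) {
    row <- list(patient = pat$id)
    for (tp in c("pre", "post")) {
      truth <- pat[[paste0("truth_", tp)]]
      row[[paste0("exponent_", tp)]] <-
        mean(vapply(truth, `[[`, numeric(1), "exponent"))
      for (i in seq_len(nrow(bands))) {
        b <- bands[i, ]
        heights <- vapply(truth, function(s) {
          pk <- s$peaks[center_in_band(s$peaks$center, b), , drop = FALSE]
          if (!nrow(pk)) NA_real_ else max(pk$height)
        }, numeric(1))
        row[[paste0(b$name, "_abundance_", tp)]] <- mean(!is.na(heights))
        row[[paste0(b$name, "_osc_", tp)]] <-
          if (all(is.na(heights))) NA_real_ else mean(heights, na.rm = TRUE)
      }
    }
    df <- as.data.frame(row)
    for (v in c("exponent", paste0(bands$name, "_abundance"),
                paste0(bands$name, "_osc"))) {
      df[[paste0(v, "_diff")]] <- df[[paste0(v, "_pre")]] - df[[paste0(v, "_post")]]
    }
    df
  })
  merge(cohort$clinical, do.call(rbind, rows), by = "patient")
}

#' The eight-test EEG feature battery with Holm correction
#'
#' Runs the gated paired comparison (pre vs post) for aperiodic exponent,
#' delta band power, delta oscillation power, delta abundance, theta
#' oscillation power, theta abundance, alpha oscillation power and alpha
#' abundance, then applies the Holm-Bonferroni step-down correction across
#' the eight tests. Oscillation-power tests use only patients with a band
#' peak at both timepoints; all other tests use all patients.
#'
#' @param features A [cohort_features()] table.
#' @param alpha Family-wise level.
#' @return List: `tests` (data frame with statistic, p, effect size,
#'   Holm rank/threshold/decisions per feature), `results` (the underlying
#'   `"paired_test_result"` objects).
#' @export
eeg_feature_tests <- function(features, alpha = 0.05) {
  specs <- list(
    exponent = "exponent",
    delta_band_power = "delta_power",
    delta_oscillation_power = "delta_osc",
    delta_abundance = "delta_abundance",
    theta_oscillation_power = "theta_osc",
    theta_abundance = "theta_abundance",
    alpha_oscillation_power = "alpha_osc",
    alpha_abundance = "alpha_abundance")
  results <- lapply(specs, function(col) {
    pre <- features[[paste0(col, "_pre")]]
    post <- features[[paste0(col, "_post")]]
    tryCatch(paired_test(pre, post), error = function(e) NULL)
  })
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (is.null(r)) {
      return(data.frame(feature = nm, test = NA_character_, n = 0L,
                        statistic = NA_real_, p = NA_real_,
                        effect_type = NA_character_, effect = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(feature = nm, test = r$test_name, n = r$n,
               statistic = r$statistic, p = r$p,
               effect_type = r$effect_type, effect = r$effect,
               stringsAsFactors = FALSE)
  }))
  ok <- !is.na(tab$p)
  holm <- holm_bonferroni(tab$p[ok], tab$feature[ok], alpha = alpha)
  tab$holm_rank <- NA_integer_
  tab$alpha_adj <- NA_real_
  tab$reject_at_rank <- NA
  tab$reject_stepdown <- NA
  tab$holm_rank[ok] <- holm$rank
  tab$alpha_adj[ok] <- holm$alpha_adj
  tab$reject_at_rank[ok] <- holm$reject_at_rank
  tab$reject_stepdown[ok] <- holm$reject_stepdown
  list(tests = tab, results = results)
}

#' Per-electrode exponent matrices of a fitted cohort
#'
#' Convenience extraction for [electrode_topography_tests()]: patients x
#' electrodes matrices of the fitted aperiodic exponent at each timepoint,
#' with entries failing the paired quality filter set to `NA`.
#'
#' @param fits A [fit_cohort()] result.
#' @param r2_min Quality threshold.
#' @return List with `pre` and `post` matrices.
#' @export
exponent_matrices <- function(fits, r2_min = 0.8) {
  chans <- names(fits[[1]]$pre)
  get <- function(tp) {
    t(vapply(fits, function(f) {
      retained <- quality_filter(f$pre, f$post, r2_min)
      v <- vapply(chans, function(ch) {
        if (ch %in% retained) f[[tp]][[ch]]$exponent else NA_real_
      }, numeric(1))
      v
    }, numeric(length(chans))))
  }
  list(pre = get("pre"), post = get("post"))
}
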