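#' Canonical frequency bands
#'
#' Delta 1-4 Hz, theta 4-7 Hz, alpha 7-12 Hz. For assigning peak centers to
#' bands, intervals are closed on the left and open on the right, except
#' alpha which closes at 12 Hz (so a peak at exactly 4 Hz is theta, not
#' delta). Band power averages over all bins with `lo <= f <= hi`.
#'
#' @return Data frame with columns `name`, `lo`, `hi`.
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha"),
             lo = c(1, 4, 7), hi = c(4, 7, 12))
}

band_row <- function(bands, band) {
  if (is.character(band)) {
    i <- match(band, bands$name)
    if (is.na(i)) abort_field("band", "unknown band name")
    bands[i, ]
  } else {
    band
  }
}

#' Canonical band power of one channel
#'
#' Mean of log10 spectral power over the bins inside the band (closed on
#' both sides). This "total" band power conflates periodic and aperiodic
#' contributions, which is exactly the ambiguity the spectral model
#' disentangles.
#'
#' @param ps A [power_spectrum()].
#' @param band Band name (`"delta"`, `"theta"`, `"alpha"`) or a one-row data
#'   frame with `lo` and `hi`.
#' @param channel Channel index or label.
#' @return Mean log10 power (log10(V^2/Hz)).
#' @export
band_power <- function(ps, band, channel = 1L) {
  stopifnot(inherits(ps, "power_spectrum"))
  b <- band_row(band_definitions(), band)
  if (is.character(channel)) channel <- match(channel, ps$channels)
  idx <- ps$freqs >= b$lo & ps$freqs <= b$hi
  if (!any(idx)) abort_field("band", "no frequency bins inside the band")
  mean(log10(ps$power[channel, idx]))
}

# TRUE if a peak center falls in the band ([lo, hi), alpha closed at 12)
center_in_band <- function(center, b) {
  closed_right <- identical(as.character(b$name), "alpha")
  center >= b$lo & (center < b$hi | (closed_right & center <= b$hi))
}

#' Highest-power oscillation peak within a band
#'
#' @param fit A [fit_spectrum()] result.
#' @param band Band name or one-row band data frame.
#' @return One-row data frame (`center`, `height`, `sd`, `bandwidth`) for
#'   the in-band peak with maximal height, or `NULL` if the band has no
#'   peak.
#' @export
select_band_peak <- function(fit, band) {
  stopifnot(inherits(fit, "spectral_fit"))
  b <- band_row(band_definitions(), band)
  pk <- fit$peaks
  pk <- pk[center_in_band(pk$center, b), , drop = FALSE]
  if (!nrow(pk)) return(NULL)
  pk[which.max(pk$height), , drop = FALSE]
}

#' Paired electrode quality filter
#'
#' An electrode is retained only if its spectral fits at both timepoints
#' reach `r2_min`; a bad fit at either timepoint removes the electrode from
#' both (so pre/post features are always computed on the same montage).
#'
#' @param fits_pre,fits_post Named lists of [fit_spectrum()] results (one
#'   per electrode, same label sets).
#' @param r2_min Minimum R^2 (default 0.8).
#' @return Character vector of retained electrode labels (may be empty).
#' @export
quality_filter <- function(fits_pre, fits_post, r2_min = 0.8) {
  if (!setequal(names(fits_pre), names(fits_post))) {
    abort_field("fits_post", "electrode labels must match fits_pre")
  }
  labs <- names(fits_pre)
  ok <- vapply(labs, function(l) {
    isTRUE(fits_pre[[l]]$r_squared >= r2_min) &&
      isTRUE(fits_post[[l]]$r_squared >= r2_min)
  }, logical(1))
  labs[ok]
}

#' Oscillation abundance
#'
#' Fraction of retained electrodes whose fitted spectrum contains at least
#' one oscillation peak in the band. Captures the *emergence* of
#' oscillations across the scalp, as distinct from power changes in existing
#' oscillations.
#'
#' @param fits Named list of [fit_spectrum()] results for one patient and
#'   timepoint.
#' @param band Band name or one-row band data frame.
#' @param retained Electrode labels to use (default: all in `fits`).
#' @return Fraction in `[0, 1]`.
#' @export
abundance <- function(fits, band, retained = names(fits)) {
  if (!length(retained)) abort_field("retained", "needs >= 1 retained electrode")
  has <- vapply(retained, function(l) {
    !is.null(select_band_peak(fits[[l]], band))
  }, logical(1))
  mean(has)
}

# electrode-averaged features for one patient/timepoint over retained labels
timepoint_features <- function(fits, ps, retained, bands) {
  out <- list(exponent = mean(vapply(retained,
                                     function(l) fits[[l]]$exponent,
                                     numeric(1))))
  for (i in seq_len(nrow(bands))) {
    b <- bands[i, ]
    bp <- mean(vapply(retained,
                      function(l) band_power(ps, b, channel = l),
                      numeric(1)))
    heights <- vapply(retained, function(l) {
      pk <- select_band_peak(fits[[l]], b)
      if (is.null(pk)) NA_real_ else pk$height
    }, numeric(1))
    # oscillation power averages only over peak-bearing electrodes:
    # peakless electrodes are absent, never imputed as zero
    osc <- if (all(is.na(heights))) NA_real_ else mean(heights, na.rm = TRUE)
    out[[paste0(b$name, "_power")]] <- bp
    out[[paste0(b$name, "_osc")]] <- osc
    out[[paste0(b$name, "_abundance")]] <- abundance(fits, b, retained)
  }
  out
}

#' Per-patient slowing features
#'
#' Electrode-averaged pre, post and difference (pre minus post) values of
#' the aperiodic exponent, canonical band power, aperiodic-adjusted
#' oscillation power and oscillation abundance for each band, after the
#' paired quality filter.
#'
#' @param fits_pre,fits_post Named lists of [fit_spectrum()] results per
#'   electrode.
#' @param ps_pre,ps_post The corresponding [power_spectrum()] objects.
#' @param bands Band definitions (default [band_definitions()]).
#' @param r2_min Quality threshold passed to [quality_filter()].
#' @return One-row data frame (`NULL` if no electrode survives the filter,
#'   in which case the patient is dropped with a message). Oscillation power
#'   is `NA` when no retained electrode has a band peak.
#' @export
patient_features <- function(fits_pre, fits_post, ps_pre, ps_post,
                             bands = band_definitions(), r2_min = 0.8) {
  retained <- quality_filter(fits_pre, fits_post, r2_min)
  if (!length(retained)) return(NULL)
  pre <- timepoint_features(fits_pre, ps_pre, retained, bands)
  post <- timepoint_features(fits_post, ps_post, retained, bands)
  row <- list(n_electrodes_retained = length(retained))
  for (nm in names(pre)) {
    row[[paste0(nm, "_pre")]] <- pre[[nm]]
    row[[paste0(nm, "_post")]] <- post[[nm]]
    row[[paste0(nm, "_diff")]] <- pre[[nm]] - post[[nm]]
  }
  as.data.frame(row)
}
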