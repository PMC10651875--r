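#' Specification of a model power spectrum
#'
#' Describes a spectrum in log10-power space as an aperiodic component
#' (`offset - exponent * log10(f)`, the 1/f^chi background) plus a sum of
#' Gaussian oscillatory peaks, with optional i.i.d. Gaussian noise per
#' frequency bin (also in log10-power units, so the noise model matches the
#' space in which spectra are later fit).
#'
#' @param offset log10-power intercept at 1 Hz (log10(V^2/Hz)).
#' @param exponent Aperiodic exponent chi (>= 0, dimensionless): the negative
#'   slope of the spectrum in log-log space.
#' @param peaks Data frame with columns `center`, `height`, `sd`: peak center
#'   frequency (Hz), height above the aperiodic component (log10-power
#'   units), and Gaussian standard deviation (Hz). May have zero rows.
#' @param noise_sd Standard deviation of additive per-bin noise in
#'   log10-power units.
#' @param freq_lo,freq_hi,freq_step Frequency grid (Hz). Defaults match a
#'   4 s Welch window at 1000 Hz over the 0.5-30 Hz fitting range.
#' @return An object of class `"spectrum_spec"`.
#' @export
spectrum_spec <- function(offset = -11.6, exponent = 1,
                          peaks = data.frame(center = numeric(),
                                             height = numeric(),
                                             sd = numeric()),
                          noise_sd = 0,
                          freq_lo = 0.5, freq_hi = 30, freq_step = 0.25) {
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent < 0) {
    abort_field("exponent", "must be a single number >= 0")
  }
  if (freq_step <= 0) abort_field("freq_step", "must be > 0")
  if (freq_lo <= 0 || freq_lo >= freq_hi) {
    abort_field("freq_lo", "grid must satisfy 0 < freq_lo < freq_hi")
  }
  peaks <- as.data.frame(peaks)
  if (nrow(peaks)) {
    if (!all(c("center", "height", "sd") %in% names(peaks))) {
      abort_field("peaks", "needs columns center, height, sd")
    }
    if (any(peaks$sd <= 0)) abort_field("peaks$sd", "must be > 0")
    if (any(peaks$center < freq_lo | peaks$center > freq_hi)) {
      abort_field("peaks$center", "must lie within [freq_lo, freq_hi]")
    }
  }
  if (noise_sd < 0) abort_field("noise_sd", "must be >= 0")
  structure(list(offset = offset, exponent = exponent, peaks = peaks,
                 noise_sd = noise_sd, freq_lo = freq_lo, freq_hi = freq_hi,
                 freq_step = freq_step),
            class = "spectrum_spec")
}

# aperiodic component in log10-power space
aperiodic_log10 <- function(freqs, offset, exponent) {
  offset - exponent * log10(freqs)
}

# sum of Gaussian peaks in log10-power space (vectorized over peaks)
gauss_vec <- function(freqs, centers, heights, sds) {
  if (!length(centers)) return(numeric(length(freqs)))
  d <- outer(freqs, centers, "-")
  E <- exp(-d * d / matrix(2 * sds^2, length(freqs), length(sds),
                           byrow = TRUE))
  drop(E %*% heights)
}

gaussian_sum <- function(freqs, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0L) return(numeric(length(freqs)))
  gauss_vec(freqs, peaks$center, peaks$height, peaks$sd)
}

# noiseless model spectrum in log10-power space
spectrum_model_log10 <- function(freqs, spec) {
  aperiodic_log10(freqs, spec$offset, spec$exponent) +
    gaussian_sum(freqs, spec$peaks)
}

#' Container for a power spectrum
#'
#' @param freqs Strictly increasing frequency vector (Hz).
#' @param power Channels x frequency matrix of spectral power, linear units
#'   (V^2/Hz), strictly positive. A vector is treated as one channel.
#' @param channels Channel labels (unique).
#' @param patient,timepoint Optional metadata.
#' @return An object of class `"power_spectrum"`.
#' @export
power_spectrum <- function(freqs, power, channels = NULL,
                           patient = NA_character_,
                           timepoint = NA_character_) {
  if (is.vector(power)) power <- matrix(power, nrow = 1L)
  if (any(diff(freqs) <= 0)) abort_field("freqs", "must be strictly increasing")
  if (ncol(power) != length(freqs)) {
    abort_field("power", "ncol(power) must equal length(freqs)")
  }
  if (any(!is.finite(power)) || any(power <= 0)) {
    abort_field("power", "must be finite and strictly positive")
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(power)))
  if (anyDuplicated(channels)) abort_field("channels", "labels must be unique")
  rownames(power) <- channels
  structure(list(freqs = freqs, power = power, channels = channels,
                 patient = patient, timepoint = timepoint),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d channel(s), %d bins, %.2f-%.2f Hz\n",
              nrow(x$power), length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Generate a power spectrum from a model specification
#'
#' Evaluates `power(f) = 10^(offset - exponent*log10(f) + sum of Gaussians
#' + noise)` on the spectrum's frequency grid.
#'
#' @param spec A [spectrum_spec()].
#' @param seed Optional integer seed for the per-bin noise.
#' @param n_channels Number of independent noise realizations (channels).
#' @return A [power_spectrum()].
#' @export
make_spectrum <- function(spec, seed = NULL, n_channels = 1L) {
  stopifnot(inherits(spec, "spectrum_spec"))
  freqs <- seq(spec$freq_lo, spec$freq_hi, by = spec$freq_step)
  base <- spectrum_model_log10(freqs, spec)
  with_seed(seed, function() {
    noise <- if (spec$noise_sd > 0) {
      matrix(stats::rnorm(n_channels * length(freqs), 0, spec$noise_sd),
             nrow = n_channels)
    } else {
      matrix(0, n_channels, length(freqs))
    }
    power_spectrum(freqs, 10^sweep(noise, 2L, base, "+"))
  })
}

#' Container for a multichannel recording
#'
#' @param samples Channels x time matrix, volts.
#' @param fs Sampling rate (Hz).
#' @param channels Channel labels.
#' @param patient,timepoint Optional metadata.
#' @return An object of class `"recording"`.
#' @export
recording <- function(samples, fs, channels = NULL,
                      patient = NA_character_, timepoint = NA_character_) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (fs <= 0) abort_field("fs", "must be > 0")
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(samples)))
  if (anyDuplicated(channels)) abort_field("channels", "labels must be unique")
  structure(list(samples = samples, fs = fs, channels = channels,
                 patient = patient, timepoint = timepoint),
            class = "recording")
}

#' Synthesize a time-domain recording with a prescribed power spectrum
#'
#' Colors complex Gaussian noise in the frequency domain so that the
#' expected one-sided power spectral density equals the model spectrum
#' (aperiodic 1/f^chi background plus Gaussian oscillatory peaks), then
#' inverse-FFTs to a real signal. This gives exact control of the expected
#' Welch PSD for both the aperiodic and the periodic parts with a single
#' mechanism.
#'
#' @param spec A [spectrum_spec()]; its frequency grid fields are ignored
#'   (the DFT grid of the recording is used), only the model parameters
#'   matter.
#' @param duration_s Duration in seconds (>= 8 s, i.e. two default Welch
#'   windows).
#' @param fs Sampling rate in Hz; must satisfy Nyquist for all peaks.
#' @param seed Optional integer seed.
#' @param n_channels Number of independent channels.
#' @return A [recording()].
#' @export
make_recording <- function(spec, duration_s = 600, fs = 1000, seed = NULL,
                           n_channels = 1L) {
  stopifnot(inherits(spec, "spectrum_spec"))
  if (duration_s < 8) abort_field("duration_s", "must cover >= 2 Welch windows (8 s)")
  if (nrow(spec$peaks) && any(spec$peaks$center >= fs / 2)) {
    abort_field("fs", "peak frequencies exceed the Nyquist limit fs/2")
  }
  n <- round(duration_s * fs)
  nhalf <- n %/% 2
  freqs <- seq_len(nhalf - 1L) * fs / n           # strictly positive, < Nyquist
  target <- 10^spectrum_model_log10(freqs, spec)  # one-sided PSD, V^2/Hz
  amp <- sqrt(target * fs * n / 2)
  with_seed(seed, function() {
    samples <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      z <- complex(real = stats::rnorm(nhalf - 1L),
                   imaginary = stats::rnorm(nhalf - 1L)) / sqrt(2)
      spec_full <- complex(length.out = n)
      spec_full[2:(nhalf)] <- amp * z
      spec_full[(n - nhalf + 2L):n] <- Conj(rev(amp * z))
      # DC and Nyquist left at zero (fit range starts at 0.5 Hz)
      samples[ch, ] <- Re(stats::fft(spec_full, inverse = TRUE)) / n
    }
    recording(samples, fs)
  })
}
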