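#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hamming taper: the recording is cut
#' into overlapping segments, each segment is mean-detrended, tapered and
#' Fourier transformed, and the squared magnitudes are averaged with density
#' scaling (V^2/Hz, one-sided).
#'
#' @param rec A [recording()].
#' @param window_s Segment length in seconds (default 4 s, giving 0.25 Hz
#'   resolution).
#' @param overlap_s Overlap between consecutive segments in seconds
#'   (default 2 s, i.e. 50 percent).
#' @param drop_dc Drop the zero-frequency bin (default `TRUE`; downstream
#'   spectral fitting starts at 0.5 Hz and the container requires strictly
#'   positive power).
#' @return A [power_spectrum()].
#' @export
welch_psd <- function(rec, window_s = 4, overlap_s = 2, drop_dc = TRUE) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  n <- ncol(rec$samples)
  nper <- round(window_s * fs)
  nov <- round(overlap_s * fs)
  if (nper > n) abort_field("window_s", "window longer than the recording")
  if (nov >= nper) abort_field("overlap_s", "overlap must be shorter than the window")
  step <- nper - nov
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0L, nper - 1L) / (nper - 1L))
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nper %/% 2 + 1L
  freqs <- (seq_len(nfreq) - 1L) * fs / nper

  psd <- matrix(0, nrow(rec$samples), nfreq)
  for (ch in seq_len(nrow(rec$samples))) {
    acc <- numeric(nfreq)
    for (s in starts) {
      seg <- rec$samples[ch, s:(s + nper - 1L)]
      seg <- (seg - mean(seg)) * w
      px <- Mod(stats::fft(seg)[seq_len(nfreq)])^2 * scale
      # one-sided: double everything except DC and (for even nper) Nyquist
      px[2:(nfreq - 1L)] <- 2 * px[2:(nfreq - 1L)]
      if (nper %% 2 != 0L) px[nfreq] <- 2 * px[nfreq]
      acc <- acc + px
    }
    psd[ch, ] <- acc / length(starts)
  }
  keep <- if (drop_dc) -1L else seq_len(nfreq)
  power_spectrum(freqs[keep], psd[, keep, drop = FALSE],
                 channels = rec$channels,
                 patient = rec$patient, timepoint = rec$timepoint)
}
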