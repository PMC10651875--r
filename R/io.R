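#' Long-format spectra table for a cohort
#'
#' Columns: `patient`, `timepoint`, `channel`, `freq`, `power` (linear
#' units).
#'
#' @param cohort A [make_cohort()] result.
#' @return Data frame.
#' @export
spectra_table <- function(cohort) {
  rows <- list()
  for (pat in cohort$patients) {
    for (tp in c("pre", "post")) {
      ps <- pat[[paste0("spectra_", tp)]]
      for (ch in seq_along(ps$channels)) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient = pat$id, timepoint = tp, channel = ps$channels[ch],
          freq = ps$freqs, power = ps$power[ch, ],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Read power spectra from a long-format CSV
#'
#' Inverse of [spectra_table()] written with `write.csv`: rebuilds one
#' [power_spectrum()] per patient/timepoint.
#'
#' @param path CSV path with columns patient, timepoint, channel, freq,
#'   power.
#' @return Nested list: `out[[patient]][[timepoint]]` is a
#'   [power_spectrum()].
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "timepoint", "channel", "freq", "power")
  if (!all(need %in% names(df))) abort_field("path", "missing spectra columns")
  out <- list()
  for (pid in unique(df$patient)) {
    out[[pid]] <- list()
    for (tp in unique(df$timepoint[df$patient == pid])) {
      sub <- df[df$patient == pid & df$timepoint == tp, ]
      chans <- unique(sub$channel)
      freqs <- sort(unique(sub$freq))
      mat <- matrix(NA_real_, length(chans), length(freqs),
                    dimnames = list(chans, NULL))
      for (ch in chans) {
        s <- sub[sub$channel == ch, ]
        mat[ch, ] <- s$power[order(s$freq)]
      }
      out[[pid]][[tp]] <- power_spectrum(freqs, mat, channels = chans,
                                         patient = pid, timepoint = tp)
    }
  }
  out
}

#' Flatten cohort spectral fits to a wide table
#'
#' One row per patient/timepoint/electrode with the aperiodic parameters,
#' R^2, and `peak<i>_center/height/bw` columns up to the largest peak count
#' present.
#'
#' @param fits A [fit_cohort()] result.
#' @return Data frame.
#' @export
fits_table <- function(fits) {
  rows <- list()
  maxk <- 0L
  for (pid in names(fits)) {
    for (tp in c("pre", "post")) {
      for (ch in names(fits[[pid]][[tp]])) {
        f <- fits[[pid]][[tp]][[ch]]
        maxk <- max(maxk, nrow(f$peaks))
        rows[[length(rows) + 1L]] <- list(patient = pid, timepoint = tp,
                                          channel = ch, fit = f)
      }
    }
  }
  out <- lapply(rows, function(r) {
    f <- r$fit
    base <- data.frame(patient = r$patient, timepoint = r$timepoint,
                       channel = r$channel, offset = f$offset,
                       exponent = f$exponent, r_squared = f$r_squared,
                       n_peaks = nrow(f$peaks), stringsAsFactors = FALSE)
    for (i in seq_len(maxk)) {
      has <- i <= nrow(f$peaks)
      base[[paste0("peak", i, "_center")]] <- if (has) f$peaks$center[i] else NA_real_
      base[[paste0("peak", i, "_height")]] <- if (has) f$peaks$height[i] else NA_real_
      base[[paste0("peak", i, "_bw")]] <- if (has) f$peaks$bandwidth[i] else NA_real_
    }
    base
  })
  do.call(rbind, out)
}

#' Read cohort spectral fits from a wide CSV
#'
#' Inverse of [fits_table()] written with `write.csv`: rebuilds the nested
#' `fits[[patient]][[timepoint]][[channel]]` structure of [fit_cohort()].
#' Peak standard deviations are recovered from the stored bandwidths
#' (`sd = bandwidth / 2`).
#'
#' @param path CSV path written from a [fits_table()].
#' @return Nested list of `"spectral_fit"` objects.
#' @export
read_fits_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "timepoint", "channel", "offset", "exponent",
            "r_squared", "n_peaks")
  if (!all(need %in% names(df))) abort_field("path", "missing fit columns")
  out <- list()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    k <- r$n_peaks
    peaks <- data.frame(center = numeric(k), height = numeric(k),
                        sd = numeric(k), bandwidth = numeric(k))
    for (j in seq_len(k)) {
      peaks$center[j] <- r[[paste0("peak", j, "_center")]]
      peaks$height[j] <- r[[paste0("peak", j, "_height")]]
      peaks$bandwidth[j] <- r[[paste0("peak", j, "_bw")]]
      peaks$sd[j] <- peaks$bandwidth[j] / 2
    }
    fit <- structure(list(offset = r$offset, exponent = r$exponent,
                          peaks = peaks, r_squared = r$r_squared,
                          converged = TRUE),
                     class = "spectral_fit")
    out[[r$patient]][[r$timepoint]][[r$channel]] <- fit
  }
  out
}

#' Write a recording as plain text with a JSON sidecar
#'
#' The samples go to a whitespace-delimited text matrix (channels as rows);
#' sampling rate, channel labels and metadata go to `<path>.json`.
#'
#' @param rec A [recording()].
#' @param path Output path for the sample matrix.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  utils::write.table(rec$samples, path, row.names = FALSE,
                     col.names = FALSE)
  meta <- list(fs = rec$fs, channels = rec$channels,
               patient = rec$patient, timepoint = rec$timepoint,
               n_samples = ncol(rec$samples))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path of the sample matrix; `<path>.json` must exist.
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  samples <- as.matrix(utils::read.table(path))
  dimnames(samples) <- NULL
  recording(samples, fs = meta$fs, channels = meta$channels,
            patient = meta$patient %||% NA_character_,
            timepoint = meta$timepoint %||% NA_character_)
}

#' Ground-truth sidecar for a synthetic cohort
#'
#' Serializable list of every generated spectrum's true parameters, suitable
#' for `jsonlite::write_json`.
#'
#' @param cohort A [make_cohort()] result.
#' @return Nested list keyed by patient, timepoint, channel.
#' @export
ground_truth_sidecar <- function(cohort) {
  out <- list()
  for (pat in cohort$patients) {
    out[[pat$id]] <- lapply(c(pre = "pre", post = "post"), function(tp) {
      lapply(pat[[paste0("truth_", tp)]], function(s) {
        list(offset = s$offset, exponent = s$exponent,
             peaks = s$peaks, noise_sd = s$noise_sd)
      })
    })
  }
  out
}
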