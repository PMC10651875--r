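#' Settings for spectral parameterization
#'
#' @param fit_lo,fit_hi Fit range in Hz (default 0.5-30 Hz).
#' @param peak_threshold Minimum peak height, in log10-power units above the
#'   aperiodic component, for a bump to count as an oscillation (default
#'   0.05).
#' @param max_n_peaks Maximum number of Gaussian peaks fit per spectrum
#'   (default 12).
#' @param bandwidth_lo,bandwidth_hi Peak bandwidth limits in Hz (default
#'   1-8 Hz). Bandwidth is defined as twice the Gaussian standard deviation,
#'   so the sd is constrained to `[bandwidth_lo, bandwidth_hi] / 2`.
#' @param r2_min Minimum model R^2 for a fit to be retained downstream
#'   (default 0.8).
#' @return An object of class `"fit_settings"`.
#' @export
fit_settings <- function(fit_lo = 0.5, fit_hi = 30,
                         peak_threshold = 0.05, max_n_peaks = 12L,
                         bandwidth_lo = 1, bandwidth_hi = 8,
                         r2_min = 0.8) {
  if (fit_lo >= fit_hi) abort_field("fit_lo", "must be < fit_hi")
  if (bandwidth_lo >= bandwidth_hi) abort_field("bandwidth_lo", "must be < bandwidth_hi")
  if (max_n_peaks < 0) abort_field("max_n_peaks", "must be >= 0")
  structure(list(fit_lo = fit_lo, fit_hi = fit_hi,
                 peak_threshold = peak_threshold,
                 max_n_peaks = as.integer(max_n_peaks),
                 bandwidth_lo = bandwidth_lo, bandwidth_hi = bandwidth_hi,
                 r2_min = r2_min),
            class = "fit_settings")
}

# aperiodic OLS in log-log space; exponent constrained >= 0
ap_ols <- function(lx, y) {
  fit <- stats::lm.fit(cbind(1, lx), y)
  offset <- fit$coefficients[[1]]
  exponent <- -fit$coefficients[[2]]
  if (exponent < 0) {
    exponent <- 0
    offset <- mean(y)
  }
  c(offset = offset, exponent = exponent)
}

# initial aperiodic estimate robust to oscillatory peaks: fit, then refit on
# the bins least elevated above the first trend (peaks only push power up)
robust_ap_fit <- function(lx, y) {
  ap <- ap_ols(lx, y)
  flat <- y - (ap[1] - ap[2] * lx)
  keep <- flat <= stats::quantile(flat, 0.6)
  if (sum(keep) >= 3L) ap <- ap_ols(lx[keep], y[keep])
  ap
}

gauss1 <- function(f, center, height, sd) {
  height * exp(-(f - center)^2 / (2 * sd^2))
}

# sum of squared errors and its analytic gradient for k Gaussians with
# parameter vector (c1, h1, s1, c2, h2, s2, ...)
gauss_sse <- function(p, freqs, flat) {
  k <- length(p) %/% 3L
  nf <- length(freqs)
  model <- numeric(nf)
  E <- matrix(0, nf, k)
  d <- matrix(0, nf, k)
  for (j in seq_len(k)) {
    b <- 3L * (j - 1L)
    d[, j] <- freqs - p[b + 1L]
    E[, j] <- exp(-d[, j]^2 / (2 * p[b + 3L]^2))
    model <- model + p[b + 2L] * E[, j]
  }
  r <- flat - model
  g <- numeric(3L * k)
  for (j in seq_len(k)) {
    b <- 3L * (j - 1L)
    hgt <- p[b + 2L]; s <- p[b + 3L]
    rE <- r * E[, j]
    g[b + 1L] <- -2 * hgt * sum(rE * d[, j]) / s^2
    g[b + 2L] <- -2 * sum(rE)
    g[b + 3L] <- -2 * hgt * sum(rE * d[, j]^2) / s^3
  }
  list(value = sum(r * r), gradient = g)
}

# optim fn/gr pair sharing one evaluation per parameter vector
sse_fns <- function(freqs, flat) {
  last_p <- NULL
  last <- NULL
  ev <- function(p) {
    if (is.null(last_p) || !identical(p, last_p)) {
      last <<- gauss_sse(p, freqs, flat)
      last_p <<- p
    }
    last
  }
  list(fn = function(p) ev(p)$value, gr = function(p) ev(p)$gradient)
}

# iterative peak extraction from the flattened spectrum
extract_peaks <- function(freqs, flat, settings) {
  sd_lo <- settings$bandwidth_lo / 2
  sd_hi <- settings$bandwidth_hi / 2
  peaks <- list()
  resid <- flat
  while (length(peaks) < settings$max_n_peaks) {
    stop_at <- max(settings$peak_threshold, 2 * stats::sd(resid))
    i <- which.max(resid)
    h0 <- resid[i]
    if (h0 <= stop_at) break
    c0 <- freqs[i]
    # crude sd guess from the half-height width around the maximum
    above <- resid >= h0 / 2
    run <- rle(above)
    ends <- cumsum(run$lengths)
    blk <- which(ends >= i & (ends - run$lengths + 1L) <= i)[1]
    width <- run$lengths[blk] * mean(diff(freqs))
    s0 <- min(max(width / 2.355, sd_lo), sd_hi)
    fns <- sse_fns(freqs, resid)
    opt <- stats::optim(c(c0, h0, s0), fn = fns$fn, gr = fns$gr,
                        method = "L-BFGS-B",
                        lower = c(max(settings$fit_lo, c0 - 2 * s0), 0, sd_lo),
                        upper = c(min(settings$fit_hi, c0 + 2 * s0),
                                  1.5 * h0, sd_hi))
    peaks[[length(peaks) + 1L]] <- opt$par
    resid <- resid - gauss1(freqs, opt$par[1], opt$par[2], opt$par[3])
  }
  if (!length(peaks)) {
    return(data.frame(center = numeric(), height = numeric(), sd = numeric()))
  }
  m <- do.call(rbind, peaks)
  data.frame(center = m[, 1], height = m[, 2], sd = m[, 3])
}

# joint re-fit of all Gaussians on the flattened spectrum
refit_peaks <- function(freqs, flat, peaks, settings) {
  if (!nrow(peaks)) return(peaks)
  sd_lo <- settings$bandwidth_lo / 2
  sd_hi <- settings$bandwidth_hi / 2
  p0 <- as.numeric(t(as.matrix(peaks[, c("center", "height", "sd")])))
  k <- nrow(peaks)
  fns <- sse_fns(freqs, flat)
  opt <- stats::optim(p0, fn = fns$fn, gr = fns$gr, method = "L-BFGS-B",
                      lower = rep(c(settings$fit_lo, 0, sd_lo), k),
                      upper = rep(c(settings$fit_hi, Inf, sd_hi), k))
  pp <- matrix(opt$par, ncol = 3, byrow = TRUE)
  data.frame(center = pp[, 1], height = pp[, 2], sd = pp[, 3])
}

#' Fit the aperiodic-plus-peaks model to one spectrum
#'
#' Parameterizes a single-channel power spectrum in log10 space as
#' `L(f) = offset - exponent*log10(f) + sum of Gaussians`. The algorithm:
#' (1) robust initial aperiodic fit on the bins least contaminated by peaks;
#' (2) iterative peak extraction from the flattened spectrum (largest
#' residual, single-Gaussian fit, subtract) until the residual maximum falls
#' below `max(peak_threshold, 2 * residual sd)` or `max_n_peaks` is reached;
#' (3) joint re-fit of all Gaussians; (4) exact OLS re-fit of the aperiodic
#' component on the peak-subtracted spectrum, iterated once. Peaks whose
#' final height does not surpass `peak_threshold` are discarded.
#'
#' @param ps A [power_spectrum()].
#' @param settings A [fit_settings()].
#' @param channel Channel index or label to fit (default first).
#' @return An object of class `"spectral_fit"` with elements `offset`,
#'   `exponent`, `peaks` (data frame: `center`, `height`, `sd`, `bandwidth`),
#'   `r_squared`, `converged`, `settings` and metadata. Non-convergence is
#'   flagged with `r_squared = 0`, never silently.
#' @export
fit_spectrum <- function(ps, settings = fit_settings(), channel = 1L) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (is.character(channel)) channel <- match(channel, ps$channels)
  idx <- ps$freqs >= settings$fit_lo & ps$freqs <= settings$fit_hi
  if (sum(idx) < 5L) abort_field("ps", "spectrum does not cover the fit range")
  freqs <- ps$freqs[idx]
  pw <- ps$power[channel, idx]
  if (any(pw <= 0)) abort_field("ps", "power must be strictly positive")
  y <- log10(pw)
  lx <- log10(freqs)

  fit <- tryCatch({
    ap <- robust_ap_fit(lx, y)
    peaks <- extract_peaks(freqs, y - (ap[1] - ap[2] * lx), settings)
    for (it in 1:2) {
      ap <- ap_ols(lx, y - gaussian_sum(freqs, peaks))
      peaks <- refit_peaks(freqs, y - (ap[1] - ap[2] * lx), peaks, settings)
    }
    peaks <- peaks[peaks$height > settings$peak_threshold, , drop = FALSE]
    ap <- ap_ols(lx, y - gaussian_sum(freqs, peaks))
    model <- (ap[1] - ap[2] * lx) + gaussian_sum(freqs, peaks)
    r2 <- if (stats::sd(y) == 0 || stats::sd(model) == 0) {
      0
    } else {
      stats::cor(model, y)^2
    }
    list(offset = unname(ap[1]), exponent = unname(ap[2]),
         peaks = peaks, r_squared = r2, converged = TRUE)
  }, error = function(e) {
    list(offset = NA_real_, exponent = NA_real_,
         peaks = data.frame(center = numeric(), height = numeric(),
                            sd = numeric()),
         r_squared = 0, converged = FALSE)
  })
  fit$peaks$bandwidth <- 2 * fit$peaks$sd
  rownames(fit$peaks) <- NULL
  structure(c(fit, list(settings = settings,
                        channel = ps$channels[channel],
                        patient = ps$patient, timepoint = ps$timepoint)),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf(
    "<spectral_fit> offset=%.3f exponent=%.3f peaks=%d R2=%.4f%s\n",
    x$offset, x$exponent, nrow(x$peaks), x$r_squared,
    if (x$converged) "" else " (non-converged)"))
  invisible(x)
}

#' Evaluate a spectral fit on a frequency grid
#'
#' @param fit A [fit_spectrum()] result.
#' @param freqs Frequencies (Hz) inside the fit range.
#' @return List with `full` and `aperiodic` log10-power vectors; their
#'   difference is the Gaussian (oscillatory) component.
#' @export
evaluate_fit <- function(fit, freqs) {
  stopifnot(inherits(fit, "spectral_fit"))
  if (any(freqs < fit$settings$fit_lo | freqs > fit$settings$fit_hi)) {
    abort_field("freqs", "must lie within the fit range")
  }
  ap <- aperiodic_log10(freqs, fit$offset, fit$exponent)
  list(full = ap + gaussian_sum(freqs, fit$peaks), aperiodic = ap)
}

#' Goodness of fit of a spectral model
#'
#' Squared Pearson correlation between modeled and observed log10 power over
#' the fit range.
#'
#' @param fit A [fit_spectrum()] result.
#' @param ps The [power_spectrum()] it was fit to.
#' @param channel Channel index or label.
#' @return R^2 in `[0, 1]`; constant data are flagged with `NA` and a
#'   warning.
#' @export
fit_r_squared <- function(fit, ps, channel = 1L) {
  stopifnot(inherits(fit, "spectral_fit"), inherits(ps, "power_spectrum"))
  if (is.character(channel)) channel <- match(channel, ps$channels)
  idx <- ps$freqs >= fit$settings$fit_lo & ps$freqs <= fit$settings$fit_hi
  y <- log10(ps$power[channel, idx])
  model <- evaluate_fit(fit, ps$freqs[idx])$full
  if (stats::sd(y) == 0) {
    warning("constant spectrum: R^2 undefined")
    return(NA_real_)
  }
  stats::cor(model, y)^2
}
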