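#' Peak-detection configuration
#'
#' @param amplitude_gate_sd Candidate gate: a local maximum of the
#'   detrended signal is a candidate only if its height exceeds this many
#'   standard deviations of the full detrended trial (default 1.5).
#' @param fit_window_seconds Width of the parabola-fit window centered on
#'   the peak (default 2.5 s, the expected duration of a visually evoked
#'   dilation).
#' @param derivative_smoothing_sd_samples Gaussian smoothing SD for the
#'   first derivative, in samples (default 2, i.e. 80 ms at 25 Hz).
#' @param signal_smoothing_sd_samples Gaussian smoothing SD applied to the
#'   detrended signal before detection, in samples (default 10 = 400 ms
#'   at 25 Hz; 0 disables). Detection operates on the filtered-and-
#'   smoothed pupil signal: the kernel passes the band of evoked
#'   transients (2-2.5 s span, main lobe below ~0.3 Hz) essentially
#'   intact while suppressing tracker noise and fast flutter, whose
#'   extrema would otherwise swamp the candidate list.
#' @return A list of class `peak_config`.
#' @export
peak_config <- function(amplitude_gate_sd = 1.5, fit_window_seconds = 2.5,
                        derivative_smoothing_sd_samples = 2,
                        signal_smoothing_sd_samples = 10) {
  stopifnot(
    amplitude_gate_sd > 0, fit_window_seconds > 0,
    derivative_smoothing_sd_samples > 0,
    signal_smoothing_sd_samples >= 0
  )
  structure(
    list(
      amplitude_gate_sd = amplitude_gate_sd,
      fit_window_seconds = fit_window_seconds,
      derivative_smoothing_sd_samples = derivative_smoothing_sd_samples,
      signal_smoothing_sd_samples = signal_smoothing_sd_samples
    ),
    class = "peak_config"
  )
}

# zero-phase Gaussian smoothing with edge replication; sd in samples
.gaussian_smooth <- function(y, sd_samples) {
  if (sd_samples <= 0) return(y)
  n <- length(y)
  half <- max(1L, ceiling(4 * sd_samples))
  kern <- stats::dnorm(seq(-half, half), sd = sd_samples)
  kern <- kern / sum(kern)
  pad <- c(rep(y[1], half), y, rep(y[n], half))
  sm <- stats::convolve(pad, rev(kern), type = "open")
  sm[(2L * half + 1L):(2L * half + n)]
}

#' Smoothed first derivative
#'
#' Central first difference (units per sample) convolved with a Gaussian
#' kernel truncated at four standard deviations; the signal is edge-padded
#' by replication so the output has the input length.
#'
#' @param signal Numeric vector with at least 3 samples.
#' @param config A [peak_config].
#' @return Numeric vector, same length as `signal`.
#' @export
smoothed_derivative <- function(signal, config = peak_config()) {
  n <- length(signal)
  if (n < 3) stop("need at least 3 samples")
  sdv <- config$derivative_smoothing_sd_samples
  half <- max(1L, ceiling(4 * sdv))
  kern <- stats::dnorm(seq(-half, half), sd = sdv)
  kern <- kern / sum(kern)
  pad <- c(
    rep(signal[1], half + 1L), signal, rep(signal[n], half + 1L)
  )
  # central difference on the padded signal
  dpad <- (pad[-(1:2)] - pad[seq_len(length(pad) - 2L)]) / 2
  sm <- stats::convolve(dpad, rev(kern), type = "open")
  # dpad[i] is the derivative at padded index i+1; crop back to signal
  start <- half + half + 1L # kernel offset + pad offset
  sm[start:(start + n - 1L)]
}

#' Detect candidate dilation peaks
#'
#' The detrended signal is first smoothed with an 80 ms Gaussian (see
#' [peak_config]); local maxima are then located at negative-going zero
#' crossings of the smoothed first derivative, and a maximum is kept as a
#' candidate iff its (smoothed) value exceeds `amplitude_gate_sd` times
#' the standard deviation of the whole smoothed detrended trial. Only
#' maxima (dilations) are considered; constriction minima are ignored.
#' Both smoothing steps are linear, so detection is invariant to scaling
#' and equivariant to time shifts.
#'
#' @param trace A detrended [pupil_trace] (mean near 0) or numeric vector.
#' @param config A [peak_config].
#' @param sampling_rate Used when `trace` is a plain vector.
#' @return A data frame of unfitted candidates: `peak_index`, `peak_time`,
#'   `amplitude_sd` (height in trial-SD units), sorted by time. Empty if
#'   nothing passes the gate.
#' @export
find_candidates <- function(trace, config = peak_config(),
                            sampling_rate = 25) {
  if (inherits(trace, "pupil_trace")) {
    y <- trace$y
    t <- trace$t
  } else {
    y <- as.numeric(trace)
    t <- (seq_along(y) - 1L) / sampling_rate
  }
  empty <- data.frame(
    peak_index = integer(0), peak_time = numeric(0), amplitude_sd = numeric(0)
  )
  if (length(y) < 3) return(empty)
  y <- .gaussian_smooth(y, config$signal_smoothing_sd_samples)
  s <- stats::sd(y)
  # guard against numerically-constant signals (FFT smoothing residue)
  if (!is.finite(s) || s <= 1e-12 * (max(abs(y)) + 1)) return(empty)
  d <- smoothed_derivative(y, config)
  n <- length(y)
  # negative-going zero crossing between i and i+1 -> maximum nearby
  pos <- which(d[-n] > 0 & d[-1] <= 0)
  if (length(pos) == 0) return(empty)
  peak_index <- vapply(pos, function(i) {
    # snap to the larger of the two bracketing samples
    if (y[i] >= y[i + 1L]) i else i + 1L
  }, integer(1))
  peak_index <- unique(peak_index)
  # extrema within the smoothing kernels' support of the trace edge are
  # padding artifacts, not data
  edge <- ceiling(4 * max(config$signal_smoothing_sd_samples,
    config$derivative_smoothing_sd_samples)) + 1L
  peak_index <- peak_index[peak_index > edge & peak_index <= n - edge]
  height <- y[peak_index]
  keep <- height > config$amplitude_gate_sd * s
  data.frame(
    peak_index = peak_index[keep],
    peak_time = t[peak_index[keep]],
    amplitude_sd = height[keep] / s
  )[order(t[peak_index[keep]]), , drop = FALSE]
}

#' Fit a parabola to a candidate peak and compute its FWHM
#'
#' Least-squares quadratic `y = a + b (t - t_peak) + c (t - t_peak)^2`
#' over the samples within half the fit window on each side of the peak
#' (2.5 s window = +/- 1.25 s), computed on the same smoothed signal the
#' detector saw. The full width at half maximum is taken
#' from the fitted parabola relative to its minimum over the window
#' (baseline): with fitted height `h` above that baseline,
#' `fwhm = 2 sqrt(h / (2 |c|))`. A candidate whose fitted vertex is not a
#' maximum (`c >= 0`) is discarded (returns `NULL`), as is one with fewer
#' than 5 in-range samples after edge truncation.
#'
#' @param trace A [pupil_trace] or numeric vector (the detrended signal).
#' @param peak_index Sample index of the candidate maximum.
#' @param config A [peak_config].
#' @param sampling_rate Used when `trace` is a plain vector.
#' @return A one-row data frame `peak_index`, `peak_time`, `a`, `b`, `c`,
#'   `fwhm`, `fit_rmse`, or `NULL` if the candidate is discarded.
#' @export
fit_parabola <- function(trace, peak_index, config = peak_config(),
                         sampling_rate = 25) {
  if (inherits(trace, "pupil_trace")) {
    y <- trace$y
    t <- trace$t
    sampling_rate <- trace$sampling_rate
  } else {
    y <- as.numeric(trace)
    t <- (seq_along(y) - 1L) / sampling_rate
  }
  y <- .gaussian_smooth(y, config$signal_smoothing_sd_samples)
  half_n <- round(config$fit_window_seconds / 2 * sampling_rate)
  lo <- max(1L, peak_index - half_n)
  hi <- min(length(y), peak_index + half_n)
  idx <- lo:hi
  if (length(idx) < 5) return(NULL)
  dt <- t[idx] - t[peak_index]
  X <- cbind(1, dt, dt^2)
  fit <- stats::lm.fit(X, y[idx])
  cf <- unname(fit$coefficients)
  if (anyNA(cf) || cf[3] >= 0) return(NULL)
  a <- cf[1]; b <- cf[2]; cc <- cf[3]
  # fitted parabola over the window; baseline = its minimum there
  pb <- a + b * dt + cc * dt^2
  vertex_val <- a - b^2 / (4 * cc)
  h <- vertex_val - min(pb)
  if (h <= 0) return(NULL)
  fwhm <- 2 * sqrt(h / (2 * abs(cc)))
  data.frame(
    peak_index = peak_index, peak_time = t[peak_index],
    a = a, b = b, c = cc, fwhm = fwhm,
    fit_rmse = sqrt(mean(fit$residuals^2))
  )
}

#' Detect and characterize candidate peaks
#'
#' Runs [find_candidates] and [fit_parabola] on a detrended trace,
#' dropping candidates whose parabola fit fails.
#'
#' @inheritParams find_candidates
#' @return Data frame of fitted candidates: `peak_index`, `peak_time`,
#'   `amplitude_sd`, `a`, `b`, `c`, `fwhm`, `fit_rmse`.
#' @export
detect_peaks <- function(trace, config = peak_config(), sampling_rate = 25) {
  # smooth the detection signal once; the callees then run unsmoothed
  if (inherits(trace, "pupil_trace")) {
    sampling_rate <- trace$sampling_rate
    smoothed <- trace
    smoothed$y <- .gaussian_smooth(trace$y, config$signal_smoothing_sd_samples)
  } else {
    smoothed <- .gaussian_smooth(as.numeric(trace),
      config$signal_smoothing_sd_samples)
  }
  cfg0 <- config
  cfg0$signal_smoothing_sd_samples <- 0
  cand <- find_candidates(smoothed, cfg0, sampling_rate)
  fits <- lapply(cand$peak_index, function(i) {
    fit_parabola(smoothed, i, cfg0, sampling_rate)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    return(data.frame(
      peak_index = integer(0), peak_time = numeric(0),
      amplitude_sd = numeric(0), a = numeric(0), b = numeric(0),
      c = numeric(0), fwhm = numeric(0), fit_rmse = numeric(0)
    ))
  }
  out <- do.call(rbind, fits[ok])
  out$amplitude_sd <- cand$amplitude_sd[ok]
  out[, c(
    "peak_index", "peak_time", "amplitude_sd", "a", "b", "c",
    "fwhm", "fit_rmse"
  )]
}
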