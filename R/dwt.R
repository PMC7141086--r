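# Orthogonal discrete wavelet transform (decimated filter bank) for the
# Daubechies family. Implemented here directly because the whole cascade
# rests on sub-band decomposition/reconstruction: an analysis low-pass and
# high-pass filter pair applied successively with downsampling by 2, and
# the exact inverse. The transform is computed periodically on a signal
# padded (by the chosen boundary extension) to a multiple of 2^level, which
# gives exact invertibility for every input length and boundary mode.

# Daubechies scaling (low-pass) filter taps, h[0..2N-1]; sum = sqrt(2),
# sum of squares = 1. db4 = 4 vanishing moments, 8 taps.
.db_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(
    0.48296291314469025, 0.8365163037378079,
    0.22414386804185735, -0.12940952255092145
  ),
  db4 = c(
    0.23037781330885523, 0.7148465705525415,
    0.6308807679295904, -0.02798376941698385,
    -0.18703481171888114, 0.030841381835986965,
    0.032883011666982945, -0.010597401784997278
  )
)

.wavelet_filter <- function(wavelet_name) {
  h <- .db_filters[[wavelet_name]]
  if (is.null(h)) {
    stop(
      "unknown wavelet '", wavelet_name, "'; available: ",
      paste(names(.db_filters), collapse = ", ")
    )
  }
  L <- length(h)
  # quadrature mirror high-pass: g[n] = (-1)^n h[L-1-n]
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g, length = L)
}

# one periodic analysis step: x (even length) -> list(a, d) of half length
.dwt_step <- function(x, flt) {
  n <- length(x)
  k <- n / 2L
  idx0 <- 2L * (seq_len(k) - 1L) # 0-based start of each window
  a <- numeric(k)
  d <- numeric(k)
  for (tap in seq_len(flt$length)) {
    xi <- x[((idx0 + tap - 1L) %% n) + 1L]
    a <- a + flt$h[tap] * xi
    d <- d + flt$g[tap] * xi
  }
  list(a = a, d = d)
}

# one periodic synthesis step: (a, d) of length k -> x of length 2k.
# Positions repeat when 2k < filter length, so contributions are summed
# per target index.
.idwt_step <- function(a, d, flt) {
  k <- length(a)
  n <- 2L * k
  idx0 <- 2L * (seq_len(k) - 1L)
  x <- numeric(n)
  for (tap in seq_len(flt$length)) {
    pos <- ((idx0 + tap - 1L) %% n) + 1L
    contrib <- flt$h[tap] * a + flt$g[tap] * d
    if (anyDuplicated(pos)) {
      s <- rowsum(contrib, pos)
      x[as.integer(rownames(s))] <- x[as.integer(rownames(s))] + s[, 1]
    } else {
      x[pos] <- x[pos] + contrib
    }
  }
  x
}

# boundary extension of x to length m >= length(x)
.extend_signal <- function(x, m, boundary_mode) {
  n <- length(x)
  extra <- m - n
  if (extra == 0L) return(x)
  pad <- switch(boundary_mode,
    periodic = x[((seq_len(extra) - 1L) %% n) + 1L],
    symmetric = {
      # half-point symmetric extension: ..., x[n-1], x[n], x[n], x[n-1], ...
      refl <- c(rev(x), x) # period-2n symmetric sequence starting after x
      refl[((seq_len(extra) - 1L) %% (2L * n)) + 1L]
    },
    stop("unknown boundary_mode '", boundary_mode, "'")
  )
  c(x, pad)
}

#' Multiresolution wavelet decomposition
#'
#' Decomposes a signal into approximation coefficients `A_J` and detail
#' coefficients `D_1` (finest) through `D_J` by successive application of
#' the analysis filter pair with downsampling by 2. The signal is first
#' extended by the chosen boundary rule to the next multiple of
#' `2^level`, and the transform is computed periodically on the extended
#' signal, so the decomposition is exactly invertible for any length.
#'
#' @param signal Numeric vector, length at least `2^level`.
#' @param wavelet_name One of `"db1"`, `"db2"`, `"db4"` (default `"db4"`).
#' @param level Decomposition depth `J` (default 4).
#' @param boundary_mode `"symmetric"` (half-point reflection, default) or
#'   `"periodic"`. With `"periodic"` on a length divisible by `2^level`
#'   the transform is orthonormal, so coefficient energy equals signal
#'   energy (Parseval).
#' @return An object of class `dwt_decomposition` with fields `approx`
#'   (`A_J`), `details` (list `D_1..D_J`, finest first), `wavelet_name`,
#'   `level`, `boundary_mode`, `original_length`.
#' @export
dwt_decompose <- function(signal, wavelet_name = "db4", level = 4,
                          boundary_mode = "symmetric") {
  signal <- as.numeric(signal)
  if (anyNA(signal) || !all(is.finite(signal))) {
    stop("signal must be finite (interpolate gaps first)")
  }
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1")
  n <- length(signal)
  if (n < 2^level) {
    stop(sprintf(
      "signal of length %d too short for level %d; maximum feasible level is %d",
      n, level, max(0L, floor(log2(n)))
    ))
  }
  if (!boundary_mode %in% c("periodic", "symmetric")) {
    stop("unknown boundary_mode '", boundary_mode, "'")
  }
  flt <- .wavelet_filter(wavelet_name)
  block <- 2^level
  m <- as.integer(ceiling(n / block) * block)
  x <- .extend_signal(signal, m, boundary_mode)
  details <- vector("list", level)
  for (j in seq_len(level)) {
    st <- .dwt_step(x, flt)
    details[[j]] <- st$d
    x <- st$a
  }
  names(details) <- sprintf("D_%d", seq_len(level))
  structure(
    list(
      approx = x, details = details,
      wavelet_name = wavelet_name, level = level,
      boundary_mode = boundary_mode,
      original_length = n, padded_length = m
    ),
    class = "dwt_decomposition"
  )
}

#' @export
print.dwt_decomposition <- function(x, ...) {
  cat(sprintf(
    "<dwt_decomposition> %s, level %d, %s boundary: A_%d (%d) + %s\n",
    x$wavelet_name, x$level, x$boundary_mode, x$level, length(x$approx),
    paste(sprintf("D_%d (%d)", seq_len(x$level),
      vapply(x$details, length, 1L)
    ), collapse = " + ")
  ))
  invisible(x)
}

#' Reconstruct a single frequency sub-band
#'
#' Inverts the decomposition with all coefficient sets except the requested
#' band zeroed, yielding the signal's component in that band at the
#' original length. The band reconstructions of `A_J` and all `D_j` sum to
#' the original signal (perfect reconstruction).
#'
#' @param decomposition A [dwt_decompose] result.
#' @param band `"A_J"` (e.g. `"A_4"`) or `"D_j"` (e.g. `"D_1"` = finest).
#' @return Numeric vector of length `original_length`.
#' @export
dwt_reconstruct_band <- function(decomposition, band) {
  d <- decomposition
  flt <- .wavelet_filter(d$wavelet_name)
  zero <- function(v) numeric(length(v))
  a <- zero(d$approx)
  dets <- lapply(d$details, zero)
  if (grepl("^A_", band)) {
    j <- as.integer(sub("^A_", "", band))
    if (is.na(j) || j != d$level) {
      stop("unknown band '", band, "': approximation is A_", d$level)
    }
    a <- d$approx
  } else if (grepl("^D_", band)) {
    j <- as.integer(sub("^D_", "", band))
    if (is.na(j) || j < 1L || j > d$level) {
      stop("unknown band '", band, "': details are D_1..D_", d$level)
    }
    dets[[j]] <- d$details[[j]]
  } else {
    stop("unknown band label '", band, "'")
  }
  x <- a
  for (j in rev(seq_len(d$level))) {
    x <- .idwt_step(x, dets[[j]], flt)
  }
  x[seq_len(d$original_length)]
}

#' Full inverse wavelet transform
#'
#' @param decomposition A [dwt_decompose] result.
#' @return The reconstructed signal at the original length.
#' @export
dwt_reconstruct <- function(decomposition) {
  d <- decomposition
  flt <- .wavelet_filter(d$wavelet_name)
  x <- d$approx
  for (j in rev(seq_len(d$level))) {
    x <- .idwt_step(x, d$details[[j]], flt)
  }
  x[seq_len(d$original_length)]
}

#' Absolute and relative sub-band energies
#'
#' The energy of a band is the sum of its squared coefficients; relative
#' energies divide by the total over all bands, characterizing how the
#' signal's energy distributes across frequency. A zero-energy signal
#' yields all relative energies 0.
#'
#' @param decomposition A [dwt_decompose] result.
#' @return A list with `e_detail` (vector `D_1..D_J`), `e_approx`,
#'   `rel_detail`, `rel_approx`.
#' @export
band_energies <- function(decomposition) {
  e_detail <- vapply(decomposition$details, function(d) sum(d^2), numeric(1))
  e_approx <- sum(decomposition$approx^2)
  total <- sum(e_detail) + e_approx
  if (total > 0) {
    rel_detail <- e_detail / total
    rel_approx <- e_approx / total
  } else {
    rel_detail <- e_detail * 0
    rel_approx <- 0
  }
  list(
    e_detail = e_detail, e_approx = e_approx,
    rel_detail = rel_detail, rel_approx = rel_approx
  )
}

#' Wavelet detrending of a pupil trace
#'
#' Estimates the slow non-stationary trend (gradual drift of pupil size
#' over minutes) as the low-frequency wavelet approximation `A_J` and
#' subtracts it. At 25 Hz the default `trend_level = 9` keeps frequencies
#' below roughly 25/2^10 = 0.024 Hz (periods longer than about 40 s) in
#' the trend, which is the time scale of drift rather than of evoked
#' dilations (a few seconds).
#'
#' @param trace A [pupil_trace] (gaps interpolated, i.e. finite `y`), or a
#'   plain numeric vector.
#' @param trend_level Decomposition depth for the trend band (default 9).
#' @param wavelet_name Wavelet for the trend estimate (default `"db4"`).
#' @return A list with `detrended` (same type as the input), `trend`
#'   (numeric vector), `trend_level`.
#' @export
dwt_detrend <- function(trace, trend_level = 9, wavelet_name = "db4") {
  y <- if (inherits(trace, "pupil_trace")) trace$y else as.numeric(trace)
  dec <- dwt_decompose(y,
    wavelet_name = wavelet_name, level = trend_level,
    boundary_mode = "symmetric"
  )
  trend <- dwt_reconstruct_band(dec, sprintf("A_%d", trend_level))
  resid <- y - trend
  # fold any residual constant (boundary leakage of the approximation)
  # into the trend so the detrended signal is exactly zero-mean
  trend <- trend + mean(resid)
  resid <- resid - mean(resid)
  out <- trace
  if (inherits(trace, "pupil_trace")) {
    out$y <- resid
    out$meta$detrended <- TRUE
  } else {
    out <- resid
  }
  list(detrended = out, trend = trend, trend_level = trend_level)
}
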