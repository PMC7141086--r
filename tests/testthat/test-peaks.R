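# config with signal smoothing off: several analytic cases below are exact
# only on the raw signal; smoothing-on behavior is covered separately
cfg_raw <- peak_config(signal_smoothing_sd_samples = 0)

test_that("smoothed derivative reproduces analytic derivatives", {
  t <- seq(0, 10, by = 0.04)
  d <- smoothed_derivative(3 * t, cfg_raw)
  # slope in units per sample: m * dt
  expect_equal(d[25:200], rep(3 * 0.04, 176), tolerance = 1e-6)

  expect_equal(smoothed_derivative(rep(5, 100), cfg_raw), rep(0, 100))

  # sine, period 2 s at 25 Hz: negative-going zero crossings within one
  # sample of the maxima at t = 0.5, 2.5, ...
  y <- sin(2 * pi * t / 2)
  d <- smoothed_derivative(y, cfg_raw)
  zc <- which(d[-length(d)] > 0 & d[-1] <= 0)
  maxima_idx <- vapply(seq(0.5, 9.5, by = 2), function(m) {
    which.min(abs(t - m))
  }, integer(1))
  for (m in maxima_idx) expect_lte(min(abs(zc - m)), 1)
})

test_that("constant and sub-gate signals yield no candidates", {
  expect_equal(nrow(find_candidates(rep(4, 200), cfg_raw)), 0)
  # pure sine: extremum height is sqrt(2) SD < 1.5 SD gate
  y <- sin(2 * pi * seq(0, 20, by = 0.04) / 2)
  expect_lt(max(y) / sd(y), 1.5)
  expect_equal(nrow(find_candidates(y, cfg_raw)), 0)
})

test_that("an injected bump above the gate is found at its apex", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 2000
    y <- rnorm(n, 0, 1)
    apex <- 1000
    bump <- 5 * exp(-((seq_len(n) - apex)^2) / (2 * 25^2))
    cand <- find_candidates(y + bump, peak_config())
    near <- cand$peak_time[abs(cand$peak_time - (apex - 1) / 25) <= 0.2]
    if (length(near) >= 1) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("detection is scale-invariant and translation-equivariant", {
  cfg <- peak_config()
  for (s in 1:50) {
    set.seed(100 + s)
    core <- rnorm(1500, 0, 0.3)
    napex <- sample(500:1000, 1)
    core <- core + 4 * exp(-((seq_len(1500) - napex)^2) / (2 * 30^2))
    pad <- rep(0, 125)
    y1 <- c(pad, core, pad)
    # scale invariance: same candidate set for k * y
    c1 <- find_candidates(y1, cfg)
    c2 <- find_candidates(7.3 * y1, cfg)
    expect_equal(c1$peak_index, c2$peak_index)
    expect_equal(c1$amplitude_sd, c2$amplitude_sd, tolerance = 1e-9)
    # translation equivariance: shifting the core by k samples within the
    # constant padding shifts every interior candidate by k samples
    k <- 50
    y2 <- c(rep(0, 125 + k), core, rep(0, 125 - k))
    c3 <- find_candidates(y2, cfg)
    i1 <- c1$peak_index[c1$peak_index > 200 & c1$peak_index < 1550]
    i3 <- c3$peak_index[c3$peak_index > 200 + k & c3$peak_index < 1550 + k]
    expect_equal(i3, i1 + k)
  }
})

test_that("candidate count is monotone non-increasing in the gate", {
  set.seed(5)
  y <- rnorm(3000, 0, 1) + 0.5 * sin(seq_len(3000) / 40)
  gates <- c(0.5, 1, 1.5, 2, 3)
  counts <- vapply(gates, function(g) {
    nrow(find_candidates(y, peak_config(amplitude_gate_sd = g)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("parabola fit recovers exact quadratics and their FWHM", {
  # vertex on the sample grid, 50 Hz so the +/- 0.5 s window is integral
  t0 <- 2.0
  tt <- seq(0, 4, by = 0.02)
  y <- 1 - 4 * (tt - t0)^2
  pk <- which(tt == t0)
  fit <- fit_parabola(y, pk, peak_config(fit_window_seconds = 1.0,
    signal_smoothing_sd_samples = 0), sampling_rate = 50)
  expect_equal(fit$a, 1, tolerance = 1e-9)
  expect_equal(fit$b, 0, tolerance = 1e-9)
  expect_equal(fit$c, -4, tolerance = 1e-9)
  expect_lt(fit$fit_rmse, 1e-9)
  # height above the window minimum (at +/-0.5 s): h = 1 ->
  # fwhm = 2 sqrt(1 / 8)
  expect_equal(fit$fwhm, 2 * sqrt(1 / 8), tolerance = 1e-9)
})

test_that("fitted FWHM matches a root-finding half-height oracle", {
  set.seed(6)
  cfg <- peak_config(signal_smoothing_sd_samples = 0)
  half_n <- round(cfg$fit_window_seconds / 2 * 25)
  for (i in 1:100) {
    a <- runif(1, 0.5, 2)
    b <- runif(1, -0.3, 0.3)
    cc <- -runif(1, 0.5, 5)
    tt <- seq(-4, 4, by = 0.04)
    y <- a + b * tt + cc * tt^2
    pk <- which.max(y)
    fit <- fit_parabola(y, pk, cfg)
    lo <- tt[pk - half_n] - tt[pk]
    hi <- tt[pk + half_n] - tt[pk]
    expect_equal(fit$fwhm, oracle_fwhm(fit$a, fit$b, fit$c, lo, hi),
      tolerance = 1e-6)
  }
})

test_that("noisy quadratic coefficients match the normal-equations oracle", {
  set.seed(7)
  for (i in 1:20) {
    tt <- seq(0, 4, by = 0.04)
    y <- 1 - 2 * (tt - 2)^2 + rnorm(length(tt), 0, 0.01)
    pk <- which(tt == 2)
    cfg <- peak_config(signal_smoothing_sd_samples = 0)
    fit <- fit_parabola(y, pk, cfg)
    half_n <- round(cfg$fit_window_seconds / 2 * 25)
    idx <- (pk - half_n):(pk + half_n)
    ora <- oracle_quadfit(tt[idx] - tt[pk], y[idx])
    expect_equal(c(fit$a, fit$b, fit$c), unname(ora), tolerance = 1e-9)
  }
})

test_that("non-concave fits and short windows discard the candidate", {
  tt <- seq(0, 4, by = 0.04)
  y <- (tt - 2)^2 # convex: c > 0
  expect_null(fit_parabola(y, which(tt == 2),
    peak_config(signal_smoothing_sd_samples = 0)))
  expect_null(fit_parabola(c(1, 2, 1), 2, cfg_raw)) # < 5 samples
})

test_that("injected events on default synthetic traces are recovered", {
  found <- total <- 0
  for (s in 1:5) {
    g <- generate_trace(synthetic_params(seed = 400 + s))
    pp <- preprocess_trace(g$trace, annotation = g$annotation)
    det <- dwt_detrend(pp$trace)$detrended
    cand <- detect_peaks(det)
    ev <- pp$annotation$events
    total <- total + nrow(ev)
    for (k in seq_len(nrow(ev))) {
      span <- g$truth$events$span[k]
      if (any(cand$peak_time >= ev$onset[k] &
          cand$peak_time <= ev$onset[k] + span)) {
        found <- found + 1
      }
    }
  }
  expect_gte(found / total, 0.9)
})
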