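bands_of <- function(dec) {
  c(sprintf("D_%d", seq_len(dec$level)), sprintf("A_%d", dec$level))
}

test_that("constant signals put all energy into the approximation", {
  dec <- dwt_decompose(rep(4, 64), level = 4, boundary_mode = "periodic")
  expect_lt(max(abs(unlist(dec$details))), 1e-10)
  en <- band_energies(dec)
  expect_equal(en$rel_approx, 1, tolerance = 1e-12)
  expect_equal(unname(en$rel_detail), rep(0, 4), tolerance = 1e-12)
  expect_lt(max(abs(dwt_reconstruct_band(dec, "D_1"))), 1e-10)
})

test_that("periodic transform on dyadic lengths preserves energy (Parseval)", {
  set.seed(1)
  for (n in c(32, 64, 128, 256)) {
    x <- rnorm(n)
    dec <- dwt_decompose(x, level = 4, boundary_mode = "periodic")
    coef_energy <- sum(dec$approx^2) + sum(unlist(dec$details)^2)
    expect_equal(coef_energy, sum(x^2), tolerance = 1e-8)
  }
})

test_that("reconstruction is exact for every boundary mode and length", {
  set.seed(2)
  for (mode in c("periodic", "symmetric")) {
    for (n in c(64, 100, 101, 333)) {
      x <- rnorm(n)
      dec <- dwt_decompose(x, level = 4, boundary_mode = mode)
      expect_lt(
        max(abs(dwt_reconstruct(dec) - x)) / max(abs(x)), 1e-8
      )
      # sum of all single-band reconstructions equals the signal
      s <- Reduce(`+`, lapply(bands_of(dec), dwt_reconstruct_band,
        decomposition = dec))
      expect_lt(max(abs(s - x)) / max(abs(x)), 1e-8)
    }
  }
})

test_that("decomposition agrees with the brute-force filter-bank oracle", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(c(16, 32, 64), 1)
    lvl <- sample(2:4, 1)
    x <- rnorm(n)
    dec <- dwt_decompose(x, level = lvl, boundary_mode = "periodic")
    ora <- oracle_dwt(x, lvl)
    expect_equal(dec$approx, ora$approx, tolerance = 1e-10)
    for (j in seq_len(lvl)) {
      expect_equal(dec$details[[j]], ora$details[[j]], tolerance = 1e-10)
    }
  }
})

test_that("coefficient lengths follow the dyadic downsampling ladder", {
  dec <- dwt_decompose(rnorm(128), level = 4, boundary_mode = "periodic")
  expect_equal(vapply(dec$details, length, 1L),
    c(D_1 = 64L, D_2 = 32L, D_3 = 16L, D_4 = 8L))
  expect_length(dec$approx, 8)
})

test_that("frequency content lands in the expected bands", {
  # slow sinusoid (period 80 samples) concentrates in A_4
  x <- sin(2 * pi * (0:255) / 80)
  dec <- dwt_decompose(x, level = 4, boundary_mode = "periodic")
  a4 <- dwt_reconstruct_band(dec, "A_4")
  expect_gte(sum(a4^2) / sum(x^2), 0.90)

  # Nyquist alternation concentrates in the finest detail band
  x <- rep(c(1, -1), 64)
  en <- band_energies(dwt_decompose(x, level = 4,
    boundary_mode = "periodic"))
  expect_equal(unname(which.max(c(en$rel_detail, en$rel_approx))), 1L)
})

test_that("relative energies are a partition of unity", {
  set.seed(4)
  for (i in 1:50) {
    x <- rnorm(75)
    en <- band_energies(dwt_decompose(x, level = 4))
    expect_equal(sum(en$rel_detail) + en$rel_approx, 1, tolerance = 1e-12)
    expect_true(all(en$rel_detail >= 0))
  }
  # zero signal: all relative energies defined as 0
  en0 <- band_energies(dwt_decompose(rep(0, 64), level = 4))
  expect_equal(sum(en0$rel_detail) + en0$rel_approx, 0)
})

test_that("over-deep decomposition requests name the feasible level", {
  expect_error(dwt_decompose(rnorm(64), level = 8), "6")
  expect_error(dwt_decompose(c(1, NA, 3), level = 1), "finite")
  expect_error(dwt_decompose(rnorm(64), level = 4, boundary_mode = "zero"),
    "boundary")
  expect_error(dwt_reconstruct_band(dwt_decompose(rnorm(64), level = 2), "D_5"),
    "unknown band")
})

test_that("wavelet detrending removes slow structure and little else", {
  # constant trace: trend is the constant, residual is zero
  d <- dwt_detrend(rep(4, 2048), trend_level = 9)
  expect_equal(d$trend, rep(4, 2048), tolerance = 1e-8)
  expect_lt(max(abs(d$detrended)), 1e-8)

  # white noise + slow ramp over 10 min: residual decorrelated from ramp
  set.seed(11)
  n <- 600 * 25
  ramp <- seq(0, 0.8, length.out = n)
  y <- 4 + ramp + rnorm(n, 0, 0.08)
  d <- dwt_detrend(y, trend_level = 9)
  expect_lt(abs(cor(d$detrended, ramp)), 0.1)
  expect_lt(abs(mean(d$detrended)), 0.01 * sd(d$detrended))

  # idempotence: a second pass finds almost no further trend
  d2 <- dwt_detrend(d$detrended, trend_level = 9)
  expect_lt(sum(d2$trend^2), 0.01 * sum(d$trend^2))
})

test_that("detrending a pupil_trace returns a trace on the same grid", {
  g <- generate_trace(synthetic_params(duration = 120, n_events = 0, seed = 2))
  tr <- interpolate_gaps(g$trace)
  d <- dwt_detrend(tr, trend_level = 9)
  expect_s3_class(d$detrended, "pupil_trace")
  expect_equal(d$detrended$t, tr$t)
  expect_equal(d$detrended$y + d$trend, tr$y, tolerance = 1e-8)
})
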