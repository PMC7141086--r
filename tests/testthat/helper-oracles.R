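# Independent oracles and small fixture builders used across the suite.

# Published Daubechies-4 (8-tap) scaling filter, written out here again so
# the oracle does not share the package's constants.
oracle_db4_h <- c(
  0.23037781330885523, 0.7148465705525415,
  0.6308807679295904, -0.02798376941698385,
  -0.18703481171888114, 0.030841381835986965,
  0.032883011666982945, -0.010597401784997278
)

# Brute-force periodic filter bank: explicit convolution + decimation with
# plain loops, one level.
oracle_dwt_step <- function(x, h) {
  L <- length(h)
  g <- numeric(L)
  for (i in seq_len(L)) g[i] <- (-1)^(i - 1) * h[L - i + 1]
  n <- length(x)
  a <- numeric(n / 2)
  d <- numeric(n / 2)
  for (k in seq_len(n / 2)) {
    for (m in seq_len(L)) {
      idx <- ((2 * (k - 1) + m - 1) %% n) + 1
      a[k] <- a[k] + h[m] * x[idx]
      d[k] <- d[k] + g[m] * x[idx]
    }
  }
  list(a = a, d = d)
}

oracle_dwt <- function(x, level) {
  details <- list()
  for (j in seq_len(level)) {
    st <- oracle_dwt_step(x, oracle_db4_h)
    details[[j]] <- st$d
    x <- st$a
  }
  list(approx = x, details = details)
}

# Closed-form least-squares quadratic via the normal equations.
oracle_quadfit <- function(dt, y) {
  X <- cbind(1, dt, dt^2)
  solve(crossprod(X), crossprod(X, y))[, 1]
}

# Half-height width of a concave parabola a + b u + c u^2 over window
# [lo, hi], baseline = its minimum on the window; root-finding oracle.
oracle_fwhm <- function(a, b, cc, lo, hi) {
  p <- function(u) a + b * u + cc * u^2
  uv <- -b / (2 * cc)
  base <- min(p(lo), p(hi))
  half <- base + (p(uv) - base) / 2
  left <- stats::uniroot(function(u) p(u) - half,
    lower = uv - 10 * (hi - lo), upper = uv, tol = 1e-12
  )$root
  right <- stats::uniroot(function(u) p(u) - half,
    lower = uv, upper = uv + 10 * (hi - lo), tol = 1e-12
  )$root
  right - left
}

# Rank-statistic (Mann-Whitney) AUC.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Independent single-pass artifact-flagging oracle (same rule precedence,
# written as one literal sweep).
oracle_flag <- function(y, valid, margin, jump_frac, out_sd) {
  n <- length(y)
  keep <- valid
  # margins
  for (i in seq_len(n)) {
    if (!valid[i]) {
      for (k in max(1, i - margin):min(n, i + margin)) keep[k] <- FALSE
    }
  }
  # jumps against the last surviving value
  ref <- NA_real_
  for (i in seq_len(n)) {
    if (!keep[i]) next
    if (is.na(ref)) {
      ref <- y[i]
    } else if (abs(y[i] - ref) / abs(ref) > jump_frac) {
      keep[i] <- FALSE
    } else {
      ref <- y[i]
    }
  }
  # single statistical pass
  if (sum(keep) >= 2) {
    m <- mean(y[keep])
    s <- sd(y[keep])
    if (is.finite(s) && s > 0) {
      for (i in seq_len(n)) {
        if (keep[i] && abs(y[i] - m) > out_sd * s) keep[i] <- FALSE
      }
    }
  }
  keep
}

# tiny uniform-grid trace builder
make_trace <- function(y, valid = NULL, rate = 25, id = "T1") {
  pupil_trace((seq_along(y) - 1) / rate, y,
    valid = valid,
    subject_id = id, sampling_rate = rate
  )
}

# cohort of synthetic subjects sharing a global seed
make_cohort <- function(n_subjects, global_seed, ...) {
  lapply(seq_len(n_subjects), function(i) {
    generate_trace(synthetic_params(seed = 100 * global_seed + i, ...))
  })
}

# run preprocess -> detrend -> detect -> features -> label for one subject
run_subject <- function(sim, peaks = peak_config()) {
  pp <- preprocess_trace(sim$trace, annotation = sim$annotation)
  det <- dwt_detrend(pp$trace)$detrended
  cand <- detect_peaks(det, peaks)
  ft <- peak_feature_table(det, cand)
  lab <- label_candidates(ft, pp$annotation)
  list(
    features = lab$candidates, unmatched = lab$unmatched_events,
    report = pp$report, annotation = pp$annotation
  )
}
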