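# Synthetic pupil traces with known ground truth. The generator emulates
# the statistical structure the cascade assumes: a slow non-stationary
# drift over minutes, band-limited stochastic fluctuation of the pupillary
# light reflex, white measurement noise, blink runs (size reported as 0),
# isolated gross outliers, and hazard-evoked dilation transients with a
# physiological time course (onset latency 200-350 ms, peak at 500-1000 ms,
# total span 2-2.5 s, oscillatory return).

#' Parameters of the synthetic pupil-trace generator
#'
#' Defaults reproduce the recording conditions the cascade targets: a
#' 40-minute drive sampled at 25 Hz with nine hazard events. Event
#' amplitude is parameterized in units of the trace's non-event
#' (noise + fluctuation) standard deviation so the 1.5-SD candidate gate
#' is exercised at a known contrast; the default of 2.5 SD is a generator
#' choice, not an empirical value.
#'
#' @param duration Trace length, seconds (default 2400).
#' @param sampling_rate Samples per second (default 25).
#' @param baseline Mean pupil size, arbitrary units (default 4.0).
#' @param drift_amplitude Total amplitude of the slow drift (sum of
#'   sinusoid amplitudes), same units (default `0.3 * baseline`).
#' @param drift_periods Sinusoid periods of the drift, seconds.
#' @param noise_sd White measurement noise SD (default `0.02 * baseline`).
#' @param plr_amplitude SD of the band-limited stochastic fluctuation
#'   (default `0.0125 * baseline`, the scale of spontaneous slow pupil
#'   oscillation relative to a 4 mm pupil).
#' @param n_events Number of hazard events (default 9).
#' @param event_amplitude_sd Evoked peak height in units of the non-event
#'   SD (default 2.5).
#' @param onset_latency_range Seconds from stimulus to dilation onset.
#' @param time_to_peak_range Seconds from stimulus to peak response.
#' @param span_range Total transient duration, seconds.
#' @param return_waves Oscillation count of the gradual return (default 2).
#' @param return_decay Geometric amplitude decay per return wave
#'   (default 0.5).
#' @param blink_rate Blinks per minute (default 12); blink duration is
#'   uniform on 2-5 samples.
#' @param outlier_rate Gross outliers per minute (default 2).
#' @param seed Integer RNG seed; one stream fully determines the trace.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(duration = 2400, sampling_rate = 25,
                             baseline = 4.0,
                             drift_amplitude = 0.3 * baseline,
                             drift_periods = c(600, 300, 120),
                             noise_sd = 0.02 * baseline,
                             plr_amplitude = 0.0125 * baseline,
                             n_events = 9,
                             event_amplitude_sd = 2.5,
                             onset_latency_range = c(0.20, 0.35),
                             time_to_peak_range = c(0.5, 1.0),
                             span_range = c(2.0, 2.5),
                             return_waves = 2,
                             return_decay = 0.5,
                             blink_rate = 12,
                             outlier_rate = 2,
                             seed = 1L) {
  stopifnot(
    duration > 0, sampling_rate > 0, baseline > 0,
    drift_amplitude >= 0, noise_sd >= 0, plr_amplitude >= 0,
    n_events >= 0, event_amplitude_sd >= 0,
    blink_rate >= 0, outlier_rate >= 0,
    onset_latency_range[1] <= onset_latency_range[2],
    time_to_peak_range[1] <= time_to_peak_range[2],
    span_range[1] <= span_range[2],
    onset_latency_range[2] < time_to_peak_range[1],
    time_to_peak_range[2] < span_range[1]
  )
  n <- duration * sampling_rate
  if (abs(n - round(n)) > 1e-9) {
    stop("duration * sampling_rate must be an integer sample count")
  }
  structure(
    as.list(environment()),
    class = "synthetic_params"
  )
}

#' Evoked-dilation kernel
#'
#' Unit-normalized time course of a hazard-evoked pupil dilation: zero
#' before the onset latency, a smooth monotone rise to 1 at the time to
#' peak, then a gradual return shaped as a raised-cosine envelope
#' modulated by decreasing oscillation waves, reaching below 0.05 of the
#' peak by the end of the span. Continuous everywhere.
#'
#' @param t_rel Seconds since the stimulus; values outside `[0, span]`
#'   return 0.
#' @param onset_latency Seconds from stimulus to dilation onset.
#' @param time_to_peak Seconds from stimulus to peak.
#' @param span Total transient duration, seconds.
#' @param return_waves Number of oscillation waves in the return phase.
#' @param return_decay Geometric amplitude decay per wave.
#' @return Amplitude multiplier in roughly `[-0.3, 1]` (the return phase
#'   undershoots, as an oscillatory relaxation does).
#' @export
event_kernel <- function(t_rel, onset_latency = 0.25, time_to_peak = 0.75,
                         span = 2.25, return_waves = 2,
                         return_decay = 0.5) {
  stopifnot(onset_latency < time_to_peak, time_to_peak < span)
  k <- numeric(length(t_rel))
  rise <- t_rel >= onset_latency & t_rel <= time_to_peak
  if (any(rise)) {
    u <- (t_rel[rise] - onset_latency) / (time_to_peak - onset_latency)
    k[rise] <- u^3 * (10 - 15 * u + 6 * u^2) # C2 monotone smoothstep
  }
  fall <- t_rel > time_to_peak & t_rel < span
  if (any(fall)) {
    s <- (t_rel[fall] - time_to_peak) / (span - time_to_peak)
    envelope <- 0.5 * (1 + cos(pi * s)) # gradual raised-cosine return, 1 -> 0
    # decreasing ripple waves on the return, geometric decay per wave
    depth <- return_decay^(return_waves * s + 1)
    k[fall] <- envelope * (1 - depth * (1 - cos(2 * pi * return_waves * s)) / 2)
  }
  k
}

#' Generate a synthetic pupil trace with ground truth
#'
#' Builds baseline + drift + band-limited fluctuation + white noise, adds
#' `n_events` non-overlapping evoked transients scaled to
#' `event_amplitude_sd` times the non-event SD, then overwrites blink runs
#' with zero size (`valid = FALSE`) and injects isolated gross outliers.
#' Fully reproducible from `seed`; the RNG state of the caller is left
#' untouched.
#'
#' @param params A [synthetic_params].
#' @return A list with `trace` ([pupil_trace]), `truth` (event onsets and
#'   peak times, blink sample ranges, outlier indices, the non-event SD),
#'   and `annotation` ([event_annotation] of the true onsets).
#' @export
generate_trace <- function(params = synthetic_params()) {
  p <- params
  n <- as.integer(round(p$duration * p$sampling_rate))
  dt <- 1 / p$sampling_rate
  t <- (seq_len(n) - 1L) * dt

  with_seed(p$seed, {
    # slow drift: sinusoids with random phases, amplitudes summing to
    # drift_amplitude, weighted toward the longest period
    drift <- numeric(n)
    if (p$drift_amplitude > 0 && length(p$drift_periods) > 0) {
      w <- p$drift_periods / sum(p$drift_periods)
      for (i in seq_along(p$drift_periods)) {
        drift <- drift + p$drift_amplitude * w[i] *
          sin(2 * pi * t / p$drift_periods[i] + stats::runif(1, 0, 2 * pi))
      }
    }

    # band-limited fluctuation: AR(1)-filtered white noise, rescaled to
    # the requested SD; the 6 s time constant concentrates power below
    # ~0.1 Hz, the band of slow spontaneous pupil oscillation (hippus)
    plr <- numeric(n)
    if (p$plr_amplitude > 0) {
      phi <- exp(-dt / 6)
      e <- stats::rnorm(n)
      plr <- as.numeric(stats::filter(e, phi, method = "recursive"))
      plr <- plr / stats::sd(plr) * p$plr_amplitude
    }

    noise <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else numeric(n)

    # the SD against which event amplitudes (and the detection gate) are
    # defined: the non-event, non-drift part of the signal
    base_sd <- stats::sd(plr + noise)
    if (!is.finite(base_sd) || base_sd == 0) base_sd <- 1

    # event placement: non-overlapping, clear of the acclimation trim
    events <- NULL
    evoked <- numeric(n)
    if (p$n_events > 0) {
      guard <- max(p$span_range) + 3.5 # transient + feature window clearance
      lo <- 60
      hi <- p$duration - guard
      if (hi - lo < p$n_events * 2 * guard) {
        stop("duration too short to host n_events non-overlapping transients")
      }
      repeat {
        onsets <- sort(stats::runif(p$n_events, lo, hi))
        if (p$n_events < 2 || min(diff(onsets)) > 2 * guard) break
      }
      lat <- stats::runif(p$n_events, p$onset_latency_range[1],
                          p$onset_latency_range[2])
      ttp <- stats::runif(p$n_events, p$time_to_peak_range[1],
                          p$time_to_peak_range[2])
      span <- stats::runif(p$n_events, p$span_range[1], p$span_range[2])
      amp <- p$event_amplitude_sd * base_sd
      for (i in seq_len(p$n_events)) {
        idx <- which(t >= onsets[i] & t <= onsets[i] + span[i])
        evoked[idx] <- evoked[idx] + amp * event_kernel(
          t[idx] - onsets[i], lat[i], ttp[i], span[i],
          p$return_waves, p$return_decay
        )
      }
      events <- data.frame(
        event_id = sprintf("H%d", seq_len(p$n_events)),
        onset = onsets, peak_time = onsets + ttp,
        onset_latency = lat, time_to_peak = ttp, span = span
      )
    }

    y <- p$baseline + drift + plr + noise + evoked
    valid <- rep(TRUE, n)

    # blinks: Poisson count, uniform 2-5 sample runs, size reported as 0
    blink_ranges <- NULL
    n_blinks <- stats::rpois(1, p$blink_rate * p$duration / 60)
    if (n_blinks > 0) {
      starts <- sort(sample.int(n - 6L, n_blinks))
      lens <- sample(2:5, n_blinks, replace = TRUE)
      blink_ranges <- data.frame(start = starts, end = pmin(starts + lens - 1L, n))
      for (i in seq_len(n_blinks)) {
        idx <- blink_ranges$start[i]:blink_ranges$end[i]
        y[idx] <- 0
        valid[idx] <- FALSE
      }
    }

    # gross outliers: isolated valid samples far off the local level
    outlier_idx <- integer(0)
    n_out <- stats::rpois(1, p$outlier_rate * p$duration / 60)
    if (n_out > 0) {
      cand <- which(valid)
      outlier_idx <- sort(sample(cand, min(n_out, length(cand))))
      shift <- sample(c(-1, 1), length(outlier_idx), replace = TRUE) *
        stats::runif(length(outlier_idx), 4, 8) * max(base_sd, 0.1 * p$baseline)
      y[outlier_idx] <- y[outlier_idx] + shift
    }

    trace <- pupil_trace(
      t, y, valid,
      subject_id = sprintf("SYN%d", p$seed),
      sampling_rate = p$sampling_rate,
      meta = list(signal = "diameter", source = "synthetic")
    )
    annotation <- event_annotation(
      trace$subject_id,
      onset = if (is.null(events)) numeric(0) else events$onset,
      event_id = if (is.null(events)) character(0) else events$event_id
    )
    list(
      trace = trace,
      truth = list(
        events = events, blink_ranges = blink_ranges,
        outlier_indices = outlier_idx, base_sd = base_sd,
        components = list(drift = drift)
      ),
      annotation = annotation
    )
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
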