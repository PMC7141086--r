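#' Preprocessing configuration
#'
#' Artifact-rejection and quality-control parameters. Defaults follow the
#' cleaning cascade for 25 Hz pupillometry: the first 30 s (acclimation)
#' are discarded; samples differing by more than 10\% from the preceding
#' valid value are rejected; two samples (40 ms at 25 Hz) on each side of
#' a blink are removed because a half-closed eyelid biases the detected
#' size; samples more than 3 trial standard deviations from the trial
#' mean are outliers; and a trial with less than 75\% valid data (with
#' interpolated samples counting as invalid) is excluded.
#'
#' @param trim_seconds Acclimation interval to discard, seconds.
#' @param jump_fraction Maximum relative change versus the last valid
#'   sample.
#' @param blink_margin_samples Samples removed before/after each blink run.
#' @param outlier_sd Statistical outlier threshold in trial SDs.
#' @param min_valid_fraction QC acceptance threshold (inclusive).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(trim_seconds = 30, jump_fraction = 0.10,
                              blink_margin_samples = 2, outlier_sd = 3.0,
                              min_valid_fraction = 0.75) {
  stopifnot(
    trim_seconds >= 0, jump_fraction > 0, jump_fraction < 1,
    blink_margin_samples >= 0, outlier_sd > 0,
    min_valid_fraction > 0, min_valid_fraction <= 1
  )
  structure(
    list(
      trim_seconds = trim_seconds, jump_fraction = jump_fraction,
      blink_margin_samples = as.integer(blink_margin_samples),
      outlier_sd = outlier_sd, min_valid_fraction = min_valid_fraction
    ),
    class = "preprocess_config"
  )
}

#' Discard the acclimation interval
#'
#' Removes all samples with `t < trim_seconds` and re-origins time to 0.
#' Event onsets must be shifted identically downstream (see
#' [shift_events]).
#'
#' @param trace A [pupil_trace].
#' @param config A [preprocess_config].
#' @return The trimmed trace.
#' @export
trim_acclimation <- function(trace, config = preprocess_config()) {
  if (config$trim_seconds == 0) return(trace)
  keep <- trace$t >= config$trim_seconds
  if (!any(keep)) {
    stop(sprintf(
      "trace (%.1f s) shorter than the %g s trim window",
      diff(range(trace$t)), config$trim_seconds
    ))
  }
  pupil_trace(
    trace$t[keep] - config$trim_seconds, trace$y[keep], trace$valid[keep],
    subject_id = trace$subject_id, sampling_rate = trace$sampling_rate,
    meta = trace$meta
  )
}

#' Flag artifact samples
#'
#' Applies the rejection rules in fixed precedence: (1) input-invalid
#' samples (blinks / tracking losses, reported as zero or non-finite
#' size); (2) a margin of `blink_margin_samples` on each side of every
#' invalid run; (3) samples whose value differs from the last still-valid
#' value by more than `jump_fraction` relatively (the reference does not
#' advance past a rejected sample, so one bad sample cannot invalidate
#' the rest of the trial); (4) samples more than `outlier_sd` standard
#' deviations from the trial mean, with mean and SD computed once over
#' the samples that survived rules 1-3.
#'
#' @param trace A [pupil_trace].
#' @param config A [preprocess_config].
#' @return A list with `valid` (the final mask) and `report`, a
#'   `preprocess_report` with per-rule counts (`n_blink`, `n_margin`,
#'   `n_jump`, `n_outlier`, non-overlapping by the precedence above),
#'   `n_interpolated`, `valid_fraction`.
#' @export
flag_invalid <- function(trace, config = preprocess_config()) {
  n <- length(trace$y)
  y <- trace$y
  blink <- !trace$valid

  # blink margins around each invalid run
  margin <- rep(FALSE, n)
  if (config$blink_margin_samples > 0 && any(blink)) {
    r <- rle(blink)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      lo <- max(1L, starts[i] - config$blink_margin_samples)
      hi <- min(n, ends[i] + config$blink_margin_samples)
      margin[lo:hi] <- TRUE
    }
    margin <- margin & !blink
  }

  # relative jump versus the last still-valid sample
  jump <- rep(FALSE, n)
  ref <- NA_real_
  pre_ok <- !blink & !margin
  for (i in seq_len(n)) {
    if (!pre_ok[i]) next
    if (is.na(ref)) {
      ref <- y[i]
      next
    }
    if (abs(y[i] - ref) / abs(ref) > config$jump_fraction) {
      jump[i] <- TRUE
    } else {
      ref <- y[i]
    }
  }

  # single-pass statistical outliers on the cleaned samples
  clean <- pre_ok & !jump
  outlier <- rep(FALSE, n)
  if (sum(clean) >= 2) {
    m <- mean(y[clean])
    s <- stats::sd(y[clean])
    if (is.finite(s) && s > 0) {
      outlier[clean] <- abs(y[clean] - m) > config$outlier_sd * s
    }
  }

  valid <- clean & !outlier
  report <- structure(
    list(
      n_total = n,
      n_blink = sum(blink),
      n_margin = sum(margin),
      n_jump = sum(jump),
      n_outlier = sum(outlier),
      n_interpolated = n - sum(valid),
      valid_fraction = if (n > 0) sum(valid) / n else 0,
      accepted = NA
    ),
    class = "preprocess_report"
  )
  report$accepted <- qc_accept(report, config)
  list(valid = valid, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<preprocess_report> %d samples: %d blink, %d margin, %d jump, ",
      "%d outlier -> %.1f%% valid (%s)\n"
    ),
    x$n_total, x$n_blink, x$n_margin, x$n_jump, x$n_outlier,
    100 * x$valid_fraction, if (isTRUE(x$accepted)) "accepted" else "rejected"
  ))
  invisible(x)
}

#' Fill invalid samples by linear interpolation
#'
#' Every invalid sample is replaced by the linear interpolant between its
#' nearest valid neighbors; invalid runs at the head or tail are filled by
#' constant extension of the nearest valid value. The output trace has no
#' non-finite values and keeps the original mask (interpolated samples
#' remain marked invalid for QC accounting).
#'
#' @param trace A [pupil_trace].
#' @param valid Logical mask to use; defaults to the trace's own.
#' @return The trace with `y` continuous.
#' @export
interpolate_gaps <- function(trace, valid = trace$valid) {
  y <- trace$y
  if (sum(valid) < 2) stop("need at least 2 valid samples to interpolate")
  if (all(valid)) return(trace)
  filled <- stats::approx(
    x = trace$t[valid], y = y[valid], xout = trace$t,
    method = "linear", rule = 2 # constant extension at the boundaries
  )$y
  out <- trace
  out$y <- filled
  out$valid <- valid
  out
}

#' Quality-control acceptance
#'
#' A trial is kept iff its valid fraction (interpolated samples counting
#' as invalid) reaches `min_valid_fraction`; the boundary is inclusive.
#'
#' @param report A `preprocess_report` from [flag_invalid].
#' @param config A [preprocess_config].
#' @return `TRUE` or `FALSE`.
#' @export
qc_accept <- function(report, config = preprocess_config()) {
  report$valid_fraction >= config$min_valid_fraction
}

#' Run the full preprocessing stage on one trace
#'
#' Trim, flag, interpolate, QC — in that order. The returned annotation
#' (if given) is shifted to the trimmed clock.
#'
#' @param trace A [pupil_trace].
#' @param config A [preprocess_config].
#' @param annotation Optional [event_annotation] on the raw clock.
#' @return A list with `trace` (cleaned, continuous), `report`,
#'   `annotation` (shifted, or `NULL`), `accepted`.
#' @export
preprocess_trace <- function(trace, config = preprocess_config(),
                             annotation = NULL) {
  trimmed <- trim_acclimation(trace, config)
  fl <- flag_invalid(trimmed, config)
  cleaned <- interpolate_gaps(trimmed, fl$valid)
  if (!is.null(annotation)) {
    annotation <- shift_events(annotation, config$trim_seconds)
  }
  list(
    trace = cleaned, report = fl$report, annotation = annotation,
    accepted = fl$report$accepted
  )
}
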