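#' Construct a pupil trace
#'
#' A `pupil_trace` holds one trial of timestamped pupil-size samples on a
#' uniform grid, together with a per-sample validity mask. Pupil "size" may
#' be a diameter or an area; the pipeline is unit-agnostic because every
#' threshold downstream is expressed in per-trial standard deviations or as
#' a relative change, so the unit is only carried as metadata.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing
#'   on a uniform grid.
#' @param y Numeric vector of pupil sizes (arbitrary units), same length as
#'   `t`. Invalid samples may be `NA`.
#' @param valid Logical mask, same length as `y`. If `NULL`, samples are
#'   valid where `y` is finite and strictly positive (a reported size of 0
#'   is a tracking loss).
#' @param subject_id Opaque subject/trial identifier.
#' @param sampling_rate Samples per second; must match the grid of `t`
#'   within 1\%.
#' @param meta Named list of free-form metadata (e.g. `signal = "area"`).
#'
#' @return An object of class `pupil_trace`: a list with elements `t`, `y`,
#'   `valid`, `subject_id`, `sampling_rate`, `meta`.
#' @export
pupil_trace <- function(t, y, valid = NULL, subject_id = "unknown",
                        sampling_rate = 25, meta = list()) {
  t <- as.numeric(t)
  y <- as.numeric(y)
  if (length(t) != length(y)) {
    stop("t and y must have the same length")
  }
  if (length(t) >= 2) {
    dt <- diff(t)
    if (any(dt <= 0)) {
      stop("timestamps must be strictly increasing")
    }
    if (max(dt) - min(dt) > 1e-9 + 1e-6 * mean(dt)) {
      stop("timestamps must lie on a uniform grid")
    }
    observed_rate <- 1 / mean(dt)
    if (abs(observed_rate - sampling_rate) > 0.01 * sampling_rate) {
      stop(sprintf(
        "sampling-rate mismatch: declared %g Hz, observed %.4g Hz",
        sampling_rate, observed_rate
      ))
    }
  }
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (is.null(valid)) {
    valid <- is.finite(y) & y > 0
  }
  valid <- as.logical(valid)
  if (length(valid) != length(y)) {
    stop("valid mask must have the same length as y")
  }
  if (any(valid & !is.finite(y))) {
    stop("y must be finite wherever valid is TRUE")
  }
  structure(
    list(
      t = t, y = y, valid = valid,
      subject_id = as.character(subject_id),
      sampling_rate = sampling_rate,
      meta = meta
    ),
    class = "pupil_trace"
  )
}

#' @export
print.pupil_trace <- function(x, ...) {
  n <- length(x$y)
  cat(sprintf(
    "<pupil_trace> subject %s: %d samples at %g Hz (%.1f s), %.1f%% valid\n",
    x$subject_id, n, x$sampling_rate,
    if (n > 0) n / x$sampling_rate else 0,
    if (n > 0) 100 * mean(x$valid) else NA_real_
  ))
  invisible(x)
}

#' @export
length.pupil_trace <- function(x) length(x$y)

#' Read a pupil trace from a delimited text file
#'
#' Expects a header naming at least a time column (`t` or `time`) and a
#' pupil-size column (`y`, `pupil`, or `size`); an optional `valid` column
#' holds 0/1 flags. When no validity column is present, samples are valid
#' where the size is finite and strictly positive.
#'
#' @param path File path (CSV, `.` decimal separator).
#' @param sampling_rate Declared sampling rate in Hz; a grid deviating from
#'   it by more than 1\% is an error.
#' @param subject_id Identifier attached to the trace; defaults to the file
#'   name without extension.
#' @return A [pupil_trace].
#' @export
read_trace <- function(path, sampling_rate = 25, subject_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  tcol <- intersect(c("t", "time"), names(df))[1]
  ycol <- intersect(c("y", "pupil", "size"), names(df))[1]
  if (is.na(tcol) || is.na(ycol)) {
    stop("trace file must have time (t/time) and size (y/pupil/size) columns")
  }
  valid <- if ("valid" %in% names(df)) as.logical(df$valid) else NULL
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (!is.null(valid)) valid <- valid & is.finite(df[[ycol]])
  pupil_trace(df[[tcol]], df[[ycol]],
    valid = valid, subject_id = subject_id,
    sampling_rate = sampling_rate, meta = list(source = path)
  )
}

#' Write a pupil trace to CSV
#'
#' Columns `t,y,valid`; invalid non-finite samples are written as empty
#' fields so the grid stays uniform on disk.
#'
#' @param trace A [pupil_trace].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(
    t = trace$t, y = trace$y, valid = as.integer(trace$valid)
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Construct an event annotation
#'
#' Ground-truth hazard onsets for one subject/trial, on the same clock as
#' the trace (seconds from recording start). The optional adequacy flag
#' mirrors an external judgment of the behavioral response; it is carried
#' through but never computed.
#'
#' @param subject_id Subject identifier.
#' @param onset Numeric vector of event onset times in seconds.
#' @param event_id Character vector of unique event identifiers.
#' @param adequate Optional logical vector of response-adequacy labels.
#' @return An object of class `event_annotation` with events sorted by
#'   onset (stable for ties).
#' @export
event_annotation <- function(subject_id, onset, event_id = NULL,
                             adequate = NULL) {
  onset <- as.numeric(onset)
  n <- length(onset)
  if (is.null(event_id)) event_id <- if (n) sprintf("H%d", seq_len(n)) else character(0)
  event_id <- as.character(event_id)
  if (length(event_id) != n) stop("event_id must match onset length")
  if (anyDuplicated(event_id)) stop("duplicate event_id within a trial")
  if (is.null(adequate)) adequate <- rep(NA, n)
  ord <- order(onset) # order() is a stable sort
  structure(
    list(
      subject_id = as.character(subject_id),
      events = data.frame(
        event_id = event_id[ord], onset = onset[ord],
        adequate = as.logical(adequate)[ord],
        stringsAsFactors = FALSE
      )
    ),
    class = "event_annotation"
  )
}

#' @export
print.event_annotation <- function(x, ...) {
  cat(sprintf(
    "<event_annotation> subject %s: %d events\n",
    x$subject_id, nrow(x$events)
  ))
  invisible(x)
}

#' Read event annotations from CSV
#'
#' Columns `subject,event,onset[,adequate]`. Returns a named list of
#' [event_annotation] objects, one per subject.
#'
#' @param path File path.
#' @return Named list of `event_annotation`.
#' @export
read_events <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(df) || nrow(df) == 0) {
    warning("empty event file: ", path)
    return(list())
  }
  names(df) <- tolower(names(df))
  need <- c("subject", "event", "onset")
  if (!all(need %in% names(df))) {
    stop("event file must have columns subject,event,onset")
  }
  if (!"adequate" %in% names(df)) df$adequate <- NA
  out <- lapply(split(df, df$subject), function(d) {
    event_annotation(d$subject[1], d$onset, d$event, as.logical(d$adequate))
  })
  out
}

#' Write event annotations to CSV
#'
#' @param annotations A single [event_annotation] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(annotations, path) {
  if (inherits(annotations, "event_annotation")) {
    annotations <- list(annotations)
  }
  rows <- do.call(rbind, lapply(annotations, function(a) {
    if (nrow(a$events) == 0) return(NULL)
    data.frame(
      subject = a$subject_id, event = a$events$event_id,
      onset = a$events$onset, adequate = as.integer(a$events$adequate),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(rows)) {
    rows <- data.frame(
      subject = character(0), event = character(0),
      onset = numeric(0), adequate = integer(0)
    )
  }
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Shift event onsets by a constant
#'
#' Used when the acclimation trim re-origins the trace clock.
#'
#' @param annotation An [event_annotation].
#' @param by Seconds to subtract from every onset.
#' @return The shifted annotation; events with negative onsets are dropped.
#' @export
shift_events <- function(annotation, by) {
  ev <- annotation$events
  ev$onset <- ev$onset - by
  keep <- ev$onset >= 0
  event_annotation(
    annotation$subject_id, ev$onset[keep], ev$event_id[keep],
    ev$adequate[keep]
  )
}
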