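#' Extract the 7-component wavelet feature vector for one candidate peak
#'
#' A temporal window of 1.5 s before and after the peak (75 samples at
#' 25 Hz: 37 + peak + 37) is cut from the detrended signal and decomposed
#' with db4 wavelets up to level 4. Amplitude, mean and area are computed
#' from the time-domain reconstruction of the A4 approximation within the
#' window (amplitude = A4 maximum minus A4 window minimum; area =
#' trapezoidal integral of A4 above its window minimum); the remaining
#' four features are the relative energies of the detail bands D1-D4.
#'
#' @param trace A detrended [pupil_trace] or numeric vector.
#' @param peak_index Sample index of the candidate peak.
#' @param window_seconds Half-window, seconds (default 1.5).
#' @param sampling_rate Used when `trace` is a plain vector.
#' @return A one-row data frame `amplitude`, `mean`, `area`, `re_d1` ..
#'   `re_d4`, or `NULL` when the window extends beyond the trace (such a
#'   candidate is dropped, never zero-padded).
#' @export
extract_features <- function(trace, peak_index, window_seconds = 1.5,
                             sampling_rate = 25) {
  if (inherits(trace, "pupil_trace")) {
    y <- trace$y
    sampling_rate <- trace$sampling_rate
  } else {
    y <- as.numeric(trace)
  }
  half_n <- floor(window_seconds * sampling_rate) # 37 at 1.5 s, 25 Hz
  lo <- peak_index - half_n
  hi <- peak_index + half_n
  if (lo < 1 || hi > length(y)) return(NULL)
  w <- y[lo:hi]
  dec <- dwt_decompose(w, wavelet_name = "db4", level = 4,
                       boundary_mode = "symmetric")
  a4 <- dwt_reconstruct_band(dec, "A_4")
  en <- band_energies(dec)
  dt <- 1 / sampling_rate
  base <- min(a4)
  rel <- a4 - base
  area <- sum((rel[-1] + rel[-length(rel)]) / 2) * dt # trapezoid rule
  data.frame(
    amplitude = max(a4) - base,
    mean = mean(a4),
    area = area,
    re_d1 = en$rel_detail[[1]],
    re_d2 = en$rel_detail[[2]],
    re_d3 = en$rel_detail[[3]],
    re_d4 = en$rel_detail[[4]]
  )
}

#' Build the feature table for a set of candidates
#'
#' @param trace Detrended [pupil_trace].
#' @param candidates Data frame from [detect_peaks] (needs `peak_index`,
#'   `peak_time`).
#' @param window_seconds Half-window for [extract_features].
#' @return Data frame with `subject`, `peak_time`, the 7 features, and
#'   `peak_index`; candidates whose window leaves the trace are dropped.
#' @export
peak_feature_table <- function(trace, candidates, window_seconds = 1.5) {
  subject <- if (inherits(trace, "pupil_trace")) trace$subject_id else "unknown"
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    f <- extract_features(trace, candidates$peak_index[i], window_seconds)
    if (is.null(f)) return(NULL)
    cbind(
      data.frame(
        subject = subject,
        peak_index = candidates$peak_index[i],
        peak_time = candidates$peak_time[i],
        stringsAsFactors = FALSE
      ),
      f
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(
      subject = character(0), peak_index = integer(0),
      peak_time = numeric(0), amplitude = numeric(0), mean = numeric(0),
      area = numeric(0), re_d1 = numeric(0), re_d2 = numeric(0),
      re_d3 = numeric(0), re_d4 = numeric(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}

#' Label candidates against hazard annotations
#'
#' A candidate is a hazard iff its peak time falls within
#' `[onset, onset + tolerance]` of an annotated event; per event only the
#' earliest matching candidate is labeled hazard (each event is matched at
#' most once) and every other candidate is noise.
#'
#' @param candidates Data frame with a `peak_time` column (same clock as
#'   the annotation).
#' @param annotation An [event_annotation].
#' @param tolerance Matching window after onset, seconds (default 2.5,
#'   the expected duration of the evoked response).
#' @return A list: `candidates` (input plus `label` = "hazard"/"noise"
#'   and `matched_event`), and `unmatched_events` (event ids with no
#'   matching candidate — missed detections).
#' @export
label_candidates <- function(candidates, annotation, tolerance = 2.5) {
  lab <- rep("noise", nrow(candidates))
  matched <- rep(NA_character_, nrow(candidates))
  unmatched <- character(0)
  ev <- annotation$events
  for (k in seq_len(nrow(ev))) {
    onset <- ev$onset[k]
    hit <- which(
      candidates$peak_time >= onset &
        candidates$peak_time <= onset + tolerance &
        lab == "noise" & is.na(matched)
    )
    if (length(hit) == 0) {
      unmatched <- c(unmatched, ev$event_id[k])
    } else {
      first <- hit[which.min(candidates$peak_time[hit])]
      lab[first] <- "hazard"
      matched[first] <- ev$event_id[k]
    }
  }
  candidates$label <- lab
  candidates$matched_event <- matched
  list(candidates = candidates, unmatched_events = unmatched)
}
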