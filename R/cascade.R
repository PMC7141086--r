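#' Run the full dilation-detection cascade over a cohort
#'
#' The central entry point of the package: for every subject the trace is
#' trimmed, artifact-flagged, interpolated and quality-controlled; the
#' slow drift is removed by wavelet approximation subtraction; candidate
#' dilation peaks are detected on the detrended signal, characterized by
#' parabola/FWHM fits and turned into 7-component wavelet feature
#' vectors; candidates are labeled against the annotated hazard onsets;
#' and an RBF-SVM is evaluated by leave-one-subject-out cross-validation.
#'
#' @param traces List of [pupil_trace] objects (one per subject/trial).
#' @param annotations List of [event_annotation] objects, matched to
#'   `traces` by subject id (names or order).
#' @param preprocess A [preprocess_config].
#' @param peaks A [peak_config].
#' @param classifier A [classifier_config].
#' @param trend_level Wavelet detrending depth (default 9; see
#'   [dwt_detrend]).
#' @param label_tolerance Seconds after onset within which a candidate
#'   matches an event (default 2.5).
#' @return An object of class `pupil_cascade`: `report`
#'   (an `evaluation_report`), `features` (pooled labeled candidate
#'   table), `folds`, `qc` (per-subject preprocessing reports),
#'   `rejected` (QC-failed subject ids), `unmatched_events`, `detrended`
#'   traces, configs, and `final_model` (an SVM trained on all accepted
#'   subjects, for scoring new data).
#' @export
#' @examples
#' sims <- lapply(1:3, function(s) {
#'   generate_trace(synthetic_params(duration = 600, n_events = 4, seed = s))
#' })
#' fit <- pupil_cascade(
#'   traces = lapply(sims, `[[`, "trace"),
#'   annotations = lapply(sims, `[[`, "annotation")
#' )
#' print(fit)
pupil_cascade <- function(traces, annotations,
                          preprocess = preprocess_config(),
                          peaks = peak_config(),
                          classifier = classifier_config(),
                          trend_level = 9,
                          label_tolerance = 2.5) {
  ids <- vapply(traces, `[[`, "", "subject_id")
  ann_ids <- vapply(annotations, `[[`, "", "subject_id")
  if (!setequal(ids, ann_ids)) {
    stop("traces and annotations must cover the same subjects")
  }
  annotations <- annotations[match(ids, ann_ids)]

  qc <- list()
  rejected <- character(0)
  detrended <- list()
  feats <- list()
  unmatched <- list()
  for (i in seq_along(traces)) {
    s <- ids[i]
    pp <- preprocess_trace(traces[[i]], preprocess, annotations[[i]])
    qc[[s]] <- pp$report
    if (!pp$accepted) {
      rejected <- c(rejected, s)
      next
    }
    det <- dwt_detrend(pp$trace, trend_level = trend_level)
    detrended[[s]] <- det$detrended
    cand <- detect_peaks(det$detrended, peaks)
    ft <- peak_feature_table(det$detrended, cand)
    lab <- label_candidates(ft, pp$annotation, tolerance = label_tolerance)
    feats[[s]] <- lab$candidates
    unmatched[[s]] <- lab$unmatched_events
  }
  if (length(feats) < 2) {
    stop("fewer than 2 subjects passed QC; cannot cross-validate")
  }
  dataset <- do.call(rbind, unname(feats))
  folds <- loso_cv(dataset, classifier)
  report <- evaluate_folds(folds, unmatched)

  bal <- oversample_minority(
    dataset[, .feature_cols, drop = FALSE], dataset$label,
    seed = classifier$oversample_seed
  )
  final_model <- train_svm(bal$features, bal$labels, classifier)

  structure(
    list(
      report = report, features = dataset, folds = folds,
      qc = qc, rejected = rejected, unmatched_events = unmatched,
      detrended = detrended, final_model = final_model,
      config = list(
        preprocess = preprocess, peaks = peaks, classifier = classifier,
        trend_level = trend_level, label_tolerance = label_tolerance
      )
    ),
    class = "pupil_cascade"
  )
}

#' @export
print.pupil_cascade <- function(x, ...) {
  cat(sprintf(
    "<pupil_cascade> %d subjects (%d rejected by QC), %d candidates\n",
    length(x$qc), length(x$rejected), nrow(x$features)
  ))
  print(x$report)
  invisible(x)
}

#' @export
summary.pupil_cascade <- function(object, ...) {
  x <- object
  cat("Dilation-detection cascade — leave-one-subject-out evaluation\n\n")
  cat(sprintf(
    "Subjects: %d accepted, %d rejected by the %.0f%% validity rule\n",
    length(x$qc) - length(x$rejected), length(x$rejected),
    100 * x$config$preprocess$min_valid_fraction
  ))
  cat(sprintf(
    "Candidates: %d (%d hazard-labeled, %d noise)\n",
    nrow(x$features), sum(x$features$label == "hazard"),
    sum(x$features$label == "noise")
  ))
  print(x$report)
  cat("\nPer-subject candidate (D) and false-positive (F) counts:\n")
  print(x$report$candidate_counts, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pupil_cascade <- function(x, ...) {
  roc <- x$report$roc
  graphics::plot(
    roc$fpr, roc$tpr,
    type = "s", xlim = c(0, 1), ylim = c(0, 1),
    xlab = "False positive rate", ylab = "True positive rate",
    main = sprintf("Candidate-level ROC (AUC = %.3f)", x$report$auc), ...
  )
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Score candidates of a new subject with the cohort model
#'
#' @param object A fitted `pupil_cascade`.
#' @param trace A raw [pupil_trace] for the new subject.
#' @param ... Unused.
#' @return Data frame of the new subject's candidates with features,
#'   decision scores and predicted labels, or an empty frame if the trace
#'   fails QC.
#' @export
predict.pupil_cascade <- function(object, trace, ...) {
  pp <- preprocess_trace(trace, object$config$preprocess)
  if (!pp$accepted) {
    warning("trace rejected by QC (valid fraction ",
      sprintf("%.2f", pp$report$valid_fraction), ")")
    return(object$features[0, ])
  }
  det <- dwt_detrend(pp$trace, trend_level = object$config$trend_level)
  cand <- detect_peaks(det$detrended, object$config$peaks)
  ft <- peak_feature_table(det$detrended, cand)
  if (nrow(ft) == 0) return(ft)
  pred <- predict(object$final_model, ft)
  cbind(ft, pred)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report` (or a `pupil_cascade`, whose
#'   report is used).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "pupil_cascade")) report <- report$report
  out <- list(
    pooled = report$pooled,
    event_level = report$event_level,
    auc = report$auc,
    per_subject = lapply(report$per_subject, function(p) {
      p[c(
        "subject", "tp", "fp", "tn", "fn", "sensitivity", "specificity",
        "precision", "n_candidates", "n_false_positives",
        "n_unmatched_events"
      )]
    }),
    roc = report$roc
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
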