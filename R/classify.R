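#' Classifier configuration
#'
#' An RBF-kernel support vector machine separates hazard-evoked from
#' spurious candidate peaks. Features are z-scored with training-fold
#' statistics before the kernel (the 7 features mix units); the minority
#' class (hazards) is oversampled to parity inside each training fold.
#'
#' @param C Soft-margin regularization (default 10, selected by
#'   leave-one-subject-out model selection on synthetic cohorts during
#'   development).
#' @param gamma RBF kernel width; `NULL` (default) uses
#'   `1 / (n_features * var(features))`, computed on the standardized
#'   training matrix.
#' @param oversample_seed Seed for minority oversampling.
#' @param standardize Z-score features with training statistics
#'   (default `TRUE`).
#' @param decision_threshold Score cut for the hazard call (default 0;
#'   swept for the ROC).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(C = 10, gamma = NULL, oversample_seed = 1L,
                              standardize = TRUE, decision_threshold = 0) {
  stopifnot(C > 0, is.null(gamma) || gamma > 0)
  structure(
    list(
      C = C, gamma = gamma, oversample_seed = as.integer(oversample_seed),
      standardize = standardize, decision_threshold = decision_threshold
    ),
    class = "classifier_config"
  )
}

.feature_cols <- c(
  "amplitude", "mean", "area", "re_d1", "re_d2", "re_d3", "re_d4"
)

#' Oversample the minority class to parity
#'
#' Rows of the minority class are duplicated uniformly at random with
#' replacement until both classes have equal counts; majority rows are
#' untouched and the set of distinct minority points never changes.
#'
#' @param features Data frame or matrix of feature rows.
#' @param labels Character/factor vector with two classes.
#' @param seed RNG seed (caller's stream is restored).
#' @return A list `features`, `labels` with balanced classes.
#' @export
oversample_minority <- function(features, labels, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  classes <- names(tab)
  if (length(classes) < 2) {
    stop(
      "both classes must be present; missing: ",
      paste(setdiff(c("hazard", "noise"), classes), collapse = ", ")
    )
  }
  if (tab[1] == tab[2]) return(list(features = features, labels = labels))
  minority <- classes[which.min(tab)]
  deficit <- abs(diff(as.integer(tab)))
  min_idx <- which(labels == minority)
  extra <- with_seed(seed, sample(min_idx, deficit, replace = TRUE))
  keep <- c(seq_along(labels), extra)
  list(
    features = features[keep, , drop = FALSE],
    labels = labels[keep]
  )
}

# z-score columns with given (training) stats; zero-variance features map
# to 0 with a warning
.standardize <- function(x, center, scale) {
  x <- as.matrix(x)
  degenerate <- !is.finite(scale) | scale == 0
  if (any(degenerate)) {
    warning(
      "zero-variance feature(s) standardized to 0: ",
      paste(colnames(x)[degenerate], collapse = ", ")
    )
    scale[degenerate] <- 1
    x[, degenerate] <- center[degenerate] # becomes 0 after centering
  }
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Train the hazard/noise SVM
#'
#' Fits an RBF support vector machine on a (balanced) training set. The
#' model exposes a real-valued decision score per input, oriented so
#' larger scores mean "hazard".
#'
#' @param features Data frame/matrix of training rows (the 7 features).
#' @param labels Vector with values `"hazard"` / `"noise"`.
#' @param config A [classifier_config].
#' @return A list of class `peak_svm`: the fitted `e1071::svm` model plus
#'   the standardization statistics and score orientation.
#' @export
train_svm <- function(features, labels, config = classifier_config()) {
  x <- as.matrix(features[, .feature_cols[.feature_cols %in% colnames(features)],
    drop = FALSE
  ])
  if (ncol(x) == 0) x <- as.matrix(features)
  labels <- factor(as.character(labels), levels = c("hazard", "noise"))
  if (any(is.na(labels))) stop("labels must be 'hazard' or 'noise'")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  if (config$standardize) {
    xs <- .standardize(x, center, scale)
  } else {
    xs <- x
  }
  gamma <- config$gamma
  if (is.null(gamma)) {
    v <- stats::var(as.vector(xs))
    gamma <- 1 / (ncol(xs) * if (is.finite(v) && v > 0) v else 1)
  }
  model <- e1071::svm(
    x = xs, y = labels, kernel = "radial", cost = config$C,
    gamma = gamma, scale = FALSE
  )
  # orient decision values so hazard scores are positive
  flip <- if (model$labels[1] == which(levels(labels) == "hazard")) 1 else -1
  structure(
    list(
      model = model, center = center, scale = scale,
      standardize = config$standardize, flip = flip, gamma = gamma,
      config = config
    ),
    class = "peak_svm"
  )
}

#' Decision scores and predicted labels for new candidates
#'
#' @param object A `peak_svm` from [train_svm].
#' @param newdata Feature rows.
#' @param threshold Score cut; defaults to the training config's.
#' @param ... Unused.
#' @return Data frame `score`, `predicted` (`"hazard"`/`"noise"`).
#' @export
predict.peak_svm <- function(object, newdata,
                             threshold = object$config$decision_threshold,
                             ...) {
  x <- as.matrix(newdata[, .feature_cols[.feature_cols %in% colnames(newdata)],
    drop = FALSE
  ])
  if (ncol(x) == 0) x <- as.matrix(newdata)
  if (object$standardize) {
    x <- suppressWarnings(.standardize(x, object$center, object$scale))
  }
  pr <- stats::predict(object$model, x, decision.values = TRUE)
  score <- object$flip * as.numeric(attr(pr, "decision.values"))
  data.frame(
    score = score,
    predicted = ifelse(score > threshold, "hazard", "noise"),
    stringsAsFactors = FALSE
  )
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the fold's model is trained on every other
#' subject's candidates (minority-oversampled and standardized with
#' training-fold statistics only) and scores the held-out subject's
#' candidates. The union of held-out predictions covers every candidate
#' exactly once. A fold whose training set lacks a class is skipped with
#' a warning.
#'
#' @param dataset Data frame of labeled candidates: `subject`, the 7
#'   feature columns, `label`.
#' @param config A [classifier_config].
#' @return A list of fold results, each with `held_out_subject`,
#'   `predictions` (the held-out rows plus `score`, `predicted`).
#' @export
loso_cv <- function(dataset, config = classifier_config()) {
  subjects <- unique(dataset$subject)
  if (length(subjects) < 2) stop("need at least 2 subjects for LOSO CV")
  folds <- lapply(subjects, function(s) {
    train <- dataset[dataset$subject != s, , drop = FALSE]
    test <- dataset[dataset$subject == s, , drop = FALSE]
    if (length(unique(train$label)) < 2) {
      warning("fold for subject ", s, " skipped: training set lacks a class")
      return(NULL)
    }
    # canonical row order, so results do not depend on how the caller
    # ordered subjects or rows (oversampling draws row positions)
    keys <- intersect(c("subject", "peak_time", .feature_cols), names(train))
    train <- train[do.call(order, unname(train[keys])), , drop = FALSE]
    bal <- oversample_minority(
      train[, .feature_cols, drop = FALSE], train$label,
      seed = config$oversample_seed
    )
    model <- train_svm(bal$features, bal$labels, config)
    pred <- predict(model, test)
    test$score <- pred$score
    test$predicted <- pred$predicted
    list(held_out_subject = s, predictions = test)
  })
  folds[!vapply(folds, is.null, logical(1))]
}

#' Confusion-matrix metrics
#'
#' @param tp,fp,tn,fn Counts.
#' @return List with `sensitivity`, `specificity`, `precision`; a metric
#'   with zero denominator is `NA` (undefined), never 0.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    precision = rate(tp, tp + fp)
  )
}

#' ROC curve from decision scores
#'
#' Sweeps the decision threshold over every observed score (plus a
#' sentinel above the maximum), yielding a step curve from (0,0) to
#' (1,1). AUC is computed by the trapezoid rule.
#'
#' @param scores Numeric decision scores (larger = more hazard-like).
#' @param truth Logical or `"hazard"`/`"noise"` ground truth.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, truth) {
  if (!is.logical(truth)) truth <- as.character(truth) == "hazard"
  pos <- sum(truth)
  neg <- sum(!truth)
  thr <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(th) {
    if (pos > 0) sum(scores >= th & truth) / pos else NA_real_
  }, numeric(1))
  fpr <- vapply(thr, function(th) {
    if (neg > 0) sum(scores >= th & !truth) / neg else NA_real_
  }, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- if (pos > 0 && neg > 0) {
    sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  } else {
    NA_real_
  }
  list(roc = roc, auc = auc)
}

#' Evaluate LOSO folds into a report
#'
#' Candidate-level confusion counts come from the labeled candidates
#' (tp = hazard candidates called hazard, etc.). Event-level sensitivity
#' additionally counts annotated events with no matching candidate as
#' false negatives, because the quantity of interest is perception of
#' the event, not of the candidate. Both views are reported, together
#' with per-subject false-positive (`F`) and candidate (`D`) counts and
#' the candidate-level ROC.
#'
#' @param folds Result of [loso_cv].
#' @param unmatched_events Named list: subject -> character vector of
#'   event ids with no matching candidate.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_folds <- function(folds, unmatched_events = list()) {
  all_pred <- do.call(rbind, lapply(folds, `[[`, "predictions"))
  per_subject <- lapply(folds, function(f) {
    p <- f$predictions
    s <- f$held_out_subject
    tp <- sum(p$label == "hazard" & p$predicted == "hazard")
    fp <- sum(p$label == "noise" & p$predicted == "hazard")
    tn <- sum(p$label == "noise" & p$predicted == "noise")
    fn <- sum(p$label == "hazard" & p$predicted == "noise")
    miss <- length(unmatched_events[[s]])
    c(
      confusion_metrics(tp, fp, tn, fn),
      list(
        subject = s,
        n_candidates = nrow(p), # D in the per-subject table
        n_false_positives = fp, # F
        n_unmatched_events = miss
      )
    )
  })
  tp <- sum(vapply(per_subject, `[[`, 0, "tp"))
  fp <- sum(vapply(per_subject, `[[`, 0, "fp"))
  tn <- sum(vapply(per_subject, `[[`, 0, "tn"))
  fn <- sum(vapply(per_subject, `[[`, 0, "fn"))
  miss <- sum(vapply(per_subject, `[[`, 0, "n_unmatched_events"))
  pooled <- confusion_metrics(tp, fp, tn, fn)
  event_level <- confusion_metrics(tp, fp, tn, fn + miss)
  rc <- roc_curve(all_pred$score, all_pred$label)
  structure(
    list(
      per_subject = per_subject,
      pooled = pooled,
      event_level = event_level,
      roc = rc$roc, auc = rc$auc,
      candidate_counts = data.frame(
        subject = vapply(per_subject, `[[`, "", "subject"),
        F = vapply(per_subject, `[[`, 0, "n_false_positives"),
        D = vapply(per_subject, `[[`, 0, "n_candidates"),
        stringsAsFactors = FALSE
      ),
      predictions = all_pred
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "undef", sprintf("%.3f", v))
  cat("<evaluation_report>\n")
  cat(sprintf(
    "  candidate level: sens %s, spec %s, prec %s (tp %d fp %d tn %d fn %d)\n",
    fmt(x$pooled$sensitivity), fmt(x$pooled$specificity),
    fmt(x$pooled$precision), x$pooled$tp, x$pooled$fp, x$pooled$tn,
    x$pooled$fn
  ))
  cat(sprintf(
    "  event level:     sens %s (missed events counted as fn)\n",
    fmt(x$event_level$sensitivity)
  ))
  cat(sprintf("  ROC AUC: %s over %d candidates, %d subjects\n",
    fmt(x$auc), nrow(x$predictions), length(x$per_subject)
  ))
  invisible(x)
}
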