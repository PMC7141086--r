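make_features <- function(n, mu, sd = 1, label, subject = "S1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * 7, mu, sd), ncol = 7))
  names(x) <- c("amplitude", "mean", "area", "re_d1", "re_d2", "re_d3", "re_d4")
  x$subject <- subject
  x$label <- label
  x
}

test_that("minority oversampling duplicates to parity and only duplicates", {
  x <- rbind(
    make_features(10, 0, label = "noise", seed = 1),
    make_features(2, 5, label = "hazard")
  )
  bal <- oversample_minority(x[, 1:7], x$label, seed = 3)
  expect_equal(unname(table(bal$labels)["hazard"]),
    unname(table(bal$labels)["noise"]))
  expect_equal(sum(bal$labels == "noise"), 10)
  # added rows are copies of existing minority rows
  minority_rows <- x[x$label == "hazard", 1:7]
  added <- bal$features[-seq_len(nrow(x)), ]
  for (i in seq_len(nrow(added))) {
    expect_true(any(apply(minority_rows, 1, function(r) {
      all(abs(r - unlist(added[i, ])) < 1e-12)
    })))
  }
  # deterministic given the seed
  bal2 <- oversample_minority(x[, 1:7], x$label, seed = 3)
  expect_identical(bal$labels, bal2$labels)
  expect_identical(bal$features, bal2$features)

  even <- oversample_minority(x[1:4, 1:7], c("hazard", "noise", "hazard", "noise"))
  expect_length(even$labels, 4)

  expect_error(oversample_minority(x[1:3, 1:7], rep("noise", 3)), "hazard")
})

test_that("the SVM separates well-separated clouds and scores sensibly", {
  train <- rbind(
    make_features(100, 0, label = "noise", seed = 10),
    make_features(100, 6, label = "hazard")
  )
  m <- train_svm(train, train$label, classifier_config())
  pred <- predict(m, train)
  expect_gte(mean(pred$predicted == train$label), 0.99)
  # hazard scores positive, noise negative (orientation contract)
  expect_gt(mean(pred$score[train$label == "hazard"]), 0)
  expect_lt(mean(pred$score[train$label == "noise"]), 0)
})

test_that("identical features for both classes give chance accuracy", {
  set.seed(11)
  base <- make_features(60, 0, label = "noise")
  flip <- base
  flip$label <- "hazard"
  train <- rbind(base, flip)
  m <- train_svm(train, train$label, classifier_config())
  test <- make_features(200, 0, label = "noise", seed = 12)
  pred <- predict(m, test)
  expect_gt(mean(pred$predicted == "hazard"), 0.2)
  expect_lt(mean(pred$predicted == "hazard"), 0.8)
})

test_that("zero-variance features are standardized to zero with a warning", {
  train <- rbind(
    make_features(20, 0, label = "noise", seed = 13),
    make_features(20, 3, label = "hazard")
  )
  train$re_d4 <- 1 # degenerate
  expect_warning(m <- train_svm(train, train$label, classifier_config()),
    "zero-variance")
  expect_gte(mean(suppressWarnings(predict(m, train))$predicted == train$label),
    0.95)
})

test_that("LOSO folds never train on the held-out subject", {
  set.seed(14)
  dat <- do.call(rbind, lapply(1:5, function(s) {
    rbind(
      make_features(30, 0, label = "noise", subject = paste0("S", s)),
      make_features(6, 4, label = "hazard", subject = paste0("S", s))
    )
  }))
  dat$peak_time <- seq_len(nrow(dat))
  folds <- loso_cv(dat, classifier_config())
  expect_length(folds, 5)
  # id audit: the union of held-out predictions is a partition
  all_pred <- do.call(rbind, lapply(folds, `[[`, "predictions"))
  expect_setequal(all_pred$peak_time, dat$peak_time)
  expect_equal(nrow(all_pred), nrow(dat))
  for (f in folds) {
    expect_true(all(f$predictions$subject == f$held_out_subject))
  }
})

test_that("LOSO predictions do not depend on subject order", {
  set.seed(15)
  dat <- do.call(rbind, lapply(1:4, function(s) {
    rbind(
      make_features(20, 0, label = "noise", subject = paste0("S", s)),
      make_features(5, 4, label = "hazard", subject = paste0("S", s))
    )
  }))
  dat$id <- seq_len(nrow(dat))
  f1 <- loso_cv(dat, classifier_config())
  perm <- dat[order(-dat$id), ]
  f2 <- loso_cv(perm, classifier_config())
  p1 <- do.call(rbind, lapply(f1, `[[`, "predictions"))
  p2 <- do.call(rbind, lapply(f2, `[[`, "predictions"))
  p2 <- p2[match(p1$id, p2$id), ]
  expect_equal(p1$score, p2$score, tolerance = 1e-9)
})

test_that("a fold whose training set lacks a class is skipped with warning", {
  dat <- rbind(
    make_features(10, 0, label = "noise", subject = "A", seed = 16),
    make_features(10, 0, label = "noise", subject = "B"),
    make_features(3, 4, label = "hazard", subject = "B")
  )
  expect_warning(folds <- loso_cv(dat, classifier_config()), "skipped")
  expect_length(folds, 1)
  expect_equal(folds[[1]]$held_out_subject, "A")
})

test_that("confusion metrics match hand-computed values and handle zeros", {
  m <- confusion_metrics(10, 2, 8, 1)
  expect_equal(m$sensitivity, 10 / 11, tolerance = 1e-12)
  expect_equal(m$specificity, 0.8, tolerance = 1e-12)
  expect_equal(m$precision, 10 / 12, tolerance = 1e-12)
  z <- confusion_metrics(0, 0, 5, 0)
  expect_true(is.na(z$sensitivity)) # undefined, not zero
  expect_true(is.na(z$precision))
  expect_equal(z$specificity, 1)
})

test_that("trapezoid AUC equals the rank-statistic oracle", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7))
    if (length(unique(truth)) < 2) next
    scores <- rnorm(n) + 2 * truth
    if (i %% 3 == 0) scores <- round(scores, 1) # force ties
    r <- roc_curve(scores, truth)
    expect_equal(r$auc, oracle_auc(scores, truth), tolerance = 1e-9)
    # step curve monotone in both axes
    expect_true(all(diff(r$roc$fpr) >= 0))
    expect_true(all(diff(r$roc$tpr) >= 0))
  }
})

test_that("raising the decision threshold never increases sensitivity", {
  set.seed(18)
  scores <- rnorm(100)
  truth <- scores + rnorm(100) > 0
  sens <- vapply(seq(-2, 2, by = 0.25), function(th) {
    tp <- sum(scores > th & truth)
    tp / sum(truth)
  }, numeric(1))
  expect_true(all(diff(sens) <= 0))
})

test_that("perfectly separable scores give a ROC through (0, 1)", {
  scores <- c(rep(2, 5), rep(-2, 20))
  truth <- c(rep(TRUE, 5), rep(FALSE, 20))
  r <- roc_curve(scores, truth)
  expect_equal(r$auc, 1)
  expect_true(any(r$roc$fpr == 0 & r$roc$tpr == 1))
})
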