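#' Leave-one-out cross-validation splits
#'
#' @param n number of subjects (>= 2).
#' @return List of `n` elements, each `list(train = indices, test = i)`;
#'   test indices enumerate `1..n` in order, each exactly once.
#' @export
loocv_splits <- function(n) {
  if (!is.numeric(n) || n < 2L)
    stop("degenerate input: need at least 2 subjects", call. = FALSE)
  n <- as.integer(n)
  lapply(seq_len(n), function(i) list(train = setdiff(seq_len(n), i),
                                      test = i))
}

#' Classifier families available to [evaluate_ovr()]
#' @return Character vector of family names.
#' @export
classifier_families <- function() {
  c("lda", "qda", "knn", "naive_bayes", "decision_tree",
    "random_forest", "logistic", "svm")
}

# kNN vote-fraction scorer: per-class probabilities from the k nearest
# training points (Euclidean), which class::knn does not expose.
.knn_score <- function(train_x, train_y, test_x, k) {
  classes <- levels(train_y)
  d <- sqrt(colSums((t(train_x) - as.numeric(test_x))^2))
  k <- min(k, length(d))
  nb <- train_y[order(d)[seq_len(k)]]
  vapply(classes, function(cl) mean(nb == cl), numeric(1))
}

# Fit one family on the training fold and return per-class scores for the
# single held-out row. All families expose class-probability-like scores
# so OvR ROC curves can be ranked.
.fit_score <- function(family, train_x, train_y, test_x, k_neighbors) {
  classes <- levels(train_y)
  test_df <- as.data.frame(test_x)
  train_df <- data.frame(.y = train_y, train_x, check.names = FALSE)
  sc <- switch(
    family,
    lda = {
      fit <- MASS::lda(train_x, grouping = train_y)
      predict(fit, test_df)$posterior[1, ]
    },
    qda = {
      fit <- MASS::qda(train_x, grouping = train_y)
      predict(fit, test_df)$posterior[1, ]
    },
    knn = .knn_score(train_x, train_y, test_x, k_neighbors),
    naive_bayes = {
      fit <- e1071::naiveBayes(train_x, train_y)
      predict(fit, test_df, type = "raw")[1, ]
    },
    decision_tree = {
      fit <- rpart::rpart(.y ~ ., data = train_df, method = "class",
                          control = rpart::rpart.control(minsplit = 4,
                                                         minbucket = 2,
                                                         cp = 0.01))
      predict(fit, test_df, type = "prob")[1, ]
    },
    random_forest = {
      fit <- randomForest::randomForest(train_x, train_y, ntree = 200)
      predict(fit, test_df, type = "prob")[1, ]
    },
    logistic = {
      fit <- suppressWarnings(
        nnet::multinom(.y ~ ., data = train_df, trace = FALSE,
                       maxit = 200))
      p <- predict(fit, test_df, type = "probs")
      if (is.null(dim(p))) {
        if (length(p) == length(classes)) p
        else stats::setNames(c(1 - p, p), classes)   # 2-class case
      } else p[1, ]
    },
    svm = {
      fit <- e1071::svm(train_x, train_y, probability = TRUE)
      attr(predict(fit, test_df, probability = TRUE), "probabilities")[1, ]
    },
    stop("config error: unknown classifier family '", family, "'",
         call. = FALSE)
  )
  sc[classes]   # fixed class order
}

# binary ROC from scores: thresholds at unique scores, plus the (0,0) end
.roc_points <- function(scores, positive) {
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(positive); Ng <- sum(!positive)
  tpr <- vapply(ths, function(t) sum(scores >= t & positive) / P, numeric(1))
  fpr <- vapply(ths, function(t) sum(scores >= t & !positive) / Ng,
                numeric(1))
  data.frame(threshold = c(Inf, ths), tpr = c(0, tpr), fpr = c(0, fpr))
}

.trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
}

#' One-vs-rest LOOCV evaluation of a feature set
#'
#' Leave-one-out cross-validation of a multiclass classifier: each fold
#' fits on all-but-one subject and scores the held-out subject with
#' per-class probabilities. Pooled scores yield per-class one-vs-rest ROC
#' curves and a micro-averaged ROC built from the pooled per-class
#' true/false positive counts — TPR as pooled TP over pooled (TP + FN)
#' and FPR as pooled FP over pooled (FP + TN) across classes. The
#' confusion matrix and precision use the arg-max decision rule.
#'
#' @param features subjects x d numeric matrix (a vector is treated as a
#'   single column); no NaN values.
#' @param labels class vector (factor or character), >= 2 classes present.
#' @param family classifier family, one of [classifier_families()].
#' @param seed integer seed (fold fits are re-seeded deterministically).
#' @param k_neighbors kNN neighbourhood size (default 2).
#' @return Object of class `ovr_report`: per-class ROC point lists and
#'   AUCs, micro-averaged ROC and AUC, confusion matrix, precision,
#'   pooled score matrix, `seed`, `n_folds`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(10, 0), rnorm(10, 4), rnorm(10, 8))
#' y <- rep(c("a", "b", "c"), each = 10)
#' evaluate_ovr(x, y, family = "lda", seed = 1)
#' @export
evaluate_ovr <- function(features, labels, family = "random_forest",
                         seed = 1, k_neighbors = 2) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (anyNA(x)) stop("validation error: NaN features", call. = FALSE)
  y <- factor(labels)
  if (nlevels(y) < 2L)
    stop("validation error: need >= 2 classes", call. = FALSE)
  if (nrow(x) != length(y))
    stop("features and labels disagree in length", call. = FALSE)
  classes <- levels(y)
  n <- nrow(x)
  splits <- loocv_splits(n)
  scores <- matrix(NA_real_, n, length(classes),
                   dimnames = list(NULL, classes))
  degenerate <- all(apply(x, 2, function(col) length(unique(col)) == 1L))
  if (degenerate) {
    warning("degenerate scores: all features identical; AUC fixed at 0.5")
    scores[] <- 1 / length(classes)
  } else {
    for (sp in splits) {
      if (length(unique(y[sp$train])) < nlevels(y))
        warning("fold ", sp$test, ": a class is absent from training")
      set.seed(seed + sp$test)   # deterministic per fold
      scores[sp$test, ] <- .fit_score(family, x[sp$train, , drop = FALSE],
                                      droplevels(y[sp$train]),
                                      x[sp$test, , drop = FALSE],
                                      k_neighbors)
    }
  }
  per_class_roc <- lapply(classes, function(cl)
    .roc_points(scores[, cl], y == cl))
  names(per_class_roc) <- classes
  per_class_auc <- vapply(per_class_roc, function(r)
    .trapezoid_auc(r$fpr, r$tpr), numeric(1))
  if (degenerate) per_class_auc[] <- 0.5
  # micro-average: pool every (subject, class) score with its OvR label
  pooled_scores <- as.numeric(scores)
  pooled_pos <- as.logical(outer(as.integer(y), seq_along(classes),
                                 function(a, b) a == b))
  micro_roc <- .roc_points(pooled_scores, pooled_pos)
  micro_auc <- if (degenerate) 0.5 else
    .trapezoid_auc(micro_roc$fpr, micro_roc$tpr)
  # arg-max decisions -> confusion counts per class (OvR binarization)
  pred <- factor(classes[max.col(scores, ties.method = "first")],
                 levels = classes)
  confusion <- table(truth = y, predicted = pred)
  counts <- t(vapply(classes, function(cl) {
    c(TP = sum(pred == cl & y == cl), FP = sum(pred == cl & y != cl),
      FN = sum(pred != cl & y == cl), TN = sum(pred != cl & y != cl))
  }, numeric(4)))
  precision <- sum(counts[, "TP"]) / sum(counts[, c("TP", "FP")])
  structure(
    list(classifier_name = family, classes = classes,
         per_class_roc = per_class_roc, per_class_auc = per_class_auc,
         micro_roc = micro_roc, micro_auc = micro_auc,
         confusion = confusion, ovr_counts = counts,
         precision = precision, scores = scores, labels = y,
         seed = seed, n_folds = n),
    class = "ovr_report"
  )
}

#' @export
print.ovr_report <- function(x, ...) {
  cat("<ovr_report>", x$classifier_name, "| LOOCV,", x$n_folds,
      "folds, seed", x$seed, "\n")
  cat("  per-class AUC:",
      paste(sprintf("%s %.3f", names(x$per_class_auc), x$per_class_auc),
            collapse = ", "), "\n")
  cat(sprintf("  micro AUC %.3f | precision %.3f\n", x$micro_auc,
              x$precision))
  invisible(x)
}

#' @export
plot.ovr_report <- function(x, ...) {
  graphics::plot(x$micro_roc$fpr, x$micro_roc$tpr, type = "l", lwd = 2,
                 xlab = "FPR", ylab = "TPR",
                 main = paste0(x$classifier_name, " (micro AUC ",
                               round(x$micro_auc, 3), ")"), ...)
  for (cl in x$classes)
    graphics::lines(x$per_class_roc[[cl]]$fpr, x$per_class_roc[[cl]]$tpr,
                    lty = 2, col = "grey40")
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Repeat LOOCV evaluation across seeds
#'
#' Repeated LOOCV (default 8 repetitions with distinct seeds) giving a
#' distribution of AUC and precision per classifier, the basis for
#' cohort-level benchmark comparisons.
#'
#' @inheritParams evaluate_ovr
#' @param repeats number of repetitions.
#' @param base_seed first seed; repetition r uses `base_seed + r - 1`.
#' @return data.frame with one row per repetition: seed, micro_auc,
#'   precision and per-class AUC columns.
#' @export
repeat_loocv <- function(features, labels, family = "random_forest",
                         repeats = 8, base_seed = 1, k_neighbors = 2) {
  out <- lapply(seq_len(repeats), function(r) {
    rep_ <- evaluate_ovr(features, labels, family = family,
                         seed = as.integer(base_seed) + r - 1L,
                         k_neighbors = k_neighbors)
    cbind(data.frame(seed = rep_$seed, micro_auc = rep_$micro_auc,
                     precision = rep_$precision),
          as.data.frame(as.list(rep_$per_class_auc)))
  })
  do.call(rbind, out)
}
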