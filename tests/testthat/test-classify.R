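test_that("LOOCV splitter enumerates every subject exactly once", {
  sp <- loocv_splits(88)
  expect_length(sp, 88)
  tests <- vapply(sp, `[[`, integer(1), "test")
  expect_identical(sort(tests), 1:88)
  expect_true(all(vapply(sp, function(s) length(s$train), integer(1)) == 87))
  expect_true(all(vapply(sp, function(s) !(s$test %in% s$train),
                         logical(1))))
  sp2 <- loocv_splits(2)
  expect_length(sp2, 2)
  expect_identical(sp2[[1]]$train, 2L)
  expect_error(loocv_splits(1), "degenerate")
})

test_that("perfectly separated classes give AUC 1 for every family", {
  set.seed(31)
  # well-separated but not so distant that Gaussian posteriors underflow
  x <- c(rnorm(10, 0), rnorm(10, 4), rnorm(10, 8))
  y <- rep(c("a", "b", "c"), each = 10)
  stopifnot(max(x[1:10]) < min(x[11:20]), max(x[11:20]) < min(x[21:30]))
  for (fam in classifier_families()) {
    rep_ <- evaluate_ovr(x, y, family = fam, seed = 1)
    expect_equal(rep_$micro_auc, 1, tolerance = 1e-9,
                 info = fam)
    expect_equal(unname(rep_$per_class_auc), c(1, 1, 1),
                 tolerance = 1e-9, info = fam)
    expect_equal(rep_$precision, 1, info = fam)
  }
})

test_that("permuted labels give chance-level micro AUC", {
  set.seed(32)
  # local (kNN) scoring: plug-in Gaussian discriminants carry the known
  # pessimistic LOOCV bias under the null, kNN does not
  x <- rnorm(88)
  aucs <- vapply(1:20, function(i) {
    y <- sample(rep(c("a", "b", "c"), times = c(30, 29, 29)))
    evaluate_ovr(x, y, family = "knn", seed = i)$micro_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.40)
  expect_lt(mean(aucs), 0.60)
})

test_that("micro-averaged ROC equals a brute-force recount of pooled counts", {
  set.seed(33)
  x <- c(rnorm(8, 0), rnorm(8, 1.5), rnorm(8, 3))
  y <- rep(c("a", "b", "c"), each = 8)
  rep_ <- evaluate_ovr(x, y, family = "qda", seed = 2)
  scores <- rep_$scores
  classes <- rep_$classes
  pooled_scores <- as.numeric(scores)
  pooled_pos <- as.logical(
    outer(as.integer(factor(y, classes)), seq_along(classes), `==`))
  # brute-force recount at every stored threshold
  for (i in seq_len(nrow(rep_$micro_roc))) {
    th <- rep_$micro_roc$threshold[i]
    TP <- sum(pooled_scores >= th & pooled_pos)
    FN <- sum(pooled_scores < th & pooled_pos)
    FP <- sum(pooled_scores >= th & !pooled_pos)
    TN <- sum(pooled_scores < th & !pooled_pos)
    expect_equal(rep_$micro_roc$tpr[i], TP / (TP + FN))
    expect_equal(rep_$micro_roc$fpr[i], FP / (FP + TN))
  }
  # AUC equals the trapezoidal integral of its own stored points
  o <- order(rep_$micro_roc$fpr, rep_$micro_roc$tpr)
  fpr <- rep_$micro_roc$fpr[o]; tpr <- rep_$micro_roc$tpr[o]
  expect_equal(rep_$micro_auc,
               sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2),
               tolerance = 1e-12)
})

test_that("per-class ROC/AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  x <- c(rnorm(12, 0, 2), rnorm(12, 2, 2), rnorm(12, 4, 2))
  y <- rep(c("a", "b", "c"), each = 12)
  rep_ <- evaluate_ovr(x, y, family = "lda", seed = 3)
  for (cl in rep_$classes) {
    ref <- suppressMessages(
      pROC::auc(pROC::roc(response = (y == cl),
                          predictor = rep_$scores[, cl],
                          direction = "<", quiet = TRUE)))
    expect_equal(unname(rep_$per_class_auc[cl]), as.numeric(ref),
                 tolerance = 1e-10)
  }
})

test_that("subject-order permutation leaves all reported metrics unchanged", {
  set.seed(35)
  x <- c(rnorm(9, 0), rnorm(9, 2), rnorm(9, 4))
  y <- rep(c("a", "b", "c"), each = 9)
  perm <- sample(27)
  r1 <- evaluate_ovr(x, y, family = "naive_bayes", seed = 4)
  r2 <- evaluate_ovr(x[perm], y[perm], family = "naive_bayes", seed = 4)
  expect_equal(r1$per_class_auc, r2$per_class_auc, tolerance = 1e-10)
  expect_equal(r1$micro_auc, r2$micro_auc, tolerance = 1e-10)
  expect_equal(r1$precision, r2$precision, tolerance = 1e-10)
})

test_that("confusion counts binarize to n subjects per class and degenerate
           features fall back to chance", {
  set.seed(36)
  x <- c(rnorm(10, 0), rnorm(10, 3))
  y <- rep(c("a", "b"), each = 10)
  rep_ <- evaluate_ovr(x, y, family = "logistic", seed = 5)
  expect_true(all(rowSums(rep_$ovr_counts) == 20))
  expect_equal(sum(rep_$confusion), 20)
  expect_warning(
    flat <- evaluate_ovr(rep(1, 20), y, family = "lda", seed = 5),
    "degenerate")
  expect_equal(flat$micro_auc, 0.5)
})

test_that("evaluation is deterministic given a seed and repeats vary by seed", {
  set.seed(37)
  x <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 2))
  y <- rep(c("a", "b", "c"), each = 8)
  r1 <- evaluate_ovr(x, y, family = "random_forest", seed = 11)
  r2 <- evaluate_ovr(x, y, family = "random_forest", seed = 11)
  expect_identical(r1$scores, r2$scores)
  reps <- repeat_loocv(x, y, family = "random_forest", repeats = 3,
                       base_seed = 1)
  expect_equal(nrow(reps), 3)
  expect_identical(reps$seed, 1:3)
})
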