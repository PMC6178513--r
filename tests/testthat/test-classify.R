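make_toy <- function(n_per_class, p = 20, sep = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), n_per_class, p),
             matrix(rnorm(n_per_class * p), n_per_class, p))
  x[seq_len(n_per_class), 1:2] <- x[seq_len(n_per_class), 1:2] + sep
  list(x = x, y = rep(c(1L, 0L), each = n_per_class))
}

test_that("augmentation multiplies counts and preserves labels and groups", {
  set <- make_labeled_roi_set(10, 0, seed = 1)
  expect_length(augment(set, 2), 20L)
  a4 <- augment(set, 4)
  expect_length(a4, 40L)
  groups <- vapply(a4, `[[`, integer(1), "group")
  expect_identical(sort(unique(groups)), 1:10)
  expect_true(all(table(groups) == 4L))
  expect_error(augment(set, 3), "factor")
})

test_that("a flip of a flip restores the original patch exactly", {
  roi <- make_sparse_roi(c(28, 26), seed = 2)
  once <- augment(list(roi), 2, seed = 1)
  flipped <- Filter(function(r) !identical(r$pixels, roi$pixels), once)[[1]]
  twice <- augment(list(flipped), 2, seed = 1)
  expect_true(any(vapply(twice, function(r) identical(r$pixels, roi$pixels),
                         logical(1))))
})

test_that("augmented transforms preserve the sparse support size", {
  roi <- make_sparse_roi(c(30, 27), seed = 3)
  for (el in augment(list(roi), 4))
    expect_identical(sum(el$mask), sum(roi$mask))
})

test_that("metric arithmetic matches hand-computed rates", {
  scores <- c(0.9, 0.8, 0.3, 0.6, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  m <- compute_metrics(scores, labels, threshold = 0.5)
  expect_identical(c(m$tp, m$fn, m$tn, m$fp), c(2L, 1L, 2L, 1L))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$accuracy, 4 / 6)
  # detection-stage arithmetic
  dr <- detection_rates(108, 115, 273, 322)
  expect_equal(round(dr$tpr, 2), 0.94)
  expect_equal(round(dr$fppi, 2), 0.85)
})

test_that("AUC is 0.5 for constant scores and 1 for perfect separation", {
  expect_equal(roc_auc(rep(0.7, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
})

test_that("trapezoidal AUC equals the normalised Mann-Whitney statistic", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    expect_equal(roc_auc(scores, labels), mann_whitney_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("cross-validation is perfect on separable data for all classifiers", {
  toy <- make_toy(30, sep = 5)
  for (clf in c("ann", "svm", "knn")) {
    rep <- three_fold_cv(toy$x, toy$y, classifier = clf, seed = 1)
    expect_equal(rep$auc, 1)
    expect_equal(rep$sensitivity, 1)
    expect_equal(rep$specificity, 1)
  }
})

test_that("permuted labels give chance-level AUC", {
  toy <- make_toy(100, sep = 5)
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    yp <- sample(toy$y)
    three_fold_cv(toy$x, yp, classifier = "knn", seed = s)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("folds are group-aware and balanced", {
  toy <- make_toy(30)
  groups <- rep(1:20, each = 3)   # 3 samples per group, 10 groups per class
  rep <- three_fold_cv(toy$x, toy$y, groups, classifier = "knn", seed = 2)
  fold <- rep$fold_assignment
  # leakage guard: each group sits in exactly one fold
  expect_true(all(tapply(fold, groups, function(f) length(unique(f))) == 1))
  # per-class group counts differ by at most one across folds
  for (cl in c(0, 1)) {
    g <- unique(groups[toy$y == cl])
    per_fold <- table(fold[match(g, groups)])
    expect_lte(diff(range(per_fold)), 1)
  }
  expect_error(three_fold_cv(toy$x, toy$y, groups = rep(1:2, 30),
                             classifier = "knn"), "groups per class")
})

test_that("cross-validation is deterministic for a fixed seed", {
  toy <- make_toy(20, sep = 2)
  r1 <- three_fold_cv(toy$x, toy$y, classifier = "ann", seed = 7)
  r2 <- three_fold_cv(toy$x, toy$y, classifier = "ann", seed = 7)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$fold_assignment, r2$fold_assignment)
})

test_that("the ANN learns a separable toy and outputs the prior on constant features", {
  toy <- make_toy(30, sep = 5)
  # embed in 986 dims, rest zeros
  x986 <- cbind(toy$x, matrix(0, nrow(toy$x), 986 - ncol(toy$x)))
  ann <- train_ann(x986, toy$y, seed = 3)
  acc <- mean((predict(ann, x986) >= 0.5) == toy$y)
  expect_equal(acc, 1)
  # constant features: score approaches the class prior (here 1/3)
  xc <- matrix(0.5, 90, 10)
  yc <- rep(c(1, 0, 0), 30)
  annc <- train_ann(xc, yc, seed = 4, validate = FALSE, epochs = 400)
  expect_lt(max(abs(predict(annc, xc) - 1 / 3)), 0.05)
  # determinism
  a1 <- train_ann(x986, toy$y, seed = 5)
  a2 <- train_ann(x986, toy$y, seed = 5)
  expect_identical(predict(a1, x986), predict(a2, x986))
})

test_that("KNN with k = N scores every sample at the class prior", {
  toy <- make_toy(15)
  knn <- train_knn(toy$x, toy$y, k = nrow(toy$x))
  expect_true(all(abs(predict(knn, toy$x) - 0.5) < 1e-12))
})

test_that("flipping the labels reverses SVM decision values", {
  toy <- make_toy(20, sep = 2)
  s1 <- predict(train_svm(toy$x, toy$y, seed = 1), toy$x)
  s2 <- predict(train_svm(toy$x, 1 - toy$y, seed = 1), toy$x)
  expect_lt(max(abs(s1 + s2)), 1e-6)
})

test_that("training refuses single-class data", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(train_ann(x, rep(1, 10)), "both classes")
  expect_error(train_svm(x, rep(0, 10)), "both classes")
  expect_error(train_knn(x, rep(1, 10)), "both classes")
})
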