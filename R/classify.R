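#' Augment a set of ROIs by flips and rotation
#'
#' Factor 2 adds a horizontal flip of every ROI; factor 4 additionally adds
#' a vertical flip and a 180-degree rotation. Originals are retained, so the
#' output has exactly `factor` times as many ROIs. Flips and the half-turn
#' preserve the sparse support exactly. Augmented copies inherit the source
#' ROI's group id so cross-validation can keep them in the same fold.
#'
#' @param roi_set List as from [make_labeled_roi_set()] (elements with
#'   `roi`, `label`, `group`) or a plain list of [sparse_roi].
#' @param factor 2 or 4.
#' @param seed Integer seed (order of the returned list is shuffled).
#' @return Augmented list in the same format as the input.
#' @export
augment <- function(roi_set, factor = 2L, seed = 1L) {
  if (!factor %in% c(2L, 4L)) stop("factor must be 2 or 4", call. = FALSE)
  hflip <- function(m) m[, ncol(m):1, drop = FALSE]
  vflip <- function(m) m[nrow(m):1, , drop = FALSE]
  rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]
  tf <- if (factor == 2L) list(hflip) else list(hflip, vflip, rot180)
  apply_tf <- function(el, f) {
    plain <- inherits(el, "sparse_roi")
    roi <- if (plain) el else el$roi
    out <- sparse_roi(f(roi$pixels), f(roi$mask), bbox = roi$bbox,
                      pixel_count = roi$pixel_count)
    if (plain) out else {el$roi <- out; el}
  }
  aug <- c(roi_set,
           unlist(lapply(tf, function(f) lapply(roi_set, apply_tf, f = f)),
                  recursive = FALSE))
  with_seed(seed, aug[sample.int(length(aug))])
}

#' Classification and detection metrics
#'
#' Thresholds scores into predictions and reports the confusion counts,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy and the
#' area under the ROC curve (trapezoidal integration over all score
#' thresholds). When lesion and image counts are supplied, the
#' detection-stage rates are added: lesion-level true-positive rate
#' `TPR = TP/n_lesions` and false positives per image
#' `FPPI = FP/n_images`.
#'
#' @param scores Numeric vector of classifier scores (higher = positive).
#' @param labels Binary vector (0/1 or logical), same length.
#' @param threshold Decision threshold: predicted positive iff
#'   `score >= threshold`.
#' @param n_lesions,n_images Optional counts for TPR / FPPI.
#' @return List of class `eval_report` with `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `specificity`, `accuracy`, `auc`, and (if requested)
#'   `tpr`, `fppi`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5,
                            n_lesions = NULL, n_images = NULL) {
  stopifnot(length(scores) == length(labels), length(scores) >= 1L)
  labels <- as.integer(as.logical(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  out <- list(tp = tp, fn = fn, tn = tn, fp = fp,
              sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
              specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
              accuracy = (tp + tn) / length(labels),
              auc = roc_auc(scores, labels))
  if (!is.null(n_lesions)) out$tpr <- tp / n_lesions
  if (!is.null(n_images)) out$fppi <- fp / n_images
  structure(out, class = "eval_report")
}

#' Detection-stage TPR and FPPI from raw counts
#'
#' Lesion-level true-positive rate (detected lesions over total lesions)
#' and false positives per image.
#'
#' @param tp Number of detected lesions.
#' @param n_lesions Total number of lesions.
#' @param fp Number of false-positive regions.
#' @param n_images Number of images.
#' @return List with `tpr = tp/n_lesions` and `fppi = fp/n_images`.
#' @export
detection_rates <- function(tp, n_lesions, fp, n_images) {
  stopifnot(n_lesions > 0, n_images > 0)
  list(tpr = tp / n_lesions, fppi = fp / n_images)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve over all score thresholds.
#' Equals the Mann-Whitney U statistic divided by `n_pos * n_neg` (ties
#' counted 1/2).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels.
#' @return AUC in `[0, 1]`; 0.5 when either class is absent or all scores tie.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) return(0.5)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # sweep thresholds through the distinct score values
  idx <- cumsum(rle(s)$lengths)
  tps <- cumsum(l)[idx]; fps <- cumsum(1L - l)[idx]
  tpr <- c(0, tps / npos, 1)
  fpr <- c(0, fps / nneg, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  accuracy %.3f  AUC %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$auc))
  if (!is.null(x$tpr)) cat(sprintf("  TPR %.3f", x$tpr))
  if (!is.null(x$fppi)) cat(sprintf("  FPPI %.3f", x$fppi))
  if (!is.null(x$tpr) || !is.null(x$fppi)) cat("\n")
  if (!is.null(x$folds))
    cat(sprintf("  (averages over %d folds)\n", length(x$folds)))
  invisible(x)
}

# --- classifiers -----------------------------------------------------------

# Forward pass of the 1-hidden-layer logistic network.
mlp_forward <- function(x, w) {
  sig <- function(z) 1 / (1 + exp(-z))
  h <- sig(sweep(x %*% w$W1, 2, w$b1, `+`))
  p <- sig(as.vector(h %*% w$W2 + w$b2))
  list(h = h, p = p)
}

# Full-batch Adam on cross-entropy + L2 penalty. Tiny problem sizes (a few
# hundred samples) make full-batch gradients the simplest stable choice.
mlp_fit <- function(x, y, hidden, decay, epochs, lr, xv, yv, check_every,
                    patience) {
  n <- nrow(x); p <- ncol(x)
  w <- list(W1 = matrix(runif(p * hidden, -0.5, 0.5) / sqrt(p), p, hidden),
            b1 = rep(0, hidden),
            W2 = matrix(runif(hidden, -0.5, 0.5) / sqrt(hidden), hidden, 1),
            b2 = 0)
  m <- v <- lapply(w, function(z) z * 0)
  b1 <- 0.9; b2m <- 0.999; eps <- 1e-8
  best <- w; best_loss <- Inf; stale <- 0L
  val_loss <- function(w) {
    pr <- pmin(pmax(mlp_forward(xv, w)$p, 1e-10), 1 - 1e-10)
    -mean(yv * log(pr) + (1 - yv) * log(1 - pr))
  }
  for (t in seq_len(epochs)) {
    fw <- mlp_forward(x, w)
    dout <- (fw$p - y) / n                       # dL/dz_out
    g <- list(W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL)
    g$W2 <- t(fw$h) %*% dout + decay * w$W2
    g$b2 <- sum(dout)
    dh <- (dout %*% t(w$W2)) * fw$h * (1 - fw$h)
    g$W1 <- t(x) %*% dh + decay * w$W1
    g$b1 <- colSums(dh)
    for (k in names(w)) {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * g[[k]]
      v[[k]] <- b2m * v[[k]] + (1 - b2m) * g[[k]]^2
      mhat <- m[[k]] / (1 - b1^t); vhat <- v[[k]] / (1 - b2m^t)
      w[[k]] <- w[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    if (length(yv) > 0L && t %% check_every == 0L) {
      loss <- val_loss(w)
      if (loss < best_loss - 1e-6) {
        best <- w; best_loss <- loss; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
  }
  if (length(yv) == 0L || best_loss == Inf) w else best
}

#' Train the feed-forward ANN scorer
#'
#' Single hidden layer with logistic activations (986 input neurons at the
#' full descriptor), one logistic output score in `[0, 1]`, trained by
#' full-batch gradient descent (Adam) on cross-entropy. The provided data
#' are split in half into a training and a validation part — so that inside
#' one fold of 3-fold cross-validation the overall split is one third each
#' for training, validation and testing — and training stops early when
#' validation loss stops improving, keeping the best weights.
#'
#' @param x Feature matrix (N x p).
#' @param y Binary labels.
#' @param hidden Hidden-layer size (default 20).
#' @param seed Integer seed (weight initialisation and the split).
#' @param decay L2 weight penalty (default 1e-4).
#' @param epochs Maximum training epochs (default 800).
#' @param lr Adam learning rate (default 0.05).
#' @param check_every Validate every this many epochs (default 25).
#' @param patience Validation checks without improvement before stopping.
#' @param validate Use the internal validation split and early stopping
#'   (disable to train on all provided rows for the full epoch budget).
#' @return Object of class `mammocad_scorer` whose `predict` returns scores
#'   in `[0, 1]`.
#' @export
train_ann <- function(x, y, hidden = 20L, seed = 1L, decay = 1e-4,
                      epochs = 800L, lr = 0.05, check_every = 25L,
                      patience = 6L, validate = TRUE) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L)
    stop("both classes must be present for training", call. = FALSE)
  with_seed(seed, {
    # stratified half/half split into train and validation
    val <- logical(length(y))
    if (validate) {
      for (cl in c(0L, 1L)) {
        idx <- which(y == cl)
        val[sample(idx, floor(length(idx) / 2))] <- TRUE
      }
      if (sum(!val) < 2L || length(unique(y[!val])) < 2L) val[] <- FALSE
    }
    w <- mlp_fit(x[!val, , drop = FALSE], y[!val], hidden = hidden,
                 decay = decay, epochs = epochs, lr = lr,
                 xv = x[val, , drop = FALSE], yv = y[val],
                 check_every = check_every, patience = patience)
    structure(list(kind = "ann", fit = w, threshold = 0.5),
              class = "mammocad_scorer")
  })
}

#' Train the SVM scorer
#'
#' Radial-basis-function support vector machine; the score is the decision
#' value, oriented so that larger means more positive.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param cost,gamma RBF-SVM hyperparameters (`gamma` defaults to
#'   `1/ncol(x)`).
#' @param seed Integer seed.
#' @return A `mammocad_scorer` with decision threshold 0.
#' @export
train_svm <- function(x, y, cost = 1, gamma = NULL, seed = 1L) {
  y <- factor(as.integer(as.logical(y)), levels = c(0L, 1L))
  if (length(unique(y)) < 2L)
    stop("both classes must be present for training", call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fit <- with_seed(seed,
    e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE))
  # orient decision values: positive class = label 1
  dv <- attr(predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  flip <- !grepl("^1", colnames(dv))   # colname "0/1" means positive dv = class 0
  structure(list(kind = "svm", fit = fit, flip = flip, threshold = 0),
            class = "mammocad_scorer")
}

#' Train the KNN scorer
#'
#' k-nearest-neighbour scorer: the score of a sample is the fraction of its
#' `k` nearest training neighbours labelled positive.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param k Neighbourhood size (default 5).
#' @param seed Integer seed (distance ties are broken at random).
#' @return A `mammocad_scorer` with threshold 0.5.
#' @export
train_knn <- function(x, y, k = 5L, seed = 1L) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L)
    stop("both classes must be present for training", call. = FALSE)
  structure(list(kind = "knn", x = x, y = y, k = as.integer(k),
                 seed = as.integer(seed), threshold = 0.5),
            class = "mammocad_scorer")
}

#' @export
predict.mammocad_scorer <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  switch(object$kind,
    ann = mlp_forward(newdata, object$fit)$p,
    svm = {
      p <- predict(object$fit, newdata, decision.values = TRUE)
      dv <- as.vector(attr(p, "decision.values"))
      if (object$flip) -dv else dv
    },
    knn = with_seed(object$seed, {
      cl <- factor(object$y, levels = c(0L, 1L))
      pr <- class::knn(object$x, newdata, cl, k = min(object$k, nrow(object$x)),
                       prob = TRUE)
      frac <- attr(pr, "prob")
      ifelse(pr == "1", frac, 1 - frac)
    }),
    stop("unknown scorer kind"))
}

#' @export
print.mammocad_scorer <- function(x, ...) {
  cat(sprintf("mammocad %s scorer (threshold %g)\n", toupper(x$kind),
              x$threshold))
  invisible(x)
}

train_scorer <- function(kind, x, y, seed, ...) {
  switch(kind,
    ann = train_ann(x, y, seed = seed, ...),
    svm = train_svm(x, y, seed = seed, ...),
    knn = train_knn(x, y, seed = seed, ...),
    stop("classifier must be one of 'ann', 'svm', 'knn'", call. = FALSE))
}

# --- cross-validation ------------------------------------------------------

# Group-aware split of groups into `nfold` folds, balancing class counts:
# groups of each class are shuffled and dealt round-robin.
group_folds <- function(labels, groups, nfold, seed) {
  with_seed(seed, {
    fold_of <- integer(0)
    gl <- tapply(labels, groups, function(v) v[1])
    for (cl in unique(gl)) {
      g <- names(gl)[gl == cl]
      g <- sample(g)
      f <- rep(seq_len(nfold), length.out = length(g))
      fold_of[g] <- f
    }
    fold_of[as.character(groups)]
  })
}

#' Three-fold cross-validated evaluation
#'
#' Randomly divides the dataset into three sets (group-aware: all samples
#' sharing a group id — e.g. augmented copies of one ROI — stay in the same
#' set, and per-class group counts differ across sets by at most one). Each
#' set is held out once; the scorer is trained on the remaining two and
#' evaluated on the held-out set. The report carries per-fold metrics and
#' their means; the final accuracy is the average of the three fold
#' accuracies.
#'
#' @param features N x p feature matrix.
#' @param labels Binary labels.
#' @param groups Group ids (default: every sample its own group).
#' @param classifier `"ann"`, `"svm"` or `"knn"`.
#' @param seed Integer seed (split and classifier initialisation).
#' @param nfold Number of folds (default 3).
#' @param ... Passed to the classifier's training function.
#' @return An `eval_report` with averaged metrics and a `folds` list of the
#'   per-fold reports.
#' @export
three_fold_cv <- function(features, labels, groups = seq_along(labels),
                          classifier = c("ann", "svm", "knn"), seed = 1L,
                          nfold = 3L, ...) {
  classifier <- match.arg(classifier)
  labels <- as.integer(as.logical(labels))
  stopifnot(nrow(features) == length(labels),
            length(groups) == length(labels))
  for (cl in c(0L, 1L))
    if (length(unique(groups[labels == cl])) < nfold)
      stop("need at least ", nfold, " groups per class", call. = FALSE)
  fold <- group_folds(labels, groups, nfold, seed)
  # leakage guard: a group id must sit in exactly one fold
  stopifnot(all(tapply(fold, groups, function(f) length(unique(f))) == 1L))
  reports <- vector("list", nfold)
  for (f in seq_len(nfold)) {
    tr <- fold != f; te <- !tr
    if (length(unique(labels[tr])) < 2L)
      stop("a class is absent from the training portion of fold ", f,
           call. = FALSE)
    scorer <- train_scorer(classifier, features[tr, , drop = FALSE],
                           labels[tr], seed = seed + f, ...)
    sc <- predict(scorer, features[te, , drop = FALSE])
    reports[[f]] <- compute_metrics(sc, labels[te],
                                    threshold = scorer$threshold)
  }
  avg <- function(field) mean(vapply(reports, `[[`, numeric(1), field))
  structure(list(
    tp = sum(vapply(reports, `[[`, numeric(1), "tp")),
    fn = sum(vapply(reports, `[[`, numeric(1), "fn")),
    tn = sum(vapply(reports, `[[`, numeric(1), "tn")),
    fp = sum(vapply(reports, `[[`, numeric(1), "fp")),
    sensitivity = avg("sensitivity"), specificity = avg("specificity"),
    accuracy = avg("accuracy"), auc = avg("auc"),
    folds = reports, fold_assignment = fold, classifier = classifier),
    class = "eval_report")
}
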