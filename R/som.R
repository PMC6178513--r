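#' Extract 3 x 3 neighbourhood pixel features
#'
#' For every pixel, the feature vector is the 9 intensities of its 3 x 3
#' neighbourhood in row-major order (centre included), with borders handled
#' by symmetric reflection so that every pixel — including border pixels —
#' has a full 9-vector.
#'
#' @param img Numeric matrix in `[0, 1]`, at least 3 x 3.
#' @return A list with `features` (N x 9 matrix, N = number of pixels, rows
#'   in column-major pixel order), and `rows`, `cols` (pixel locations).
#' @export
extract_pixel_features <- function(img) {
  check_gray(img)
  if (nrow(img) < 3L || ncol(img) < 3L)
    stop("image must be at least 3 x 3", call. = FALSE)
  p <- reflect_pad(img, 1L)
  nr <- nrow(img); nc <- ncol(img)
  # 3 x 3 window in row-major order: (dr, dc) = (-1,-1) (-1,0) (-1,1) (0,-1) ...
  offs <- expand.grid(dc = -1:1, dr = -1:1)[, c("dr", "dc")]
  feats <- vapply(seq_len(9L), function(k) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    as.vector(p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)])
  }, numeric(nr * nc))
  list(features = feats,
       rows = rep(seq_len(nr), times = nc),
       cols = rep(seq_len(nc), each = nr))
}

#' Train a self-organising map on pixel features
#'
#' Online Kohonen training: for each sampled feature `f`, the best-matching
#' unit is `c = argmin_i ||f - W_i||`, and every node is updated by
#' `W_i <- W_i + N_ci(t) (f - W_i)` with neighbourhood kernel
#' `N_ci(t) = eta(t) exp(-||m_c - m_i||^2 / (2 sigma(t)^2))`. The learning
#' rate and kernel width decay exponentially from their initial values to
#' 1 % of them over the `iterations` samples. Node coordinates `m_i` lie on
#' a near-square unit-spacing grid (2 x 2 for the default `M = 4`).
#'
#' @param features N x 9 feature matrix (or the list from
#'   [extract_pixel_features()]).
#' @param M Number of map nodes / clusters (default 4).
#' @param iterations Number of training samples (default 20000).
#' @param eta0 Initial learning rate (default 0.5).
#' @param sigma0 Initial neighbourhood width (default 1).
#' @param seed Integer seed for weight initialisation and sampling.
#' @return Object of class `som_map`: list with `weights` (M x 9), `grid`
#'   (M x 2 node coordinates) and the training parameters.
#' @export
train_som <- function(features, M = 4L, iterations = 20000L, eta0 = 0.5,
                      sigma0 = 1.0, seed = 1L) {
  if (is.list(features)) features <- features$features
  stopifnot(is.matrix(features))
  M <- as.integer(M)
  if (M < 2L) stop("M must be >= 2", call. = FALSE)
  if (nrow(features) < M)
    stop("need at least M feature vectors to train", call. = FALSE)
  side <- ceiling(sqrt(M))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side)))[seq_len(M), , drop = FALSE]
  storage.mode(grid) <- "double"
  with_seed(seed, {
    W <- matrix(runif(M * ncol(features)), M, ncol(features))
    idx <- sample.int(nrow(features), iterations, replace = TRUE)
    Tt <- max(1L, iterations - 1L)
    for (t in seq_len(iterations)) {
      f <- features[idx[t], ]
      decay <- 0.01^((t - 1) / Tt)
      eta <- eta0 * decay
      sigma <- sigma0 * decay
      d2 <- rowSums((W - matrix(f, M, length(f), byrow = TRUE))^2)
      cwin <- which.min(d2)
      g2 <- (grid[, 1] - grid[cwin, 1])^2 + (grid[, 2] - grid[cwin, 2])^2
      nci <- eta * exp(-g2 / (2 * sigma^2))
      W <- W + nci * (matrix(f, M, length(f), byrow = TRUE) - W)
    }
    structure(list(weights = W, grid = grid, M = M, eta0 = eta0,
                   sigma0 = sigma0, iterations = iterations, seed = seed),
              class = "som_map")
  })
}

#' @export
print.som_map <- function(x, ...) {
  cat(sprintf("Self-organising map: %d nodes, %d-dim weights, %d training samples\n",
              x$M, ncol(x$weights), x$iterations))
  invisible(x)
}

#' Assign every pixel to its best-matching SOM node
#'
#' Labels each pixel of `img` with the index of the nearest weight vector
#' (minimum Euclidean distance over the 9-dim neighbourhood feature); ties
#' are broken toward the lowest node index.
#'
#' @param model A trained [train_som()] map.
#' @param img Numeric matrix in `[0, 1]`.
#' @return Integer matrix of cluster labels in `1..M`, same shape as `img`.
#' @export
assign_clusters <- function(model, img) {
  stopifnot(inherits(model, "som_map"))
  fx <- extract_pixel_features(img)
  F <- fx$features
  W <- model$weights
  # squared distances N x M without forming N x M x 9
  d2 <- outer(rowSums(F^2), rep(1, nrow(W))) - 2 * F %*% t(W) +
        outer(rep(1, nrow(F)), rowSums(W^2))
  lab <- max.col(-d2, ties.method = "first")
  matrix(lab, nrow(img), ncol(img))
}

#' @export
predict.som_map <- function(object, newdata, ...) assign_clusters(object, newdata)

#' Select candidate mass regions by pixel-count thresholds
#'
#' The cluster of interest is the SOM cluster with the highest mean image
#' intensity (masses are bright). Its 8-connected components whose pixel
#' counts lie within the pixel-level-threshold (PLT) window
#' `[min_pixels, max_pixels]` are returned as candidates; components outside
#' the window are discarded. The defaults are the thresholds used for
#' 1024 x 1024 screening mammograms (450 to 31,500 pixels).
#'
#' @param cmap Integer cluster-label matrix from [assign_clusters()].
#' @param img The intensity image the labels refer to (same shape).
#' @param min_pixels,max_pixels PLT window, `0 < min_pixels < max_pixels`.
#' @return List of `region_candidate` objects: `mask` (logical matrix cropped
#'   to the bounding box), `bbox` (half-open `(row0, col0, row1, col1)`),
#'   `pixel_count`.
#' @export
select_candidates <- function(cmap, img, min_pixels = 450L,
                              max_pixels = 31500L) {
  stopifnot(all(dim(cmap) == dim(img)))
  if (!(min_pixels > 0 && min_pixels < max_pixels))
    stop("require 0 < min_pixels < max_pixels", call. = FALSE)
  means <- vapply(sort(unique(as.vector(cmap))),
                  function(k) mean(img[cmap == k]), numeric(1))
  coi <- sort(unique(as.vector(cmap)))[which.max(means)]
  lab <- .label8_cpp(cmap == coi)
  n <- attr(lab, "n")
  if (n == 0L) return(list())
  counts <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(counts >= min_pixels & counts <= max_pixels)
  lapply(keep, function(k) {
    full <- lab == k
    bb <- mask_bbox(full)
    structure(list(mask = full[bb[1]:(bb[3] - 1L), bb[2]:(bb[4] - 1L), drop = FALSE],
                   bbox = bb, pixel_count = counts[k]),
              class = "region_candidate")
  })
}

#' @export
print.region_candidate <- function(x, ...) {
  cat(sprintf("Region candidate: %d px, bbox [%d, %d) x [%d, %d)\n",
              x$pixel_count, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  invisible(x)
}

#' Extract sparse ROIs from candidate regions
#'
#' Each candidate is cropped to its tight bounding box; pixels outside the
#' candidate mask are set exactly to zero, making the patch a sparse matrix.
#' Patches smaller than `min_size` (default 25 x 22, the smallest mass ROI
#' supported by the descriptor) are zero-padded symmetrically up to it.
#'
#' @param img Source intensity image.
#' @param candidates List of `region_candidate` objects.
#' @param min_size Minimum ROI size `(rows, cols)`.
#' @return List of [sparse_roi] objects.
#' @export
extract_rois <- function(img, candidates, min_size = c(25L, 22L)) {
  check_gray(img)
  lapply(candidates, function(cand) {
    bb <- cand$bbox
    stopifnot(bb[1] >= 1, bb[2] >= 1, bb[3] - 1L <= nrow(img),
              bb[4] - 1L <= ncol(img))
    patch <- img[bb[1]:(bb[3] - 1L), bb[2]:(bb[4] - 1L), drop = FALSE]
    patch[!cand$mask] <- 0
    mask <- cand$mask
    pr <- max(0L, min_size[1] - nrow(patch))
    pc <- max(0L, min_size[2] - ncol(patch))
    if (pr > 0 || pc > 0) {
      top <- pr %/% 2L; bottom <- pr - top
      left <- pc %/% 2L; right <- pc - left
      pad <- function(m, fill) {
        out <- matrix(fill, nrow(m) + pr, ncol(m) + pc)
        out[(top + 1L):(top + nrow(m)), (left + 1L):(left + ncol(m))] <- m
        out
      }
      patch <- pad(patch, 0)
      mask <- pad(mask, FALSE)
    }
    sparse_roi(patch, mask, bbox = bb, pixel_count = cand$pixel_count)
  })
}

#' Run the full segmentation front end on an image
#'
#' Enhancement (CLAHE + entropy fusion), optional pectoral suppression, SOM
#' clustering, PLT candidate filtering and sparse-ROI extraction in one call.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param pectoral `"off"`, `"auto"`, `"left"` or `"right"`.
#' @param M Number of SOM clusters.
#' @param iterations SOM training samples.
#' @param min_pixels,max_pixels PLT window.
#' @param seed Integer seed (SOM initialisation and sampling).
#' @param sample_cap Cap on the number of pixel features used for SOM
#'   training (features are subsampled deterministically above it).
#' @return List with `enhanced`, `cluster_map`, `candidates`, `rois`,
#'   `model`.
#' @export
segment_masses <- function(img, pectoral = "off", M = 4L, iterations = 20000L,
                           min_pixels = 450L, max_pixels = 31500L, seed = 1L,
                           sample_cap = 20000L) {
  enh <- enhance(img)
  if (pectoral != "off") enh <- remove_pectoral(enh, pectoral)
  fx <- extract_pixel_features(enh)
  feats <- fx$features
  if (nrow(feats) > sample_cap)
    feats <- with_seed(seed, feats[sample.int(nrow(feats), sample_cap), ])
  model <- train_som(feats, M = M, iterations = iterations, seed = seed)
  cmap <- assign_clusters(model, enh)
  cands <- select_candidates(cmap, enh, min_pixels, max_pixels)
  rois <- extract_rois(img, cands)
  list(enhanced = enh, cluster_map = cmap, candidates = cands, rois = rois,
       model = model)
}
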