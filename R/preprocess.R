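#' Contrast-limited adaptive histogram equalisation
#'
#' Tile-wise histogram equalisation with a clip limit, the standard CLAHE
#' enhancement. This is the "enhanced" input to [entropy_fusion()].
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param clip_limit Clip limit as a fraction of the tile pixel count
#'   (default 0.01).
#' @param tiles Number of contextual tiles per axis (length 1 or 2).
#' @return Enhanced image, clipped to `[0, 1]`.
#' @export
clahe <- function(img, clip_limit = 0.01, tiles = 8L) {
  check_gray(img)
  if (clip_limit <= 0) stop("clip_limit must be > 0", call. = FALSE)
  tiles <- rep_len(as.integer(tiles), 2L)
  if (any(tiles < 1)) stop("tiles must be >= 1 per axis", call. = FALSE)
  if (max(img) - min(img) < .Machine$double.eps) return(img)
  bins <- 256L
  out <- EBImage::clahe(img, nx = tiles[1], ny = tiles[2], bins = bins,
                        limit = max(clip_limit * bins, 1), keep.range = FALSE)
  clip01(as.matrix(EBImage::imageData(out)))
}

#' Local Shannon entropy map
#'
#' Entropy (base-2 logarithm, `0 log 0 := 0`) of the 256-bin intensity
#' histogram of the `window` x `window` neighbourhood centred at each pixel.
#' The image is quantised to 256 levels internally and borders are handled
#' by symmetric reflection, so every value lies in
#' `[0, log2(window^2)]` bits.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param window Odd window side length (default 5).
#' @return Numeric matrix of entropies, same shape as `img`.
#' @export
local_entropy <- function(img, window = 5L) {
  check_gray(img)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3", call. = FALSE)
  .local_entropy_cpp(img, window)
}

#' Entropy-maximising image fusion
#'
#' Fuses two registered images pixel by pixel: each output pixel takes its
#' value from whichever source image has the larger local entropy at that
#' position (ties go to `orig`). With `enhanced = clahe(orig)` this is the
#' contrast-enhancement rule used by the pipeline: keep CLAHE output only
#' where it increases local information content.
#'
#' @param orig,enhanced Numeric matrices in `[0, 1]`, same shape.
#' @param window Odd entropy window (default 5).
#' @return Fused image, same shape.
#' @export
entropy_fusion <- function(orig, enhanced, window = 5L) {
  check_gray(orig, "orig"); check_gray(enhanced, "enhanced")
  if (!all(dim(orig) == dim(enhanced)))
    stop("images must have the same shape", call. = FALSE)
  e_orig <- local_entropy(orig, window)
  e_enh <- local_entropy(enhanced, window)
  ifelse(e_enh > e_orig, enhanced, orig)
}

#' Enhance a mammogram by CLAHE + entropy fusion
#'
#' Convenience wrapper: `entropy_fusion(img, clahe(img, ...), window)`.
#'
#' @inheritParams clahe
#' @inheritParams entropy_fusion
#' @return Enhanced image in `[0, 1]`.
#' @export
enhance <- function(img, clip_limit = 0.01, tiles = 8L, window = 5L) {
  entropy_fusion(img, clahe(img, clip_limit, tiles), window)
}

#' Segment the breast region
#'
#' Otsu threshold, largest 8-connected foreground component, holes filled.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @return Logical matrix: `TRUE` inside the breast.
#' @export
breast_mask <- function(img) {
  check_gray(img)
  if (max(img) <= 0) stop("image has empty foreground (all zero)", call. = FALSE)
  th <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256L)
  fg <- img > th
  if (!any(fg)) stop("image has empty foreground after thresholding", call. = FALSE)
  lab <- .label8_cpp(fg)
  counts <- tabulate(lab[lab > 0L], nbins = attr(lab, "n"))
  mask <- lab == which.max(counts)
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  as.matrix(EBImage::imageData(filled)) > 0.5
}

#' Suppress the pectoral muscle
#'
#' Searches the top-corner rectangle on the pectoral side (top 40 % of rows,
#' near-chest-wall 50 % of columns) for the strongest horizontal intensity
#' edge in each row, fits a straight line to those edge points by least
#' squares, and zeroes the pixels between the chest wall and the fitted line.
#' If too few rows contain a convincing edge, or the region delimited by the
#' fitted line is not actually brighter than the surrounding tissue (the
#' pectoral muscle is the brightest structure in that corner), the image is
#' returned unchanged with a warning.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param side `"auto"`, `"left"` or `"right"` — which top corner holds the
#'   pectoral muscle. `"auto"` picks the brighter top corner.
#' @param min_gradient Minimum edge strength for a row to contribute a point.
#' @param min_rows Minimum number of edge rows required to fit the line.
#' @param intensity_margin Minimum brightness excess of the cut region over
#'   the remaining top-corner tissue for the cut to be applied.
#' @return Image with the pectoral triangle set to 0.
#' @export
remove_pectoral <- function(img, side = c("auto", "left", "right"),
                            min_gradient = 0.1, min_rows = 5L,
                            intensity_margin = 0.05) {
  check_gray(img)
  side <- match.arg(side)
  nr <- nrow(img); nc <- ncol(img)
  top <- seq_len(max(2L, floor(0.4 * nr)))
  if (side == "auto") {
    lmean <- mean(img[top, seq_len(floor(nc / 4))])
    rmean <- mean(img[top, (nc - floor(nc / 4) + 1):nc])
    side <- if (lmean >= rmean) "left" else "right"
  }
  flip <- side == "right"
  x <- if (flip) img[, nc:1] else img

  cols <- seq_len(max(3L, floor(0.5 * nc)))
  rect <- x[top, cols, drop = FALSE]
  grad <- abs(rect[, -1, drop = FALSE] - rect[, -ncol(rect), drop = FALSE])
  best <- max.col(grad, ties.method = "first")
  strength <- grad[cbind(seq_along(best), best)]
  keep <- strength >= min_gradient
  if (sum(keep) < min_rows) {
    warning("no pectoral edge found; image returned unchanged")
    return(img)
  }
  fit <- stats::lm.fit(cbind(1, top[keep]), best[keep] + 0.5)
  cut <- fit$coefficients[1] + fit$coefficients[2] * top
  cut <- pmin(pmax(round(cut), 0L), nc)
  zone <- matrix(FALSE, nr, nc)
  for (i in seq_along(top)) if (cut[i] >= 1) zone[top[i], seq_len(cut[i])] <- TRUE
  rest <- matrix(FALSE, nr, nc)
  rest[top, cols] <- TRUE
  rest <- rest & !zone
  # compare tissue only: the dark off-breast background would otherwise
  # drag the reference mean down and let any bright corner pass
  tissue <- x > 0.1
  zone_mean <- if (any(zone & tissue)) mean(x[zone & tissue]) else 0
  rest_mean <- if (any(rest & tissue)) mean(x[rest & tissue]) else 0
  if (!any(zone) || zone_mean < rest_mean + intensity_margin) {
    warning("no pectoral muscle evident; image returned unchanged")
    return(img)
  }
  x[zone] <- 0
  if (flip) x[, nc:1] else x
}
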