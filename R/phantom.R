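#' Specification for a synthetic mammogram phantom
#'
#' Collects the parameters of the phantom generator: image size, number of
#' masses, mass size range, boundary irregularity, mass-over-background
#' contrast, additive noise level, and whether a pectoral-muscle wedge is
#' drawn in the top corner.
#'
#' @param width,height Image size in pixels (at least 64 x 64).
#' @param n_masses Number of bright masses to plant (>= 0).
#' @param mass_radius_range Length-2 vector, min/max mean mass radius (px).
#' @param irregularity Radial perturbation amplitude of the mass boundary,
#'   in `[0, 1]`; 0 gives smooth ellipses, larger values star-shaped borders.
#' @param contrast Peak mass intensity above the local background, in
#'   `[0, 1]` intensity units.
#' @param noise_sigma Standard deviation of additive pixel noise.
#' @param with_pectoral Draw a brighter pectoral-muscle wedge in the top
#'   corner on `pectoral_side`.
#' @param pectoral_side `"left"` or `"right"`.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `phantom_spec` (a list of the above).
#' @export
phantom_spec <- function(width = 256L, height = 256L, n_masses = 2L,
                         mass_radius_range = c(15, 32), irregularity = 0.3,
                         contrast = 0.4, noise_sigma = 0.02,
                         with_pectoral = FALSE, pectoral_side = "left",
                         seed = 1L) {
  if (width < 64 || height < 64)
    stop("phantom dimensions must be at least 64 x 64", call. = FALSE)
  if (n_masses < 0) stop("n_masses must be >= 0", call. = FALSE)
  if (irregularity < 0 || irregularity > 1)
    stop("irregularity must lie in [0, 1]", call. = FALSE)
  if (contrast <= 0) stop("contrast must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  pectoral_side <- match.arg(pectoral_side, c("left", "right"))
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_masses = as.integer(n_masses),
                 mass_radius_range = mass_radius_range,
                 irregularity = irregularity, contrast = contrast,
                 noise_sigma = noise_sigma, with_pectoral = with_pectoral,
                 pectoral_side = pectoral_side, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Irregular ("star-perturbed") radius profile: r(theta) = r0 * (1 + irr * sum_k
# a_k cos(k theta + phi_k)), harmonics k = 2..5, amplitudes a_k >= 0 summing
# to 1 so the factor stays within [1 - irr, 1 + irr].
star_radius <- function(theta, r0, irregularity) {
  k <- 2:5
  a <- runif(4)
  a <- a / sum(a)
  phi <- runif(4, 0, 2 * pi)
  pert <- rowSums(vapply(seq_along(k),
                         function(j) a[j] * cos(k[j] * theta + phi[j]),
                         numeric(length(theta))))
  r0 * (1 + irregularity * pert)
}

# Logical mask of one star-perturbed mass on an nr x nc grid.
mass_mask_at <- function(nr, nc, cy, cx, r0, irregularity) {
  half <- ceiling(r0 * 2) + 2
  rows <- max(1, floor(cy - half)):min(nr, ceiling(cy + half))
  cols <- max(1, floor(cx - half)):min(nc, ceiling(cx + half))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  theta <- atan2(dx, dy)      # orientation convention is arbitrary but fixed
  d <- sqrt(dy^2 + dx^2)
  rtheta <- matrix(star_radius(as.vector(theta), r0, irregularity),
                   nrow = length(rows))
  inside <- d <= rtheta
  mask <- matrix(FALSE, nr, nc)
  mask[rows, cols] <- inside
  # normalised radial coordinate (0 centre, 1 boundary) for the bump profile
  rho <- matrix(1, nr, nc)
  rho[rows, cols] <- pmin(d / pmax(rtheta, 1e-9), 1)
  list(mask = mask, rho = rho)
}

#' Generate a synthetic mammogram phantom
#'
#' Produces a mammogram-like test image: a breast half-disc against a dark
#' background, with a smoothly varying intensity ramp (brightest at the chest
#' wall), correlated background texture, optional pectoral-muscle wedge, and
#' `n_masses` bright masses with irregular borders. Masses are pairwise
#' disjoint and lie fully inside the breast; each is a local intensity
#' maximum relative to its surrounding annulus.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `image` (matrix in
#'   `[0, 1]`), `masses` (list of logical matrices, one per planted mass),
#'   `pectoral` (logical matrix or `NULL`), `breast` (logical matrix of the
#'   half-disc) and `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(n_masses = 1, seed = 7))
#' range(ph$image)
#' sum(ph$masses[[1]])
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    nr <- spec$height; nc <- spec$width
    flip <- spec$pectoral_side == "right"

    # breast half-disc: chest wall along the left image edge
    cy <- nr / 2
    Rx <- 0.92 * nc; Ry <- 0.46 * nr
    col_d <- outer(rep(1, nr), (seq_len(nc) - 1) / Rx)
    row_d <- outer((seq_len(nr) - cy) / Ry, rep(1, nc))
    breast <- (col_d^2 + row_d^2) <= 1

    # intensity ramp, brightest near the chest wall, plus correlated texture
    ramp <- 0.32 - 0.12 * sqrt(pmin(col_d^2 + row_d^2, 1))
    img <- ifelse(breast, ramp, 0.02)
    tex <- gauss_smooth(matrix(rnorm(nr * nc), nr, nc), sigma = 4)
    tex <- tex / max(sd(tex), 1e-12) * 0.035
    img <- img + ifelse(breast, tex, 0)

    pect <- NULL
    if (spec$with_pectoral) {
      # top-corner triangle: (row 1, chest wall) to (row 1, 0.35 w) to
      # (0.45 h, chest wall), at a fixed brighter level
      rr <- outer(seq_len(nr), rep(1, nc))
      cc <- outer(rep(1, nr), seq_len(nc))
      pect <- (cc / (0.35 * nc) + rr / (0.45 * nr)) <= 1 & breast
      img[pect] <- 0.55
    }

    masses <- list()
    rho_maps <- list()
    if (spec$n_masses > 0) {
      centers <- matrix(numeric(0), 0, 3)  # cy, cx, r0
      tries <- 0L
      while (nrow(centers) < spec$n_masses) {
        tries <- tries + 1L
        if (tries > 500L)
          stop("could not place ", spec$n_masses,
               " disjoint masses inside the breast region", call. = FALSE)
        r0 <- runif(1, spec$mass_radius_range[1], spec$mass_radius_range[2])
        if (1 + r0 * 1.6 >= nr - r0 * 1.6 || 1 + r0 * 1.6 >= nc - r0 * 1.6)
          stop("mass radius too large for the image dimensions", call. = FALSE)
        my <- runif(1, 1 + r0 * 1.6, nr - r0 * 1.6)
        mx <- runif(1, 1 + r0 * 1.6, nc - r0 * 1.6)
        # fully inside the breast (margin beyond the max perturbed radius)
        marg <- r0 * (1 + spec$irregularity) + 3
        if (((mx + marg - 1) / Rx)^2 + ((my - cy) / Ry)^2 > 1 ||
            ((mx - 1) / Rx)^2 + ((abs(my - cy) + marg) / Ry)^2 > 1) next
        if (!is.null(pect) &&
            (mx / (0.35 * nc) + my / (0.45 * nr)) <= 1.3) next
        if (nrow(centers) > 0) {
          dd <- sqrt((centers[, 1] - my)^2 + (centers[, 2] - mx)^2)
          if (any(dd < centers[, 3] * (1 + spec$irregularity) +
                       r0 * (1 + spec$irregularity) + 6)) next
        }
        centers <- rbind(centers, c(my, mx, r0))
      }
      for (i in seq_len(spec$n_masses)) {
        mm <- mass_mask_at(nr, nc, centers[i, 1], centers[i, 2],
                           centers[i, 3], spec$irregularity)
        masses[[i]] <- mm$mask
        rho_maps[[i]] <- mm$rho
        # smooth bump: contrast at the core, tapering to 0 at the boundary
        img <- img + ifelse(mm$mask, spec$contrast * (1 - mm$rho^4), 0)
      }
    }

    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(nr * nc, sd = spec$noise_sigma), nr, nc)
    img <- clip01(img)

    if (flip) {
      img <- img[, nc:1]
      breast <- breast[, nc:1]
      if (!is.null(pect)) pect <- pect[, nc:1]
      masses <- lapply(masses, function(m) m[, nc:1])
    }

    for (m in masses) {
      if (sum(m) < 1) stop("internal: empty mass mask", call. = FALSE)
      bb <- mask_bbox(m)
      if (bb[3] - bb[1] < 5 || bb[4] - bb[2] < 5)
        stop("internal: mass bounding box below 5 x 5", call. = FALSE)
    }

    structure(list(image = img, masses = masses, pectoral = pect,
                   breast = breast, spec = spec), class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Synthetic mammogram phantom: %d x %d px, %d mass(es)%s\n",
              nrow(x$image), ncol(x$image), length(x$masses),
              if (is.null(x$pectoral)) "" else ", pectoral wedge"))
  invisible(x)
}

# Tight half-open bounding box (row0, col0, row1, col1) of a logical mask.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]) + 1L, max(idx[, 2]) + 1L)
}

#' Generate a sparse region-of-interest patch
#'
#' A sparse ROI is a rectangular patch in which every pixel outside an
#' irregular mass-like shape is exactly zero and every pixel inside is
#' strictly positive. The minimum accepted patch size is 25 x 22 pixels,
#' the smallest mass ROI the pipeline is designed around.
#'
#' @param size Length-2 integer vector `(rows, cols)`, at least `c(25, 22)`.
#' @param irregularity Boundary perturbation amplitude in `[0, 1]`; 0 gives
#'   an axis-aligned ellipse.
#' @param contrast Peak in-shape intensity in `[0, 1]` units.
#' @param seed Integer seed.
#' @param texture Standard deviation of multiplicative in-shape texture.
#' @return An object of class `sparse_roi`: list with `pixels` (numeric
#'   matrix), `mask` (logical matrix of the in-shape support) and `bbox`
#'   (`NULL` for generated patches).
#' @export
make_sparse_roi <- function(size = c(40, 40), irregularity = 0.3,
                            contrast = 0.4, seed = 1L, texture = 0.1) {
  size <- as.integer(size)
  if (length(size) != 2L || size[1] < 25L || size[2] < 22L)
    stop("sparse ROI size must be at least 25 x 22 pixels", call. = FALSE)
  with_seed(seed, {
    nr <- size[1]; nc <- size[2]
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    ry <- 0.40 * nr; rx <- 0.40 * nc
    dy <- outer((seq_len(nr) - cy) / ry, rep(1, nc))
    dx <- outer(rep(1, nr), (seq_len(nc) - cx) / rx)
    d <- sqrt(dy^2 + dx^2)
    theta <- atan2(dx, dy)
    if (irregularity > 0) {
      fac <- matrix(star_radius(as.vector(theta), 1, irregularity), nr, nc)
    } else fac <- matrix(1, nr, nc)
    mask <- d <= fac
    rho <- pmin(d / pmax(fac, 1e-9), 1)
    tex <- 1 + gauss_smooth(matrix(rnorm(nr * nc), nr, nc), sigma = 2) * texture
    px <- contrast * (1 - rho^4) * tex
    px <- ifelse(mask, pmax(px, 0.02), 0)
    sparse_roi(clip01(px), mask)
  })
}

# Constructor: pixels outside `mask` must be exactly zero, inside > 0.
sparse_roi <- function(pixels, mask, bbox = NULL, pixel_count = sum(mask)) {
  stopifnot(all(dim(pixels) == dim(mask)))
  structure(list(pixels = pixels, mask = mask, bbox = bbox,
                 pixel_count = pixel_count), class = "sparse_roi")
}

#' @export
print.sparse_roi <- function(x, ...) {
  cat(sprintf("Sparse ROI: %d x %d px, %d foreground pixel(s)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$mask)))
  invisible(x)
}

#' Generate a labelled set of positive and negative sparse ROIs
#'
#' Positives emulate true mass patches: high-contrast, irregular bright
#' shapes. Negatives emulate false-positive candidate patches: the same
#' sparse support structure but low-contrast texture. The returned list is
#' shuffled deterministically by `seed`.
#'
#' @param n_pos,n_neg Numbers of positive / negative ROIs (>= 0).
#' @param seed Integer seed.
#' @param size_range Range of patch side lengths (rows and cols drawn
#'   independently), at least `c(25, 22)` after rounding.
#' @param pos_contrast,neg_contrast Peak contrast ranges for the two classes.
#' @return A list with one element per ROI: `list(roi = sparse_roi,
#'   label = 1 or 0, group = integer)`; `group` identifies the source patch
#'   so augmented copies can be kept in the same cross-validation fold.
#' @export
make_labeled_roi_set <- function(n_pos, n_neg, seed = 1L,
                                 size_range = c(30, 60),
                                 pos_contrast = c(0.35, 0.5),
                                 neg_contrast = c(0.08, 0.16)) {
  if (n_pos < 0 || n_neg < 0) stop("counts must be >= 0", call. = FALSE)
  if (n_pos + n_neg == 0) return(list())
  with_seed(seed, {
    make_one <- function(i, positive) {
      nr <- max(25L, as.integer(round(runif(1, size_range[1], size_range[2]))))
      nc <- max(22L, as.integer(round(runif(1, size_range[1], size_range[2]))))
      cr <- if (positive) runif(1, pos_contrast[1], pos_contrast[2])
            else runif(1, neg_contrast[1], neg_contrast[2])
      irr <- if (positive) runif(1, 0.2, 0.5) else runif(1, 0.1, 0.6)
      tex <- if (positive) 0.1 else 0.35
      make_sparse_roi(c(nr, nc), irregularity = irr, contrast = cr,
                      seed = sample.int(.Machine$integer.max, 1), texture = tex)
    }
    set <- c(
      lapply(seq_len(n_pos), function(i)
        list(roi = make_one(i, TRUE), label = 1L, group = i)),
      lapply(seq_len(n_neg), function(i)
        list(roi = make_one(i, FALSE), label = 0L, group = n_pos + i))
    )
    set[sample.int(length(set))]
  })
}
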