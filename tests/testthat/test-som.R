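test_that("pixel features read the 3x3 neighbourhood row-major with reflected borders", {
  const <- matrix(0.4, 5, 5)
  fx <- extract_pixel_features(const)
  expect_true(all(fx$features == 0.4))
  expect_identical(dim(fx$features), c(25L, 9L))
  m <- matrix(1:9 / 10, 3, 3)
  fx3 <- extract_pixel_features(m)
  centre <- fx3$features[fx3$rows == 2 & fx3$cols == 2, ]
  expect_equal(centre, as.vector(t(m)))
  expect_error(extract_pixel_features(matrix(0.1, 2, 5)), "3 x 3")
})

test_that("pixel features equal brute-force window gathers at random positions", {
  set.seed(5)
  img <- matrix(runif(64), 8, 8)
  pad <- rbind(img[1, ], img, img[8, ])
  pad <- cbind(pad[, 1], pad, pad[, 8])
  fx <- extract_pixel_features(img)
  for (k in sample(64, 5)) {
    r <- fx$rows[k]; c <- fx$cols[k]
    win <- pad[r:(r + 2), c:(c + 2)]
    expect_equal(fx$features[k, ], as.vector(t(win)))
  }
})

test_that("SOM training converges to a single repeated feature", {
  f <- matrix(rep(c(0.2, 0.8, 0.5, 0.1, 0.9, 0.3, 0.6, 0.4, 0.7), 50),
              ncol = 9, byrow = TRUE)
  model <- train_som(f, M = 4, iterations = 2000, seed = 2)
  d <- apply(model$weights, 1, function(w) sqrt(sum((w - f[1, ])^2)))
  expect_lt(min(d), 1e-3)
})

test_that("a zero learning rate leaves the initial weights untouched", {
  set.seed(99)
  f <- matrix(runif(90), 10, 9)
  m0 <- train_som(f, M = 4, iterations = 1, eta0 = 0, seed = 31)
  m1 <- train_som(f, M = 4, iterations = 500, eta0 = 0, seed = 31)
  expect_identical(m0$weights, m1$weights)
})

test_that("an update with kernel weight in (0, 1] never moves the winner away", {
  set.seed(14)
  for (rep in 1:20) {
    w <- runif(9); f <- runif(9)
    nci <- runif(1)
    w2 <- w + nci * (f - w)
    expect_lte(sqrt(sum((f - w2)^2)), sqrt(sum((f - w)^2)) + 1e-12)
  }
})

test_that("cluster assignment equals brute-force nearest-weight search", {
  set.seed(8)
  img <- matrix(runif(16 * 16), 16, 16)
  model <- train_som(extract_pixel_features(img), M = 4,
                     iterations = 2000, seed = 8)
  cmap <- assign_clusters(model, img)
  fx <- extract_pixel_features(img)
  for (k in seq_len(nrow(fx$features))) {
    expect_identical(cmap[fx$rows[k], fx$cols[k]],
                     naive_bmu(model$weights, fx$features[k, ]))
  }
})

test_that("four well-separated plateaus are recovered almost perfectly", {
  skip_if_not_installed("mclust")
  levels <- c(0.05, 0.35, 0.65, 0.95)
  truth <- matrix(rep(rep(1:4, each = 8), 32), 32, 32, byrow = TRUE)
  img <- matrix(levels[truth], 32, 32)
  model <- train_som(extract_pixel_features(img), M = 4,
                     iterations = 5000, seed = 4)
  cmap <- assign_clusters(model, img)
  interior <- truth[, -c(8, 9, 16, 17, 24, 25)]  # drop plateau borders
  pred <- cmap[, -c(8, 9, 16, 17, 24, 25)]
  ari <- mclust::adjustedRandIndex(as.vector(pred), as.vector(interior))
  expect_gte(ari, 0.9)
})

test_that("a constant image lands in a single cluster", {
  img <- matrix(0.5, 20, 20)
  model <- train_som(extract_pixel_features(img), M = 4,
                     iterations = 500, seed = 3)
  expect_length(unique(as.vector(assign_clusters(model, img))), 1L)
})

test_that("candidate selection applies the pixel-level threshold window", {
  # cluster map with two bright components: 100 px and 2000 px
  cmap <- matrix(1L, 100, 100)
  img <- matrix(0.1, 100, 100)
  cmap[10:19, 10:19] <- 2L                  # 100 px
  cmap[40:79, 40:89] <- 2L                  # 2000 px
  img[cmap == 2L] <- 0.9
  cands <- select_candidates(cmap, img, min_pixels = 450, max_pixels = 31500)
  expect_length(cands, 1L)
  expect_identical(cands[[1]]$pixel_count, 2000L)
  # both pass under a wider window
  wide <- select_candidates(cmap, img, min_pixels = 50, max_pixels = 50000)
  expect_length(wide, 2L)
  expect_error(select_candidates(cmap, img, 0, 100), "min_pixels")
})

test_that("widening the PLT window never removes a candidate (monotonicity)", {
  set.seed(17)
  ph <- make_phantom(phantom_spec(width = 128, height = 128, seed = 17,
                                  mass_radius_range = c(10, 16)))
  seg <- segment_masses(ph$image, seed = 17, min_pixels = 200,
                        max_pixels = 31500)
  narrow <- seg$candidates
  expect_gt(length(narrow), 0L)
  wide <- select_candidates(seg$cluster_map, seg$enhanced,
                            min_pixels = 50, max_pixels = 60000)
  expect_gte(length(wide), length(narrow))
  narrow_boxes <- lapply(narrow, `[[`, "bbox")
  wide_boxes <- lapply(wide, `[[`, "bbox")
  for (bb in narrow_boxes)
    expect_true(any(vapply(wide_boxes, identical, logical(1), bb)))
})

test_that("ROI extraction crops, zeroes the background and pads to 25 x 22", {
  img <- matrix(runif(60 * 60, 0.2, 0.9), 60, 60)
  # full-rectangle candidate: nothing zeroed
  rect <- structure(list(mask = matrix(TRUE, 30, 30),
                         bbox = c(11L, 11L, 41L, 41L), pixel_count = 900L),
                    class = "region_candidate")
  roi <- extract_rois(img, list(rect))[[1]]
  expect_equal(roi$pixels, img[11:40, 11:40])
  # irregular mask: nonzero count equals the candidate pixel count
  m <- matrix(FALSE, 30, 30); m[cbind(sample(30, 100, TRUE), sample(30, 100, TRUE))] <- TRUE
  irr <- structure(list(mask = m, bbox = c(11L, 11L, 41L, 41L),
                        pixel_count = sum(m)), class = "region_candidate")
  roi2 <- extract_rois(img, list(irr))[[1]]
  expect_identical(sum(roi2$pixels != 0), sum(m))
  # 10 x 10 candidate: padded to the 25 x 22 minimum
  small <- structure(list(mask = matrix(TRUE, 10, 10),
                          bbox = c(5L, 5L, 15L, 15L), pixel_count = 100L),
                     class = "region_candidate")
  roi3 <- extract_rois(img, list(small))[[1]]
  expect_identical(dim(roi3$pixels), c(25L, 22L))
  expect_identical(sum(roi3$pixels != 0), 100L)
})
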