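test_that("the uniform codebook holds exactly the 58 uniform patterns, bijectively", {
  cb <- ulbp_codebook()
  expect_length(cb$patterns, 58L)
  expect_identical(sort(unique(cb$bins[!is.na(cb$bins)])), 1:58)
  expect_identical(sum(!is.na(cb$bins)), 58L)
  # spot-check uniformity: 0x00 and 0xFF are uniform, 0b01010101 is not
  expect_false(is.na(cb$bins[0 + 1]))
  expect_false(is.na(cb$bins[255 + 1]))
  expect_true(is.na(cb$bins[85 + 1]))
})

test_that("single-window codes follow the >= comparison and uniformity rule", {
  # all neighbours equal to the centre: S(0) = 1, pattern 11111111
  expect_identical(ulbp_code(matrix(0.5, 3, 3)), ulbp_codebook()$bins[256])
  # all neighbours below the centre: pattern 00000000
  m <- matrix(0.1, 3, 3); m[2, 2] <- 0.9
  expect_identical(ulbp_code(m), ulbp_codebook()$bins[1])
  # alternating above/below around the ring: 8 transitions, non-uniform
  alt <- matrix(0.5, 3, 3)
  ring <- rbind(c(2, 3), c(1, 3), c(1, 2), c(1, 1),
                c(2, 1), c(3, 1), c(3, 2), c(3, 3))  # CCW from east
  alt[ring] <- rep(c(0.9, 0.1), 4)
  expect_true(is.na(ulbp_code(alt)))
})

test_that("the lookup table flags foreground iff a window has more than 2 nonzeros", {
  expect_false(any(build_lookup(matrix(0, 5, 5))$foreground))
  expect_true(all(build_lookup(matrix(1, 5, 5))$foreground))
  # 3-pixel diagonal in a 5x5 grid: enumerate all 9 interior windows
  g <- matrix(0, 5, 5); g[cbind(2:4, 2:4)] <- 1
  lut <- build_lookup(g)
  expect_identical(nrow(lut), 9L)
  counts <- vapply(seq_len(9), function(k) {
    i <- lut$row[k]; j <- lut$col[k]
    sum(g[(i - 1):(i + 1), (j - 1):(j + 1)] != 0)
  }, numeric(1))
  expect_identical(lut$foreground, counts > 2)
  expect_identical(lut$foreground, lut$nonzero > 2L)
  # the centre window covers all 3 diagonal pixels
  expect_true(lut$foreground[lut$row == 3 & lut$col == 3])
  expect_error(build_lookup(matrix(0, 2, 5)), "3 x 3")
})

test_that("a window with exactly 2 nonzeros is background (count > 2 is strict)", {
  g <- matrix(0, 3, 3); g[1, 1] <- 1; g[3, 3] <- 1
  expect_false(build_lookup(g)$foreground)
})

test_that("sparse histograms have 58 bins summing to 1, or all zero when empty", {
  h0 <- sparse_lbp_hist(matrix(0, 10, 10))
  expect_length(h0$bins, 58L)
  expect_true(all(h0$bins == 0))
  expect_identical(h0$n_foreground, 0L)
  set.seed(2)
  h <- sparse_lbp_hist(random_sparse_band(20, 20, 0.6))
  expect_equal(sum(h$bins), 1)
  expect_true(all(h$bins >= 0))
})

test_that("on a fully dense band the sparse histogram equals the plain ULBP histogram", {
  set.seed(3)
  band <- matrix(runif(18 * 18, 0.1, 1), 18, 18)
  h <- sparse_lbp_hist(band, tol = 0)
  # plain oracle over every interior pixel
  expect_equal(h$bins, naive_sparse_hist(band, tol = 0))
  expect_identical(h$n_foreground, 16L * 16L)
})

test_that("the lookup path equals the naive per-pixel oracle on random sparse bands", {
  set.seed(4)
  for (rep in 1:20) {
    nr <- sample(5:32, 1); nc <- sample(5:32, 1)
    band <- random_sparse_band(nr, nc, runif(1, 0.1, 0.9))
    h <- sparse_lbp_hist(band, tol = 0)
    expect_equal(h$bins, naive_sparse_hist(band, tol = 0), tolerance = 1e-12)
  }
})

test_that("the histogram is invariant to translations that keep windows interior", {
  set.seed(5)
  core <- random_sparse_band(8, 8, 0.5)
  emb <- function(dr, dc) {
    m <- matrix(0, 20, 20)
    m[(4 + dr):(11 + dr), (4 + dc):(11 + dc)] <- core
    m
  }
  h1 <- sparse_lbp_hist(emb(0, 0))
  h2 <- sparse_lbp_hist(emb(3, 5))
  expect_equal(h1$bins, h2$bins)
  expect_identical(h1$n_foreground, h2$n_foreground)
})

test_that("sparse selection never evaluates more windows than the dense descriptor", {
  set.seed(6)
  for (rep in 1:5) {
    band <- random_sparse_band(15, 15, runif(1, 0.2, 0.8))
    h <- sparse_lbp_hist(band)
    expect_lte(h$n_foreground, 13L * 13L)
  }
  dense <- matrix(runif(15 * 15, 0.1, 1), 15, 15)
  expect_identical(sparse_lbp_hist(dense)$n_foreground, 13L * 13L)
})

test_that("the ROI descriptor concatenates 17 x 58 = 986 features deterministically", {
  roi <- make_sparse_roi(c(30, 28), seed = 9)
  fv <- describe_roi(roi)
  expect_length(fv, 986L)
  expect_identical(fv, describe_roi(roi))
  expect_true(all(is.finite(fv)))
  z <- mammocad:::sparse_roi(matrix(0, 30, 30), matrix(FALSE, 30, 30))
  expect_true(all(describe_roi(z) == 0))
  expect_error(describe_roi(matrix(0.1, 10, 10)), "25 x 22")
})

test_that("foreground selection reduces the evaluated windows, matching a brute-force count", {
  roi <- make_sparse_roi(c(32, 30), seed = 10)
  fv <- describe_roi(roi)
  red <- attr(fv, "reduction")
  expect_identical(nrow(red), 17L)
  expect_true(all(red$n_foreground <= red$n_windows))
  expect_true(any(red$n_foreground < red$n_windows))
  # recompute the per-band foreground count without the lookup table
  dec <- fdct_forward(roi$pixels)
  bands <- subband_list(dec)
  for (i in c(1, 5, 12)) {
    b <- bands[[i]]
    tol <- 1e-2 * max(abs(b))
    nz <- abs(b) > tol
    cnt <- 0L
    for (r in 2:(nrow(b) - 1)) for (cc in 2:(ncol(b) - 1))
      if (sum(nz[(r - 1):(r + 1), (cc - 1):(cc + 1)]) > 2) cnt <- cnt + 1L
    expect_identical(red$n_foreground[i], cnt)
  }
})

test_that("the spatial-domain descriptor matches the plain histogram on dense ROIs", {
  set.seed(11)
  dense <- mammocad:::sparse_roi(matrix(runif(28 * 26, 0.1, 1), 28, 26),
                                 matrix(TRUE, 28, 26))
  h <- spatial_sparse_lbp(dense)
  expect_equal(h$bins, naive_sparse_hist(dense$pixels, tol = 0))
  # support too sparse for any window: zero histogram
  px <- matrix(0, 30, 30); px[seq(2, 28, by = 4), 15] <- 0.5
  h0 <- spatial_sparse_lbp(px)
  expect_true(all(h0$bins == 0))
})
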