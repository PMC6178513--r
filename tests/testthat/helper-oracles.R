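# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorised/lookup code paths.

# Per-window histogram entropy, computed pixel by pixel.
naive_local_entropy <- function(img, window = 5L) {
  h <- window %/% 2L
  q <- matrix(as.integer(round(pmin(pmax(img, 0), 1) * 255)), nrow(img))
  ref <- function(i, n) {
    period <- 2L * n
    i <- ((i - 1L) %% period + period) %% period
    ifelse(i >= n, period - 1L - i, i) + 1L
  }
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    vals <- q[ref(seq(i - h, i + h), nrow(img)),
              ref(seq(j - h, j + h), ncol(img))]
    p <- table(vals) / length(vals)
    out[i, j] <- -sum(p * log2(p))
  }
  out
}

# Scalar uniform LBP code of a 3x3 matrix; returns bin 1..58 or NA.
naive_ulbp <- local({
  trans <- function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(abs(bits - bits[c(2:8, 1)]))
  }
  u <- vapply(0:255, trans, integer(1))
  bins <- rep(NA_integer_, 256)
  bins[which(u <= 2) ] <- seq_len(sum(u <= 2))
  function(m) {
    gc <- m[2, 2]
    nb <- c(m[2, 3], m[1, 3], m[1, 2], m[1, 1], m[2, 1], m[3, 1], m[3, 2], m[3, 3])
    code <- sum((nb >= gc) * 2^(0:7))
    bins[code + 1]
  }
})

# Naive sparse uniform-LBP histogram: explicit loop over every interior
# pixel, count nonzeros in its window, apply the > 2 rule, histogram the
# uniform codes.
naive_sparse_hist <- function(band, tol = 0) {
  bins <- numeric(58)
  n_ret <- 0L
  for (i in 2:(nrow(band) - 1)) for (j in 2:(ncol(band) - 1)) {
    win <- band[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (sum(abs(win) > tol) > 2) {
      b <- naive_ulbp(win)
      if (!is.na(b)) { bins[b] <- bins[b] + 1; n_ret <- n_ret + 1L }
    }
  }
  if (n_ret > 0) bins / n_ret else bins
}

# Brute-force best-matching-unit assignment for a SOM.
naive_bmu <- function(weights, feat) {
  d <- apply(weights, 1, function(w) sum((w - feat)^2))
  which.min(d)
}

# AUC as the normalised Mann-Whitney U statistic (ties counted 1/2).
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small random sparse band: smooth blob support with values inside.
random_sparse_band <- function(nr, nc, density = 0.4) {
  mask <- matrix(runif(nr * nc) < density, nr, nc)
  band <- matrix(rnorm(nr * nc), nr, nc)
  band[!mask] <- 0
  band
}
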