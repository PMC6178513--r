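#' @useDynLib mammocad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft predict rnorm runif sd
#' @importFrom utils read.csv write.csv
NULL

# Validate a grayscale image: numeric matrix, finite, values in [0, 1].
check_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  if (min(img) < 0 || max(img) > 1)
    stop(sprintf("`%s` must have intensities in [0, 1]", arg), call. = FALSE)
  invisible(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Symmetric (edge-including) reflection indices for padding.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  i <- ((i - 1L) %% period + period) %% period
  ifelse(i >= n, period - 1L - i, i) + 1L
}

# Pad a matrix by k pixels on every side with symmetric reflection.
reflect_pad <- function(x, k) {
  ri <- reflect_index(seq(1L - k, nrow(x) + k), nrow(x))
  ci <- reflect_index(seq(1L - k, ncol(x) + k), ncol(x))
  x[ri, ci, drop = FALSE]
}

# Run the RNG at a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Gaussian smoothing of a matrix (EBImage handles the separable filter).
gauss_smooth <- function(x, sigma) {
  as.matrix(EBImage::imageData(EBImage::gblur(x, sigma = sigma)))
}
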