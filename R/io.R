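#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM (plain `P2` or binary `P5`) images as a numeric
#' matrix with intensities scaled to `[0, 1]`. Colour images are converted to
#' grayscale by channel averaging.
#'
#' @param path Path to the image file; format is chosen by extension.
#' @return A numeric matrix (rows x columns) with values in `[0, 1]`.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      x <- png::readPNG(path)
      if (length(dim(x)) == 3L) x <- apply(x[, , seq_len(min(3L, dim(x)[3]))], c(1, 2), mean)
      x
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      x <- tiff::readTIFF(path)
      if (length(dim(x)) == 3L) x <- apply(x[, , seq_len(min(3L, dim(x)[3]))], c(1, 2), mean)
      x
    },
    pgm = read_pgm(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  clip01(img)
}

#' Write a grayscale image
#'
#' Writes a `[0, 1]` intensity matrix as PNG or plain-text PGM (`P2`, 8-bit).
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param path Output path; format chosen by extension (`.png` or `.pgm`).
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  check_gray(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    pgm = write_pgm(img, path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  invisible(path)
}

# Plain-text (P2) and binary (P5) PGM reader; 8- or 16-bit.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  vals <- integer(0)
  header <- integer(0)
  # header tokens: width height maxval (skipping comments)
  buf <- character(0)
  while (length(header) < 3L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*$", "", line)
    tok <- scan(text = line, what = integer(), quiet = TRUE)
    header <- c(header, tok)
  }
  w <- header[1]; h <- header[2]; maxval <- header[3]
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    size <- if (maxval > 255) 2L else 1L
    vals <- readBin(con, "integer", n = w * h, size = size, signed = FALSE,
                    endian = "big")
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

write_pgm <- function(img, path) {
  q <- round(img * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  apply(q, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Write a set of sparse ROIs with a CSV manifest
#'
#' Each ROI patch is written as a PNG together with a `manifest.csv` listing
#' filename, class label and the source bounding box when known.
#'
#' @param rois List of [sparse_roi] objects.
#' @param dir Output directory (created if missing).
#' @param labels Optional vector of class labels, recycled along `rois`.
#' @return Data frame manifest, invisibly.
#' @export
write_roi_set <- function(rois, dir, labels = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- rep_len(labels, length(rois))
  rows <- lapply(seq_along(rois), function(i) {
    fn <- sprintf("roi_%04d.png", i)
    png::writePNG(rois[[i]]$pixels, file.path(dir, fn))
    bb <- rois[[i]]$bbox
    data.frame(filename = fn, label = labels[i],
               row0 = if (is.null(bb)) NA else bb[1],
               col0 = if (is.null(bb)) NA else bb[2],
               row1 = if (is.null(bb)) NA else bb[3],
               col1 = if (is.null(bb)) NA else bb[4],
               pixel_count = sum(rois[[i]]$mask))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
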