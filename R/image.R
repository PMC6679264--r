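#' @keywords internal
"_PACKAGE"

# Images are plain numeric matrices: the first index is the row (the "x" of
# the finite-difference stencils), intensities are real-valued, nominally on
# [0, 255]. 8-bit integer inputs are promoted to float on load; all PDE
# arithmetic is in double precision.

check_image <- function(img, arg = "image", require_nonneg = FALSE) {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` contains non-finite pixels", arg), call. = FALSE)
  if (require_nonneg && any(img < 0))
    stop(sprintf("`%s` contains negative pixels; the speckle model needs sqrt(I)",
                 arg), call. = FALSE)
  invisible(img)
}

check_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images have different dimensions", call. = FALSE)
  invisible(NULL)
}

# Evaluate f under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is left untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Separable Gaussian smoothing
#'
#' Convolves a matrix with a normalized Gaussian kernel, dimension by
#' dimension, using mirror (edge-duplicating) boundary padding. The kernel
#' radius is `floor(4*sigma + 0.5)`, so `sigma = 0` (or a radius of zero)
#' returns the input unchanged.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation of the Gaussian kernel, in pixels.
#' @return smoothed matrix of the same dimensions.
#' @export
gaussian_smooth <- function(img, sigma) {
  check_image(img)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  r <- floor(4 * sigma + 0.5)
  if (r < 1L) return(img)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  img <- convolve_rows(img, k, r)
  t(convolve_rows(t(img), k, r))
}

# 1-D convolution along the first dimension with mirror padding.
convolve_rows <- function(m, k, r) {
  nr <- nrow(m)
  idx <- c(rev(seq_len(min(r, nr))), seq_len(nr),
           nr + 1L - rev(seq_len(min(r, nr))))
  # if r > nr the mirror index set is too short; clamp instead (tiny images)
  if (r > nr) {
    idx <- pmin(pmax(seq(1L - r, nr + r), 1L), nr)
  }
  p <- m[idx, , drop = FALSE]
  out <- matrix(0, nr, ncol(m))
  for (o in seq_along(k)) {
    out <- out + k[o] * p[(o - 1L) + seq_len(nr), , drop = FALSE]
  }
  out
}

#' Read an image file as a numeric matrix
#'
#' Supports PNG and TIFF through the \pkg{png} and \pkg{tiff} packages and
#' plain PGM (P2/P5). 8-bit and 16-bit integer images are promoted to float
#' on the 0--255 scale; 32-bit float TIFFs are returned as stored. RGB images
#' are returned as a height x width x 3 array.
#'
#' @param path file path; format follows the extension.
#' @return numeric matrix (grayscale) or 3-D array (RGB).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    img <- img * 255
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    if (max(img) <= 1 + 1e-9) img <- img * 255
  } else if (ext == "pgm") {
    return(read_pgm(path))
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1L]
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  img
}

#' Write a numeric matrix (or RGB array) to an image file
#'
#' Intensities are interpreted on the 0--255 scale and clipped to
#' \code{[0, 255]} at export (raw, possibly negative, working values live in
#' memory only; clipping is a display concern). PNG and PGM are quantized to
#' 8 bits; TIFF is written as 32-bit float and keeps fractional values.
#'
#' @param img numeric matrix or height x width x 3 array.
#' @param path output path; format follows the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pmin(pmax(img / 255, 0), 1), path, bits.per.sample = 32L)
  } else if (ext == "pgm") {
    write_pgm(img, path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file", call. = FALSE)
  toks <- integer(0)
  # header: width height maxval, '#' comments allowed
  while (length(toks) < 3L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*$", "", line)
    toks <- c(toks, as.integer(strsplit(trimws(line), "\\s+")[[1]]))
  }
  w <- toks[1]; h <- toks[2]; maxv <- toks[3]
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    vals <- as.integer(readBin(con, "integer", n = w * h,
                               size = if (maxv > 255) 2L else 1L,
                               signed = FALSE, endian = "big"))
  }
  matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path) {
  q <- round(pmin(pmax(img, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), "255"), con)
  write(t(q), file = con, ncolumns = ncol(q))
  invisible(path)
}
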