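# The compressed speckle noise model and synthetic fixtures.
#
# Log-compressed ultrasound speckle behaves as signal-dependent additive
# noise: I0 = I + sqrt(I) * n with n ~ N(0, sigma^2) i.i.d. per pixel, so
# E[I0] = I and Var[I0] = I * sigma^2 -- the noise standard deviation grows
# with the square root of the gray level.

# Ellipse table of the ten-ellipse analytic head phantom (Toft contrast
# variant: the de-facto standard in image restoration work): additive
# intensity A, semi-axes a, b, center (x0, y0), rotation phi in degrees,
# on the unit square [-1, 1]^2.
shepp_logan_ellipses <- function() {
  m <- rbind(
    c( 1.0, 0.6900, 0.9200,  0.00,  0.0000,   0),
    c(-0.8, 0.6624, 0.8740,  0.00, -0.0184,   0),
    c(-0.2, 0.1100, 0.3100,  0.22,  0.0000, -18),
    c(-0.2, 0.1600, 0.4100, -0.22,  0.0000,  18),
    c( 0.1, 0.2100, 0.2500,  0.00,  0.3500,   0),
    c( 0.1, 0.0460, 0.0460,  0.00,  0.1000,   0),
    c( 0.1, 0.0460, 0.0460,  0.00, -0.1000,   0),
    c( 0.1, 0.0460, 0.0230, -0.08, -0.6050,   0),
    c( 0.1, 0.0230, 0.0230,  0.00, -0.6050,   0),
    c( 0.1, 0.0230, 0.0460,  0.06, -0.6050,   0))
  colnames(m) <- c("A", "a", "b", "x0", "y0", "phi")
  m
}

#' Analytic Shepp-Logan head phantom
#'
#' Rasterizes the standard ten-ellipse analytic head phantom on a square
#' pixel grid and rescales it linearly so the minimum pixel is 0 and the
#' maximum equals `intensity_max`. The background (e.g. any corner pixel)
#' is exactly zero.
#'
#' @param size grid side length in pixels (>= 16).
#' @param intensity_max intensity of the brightest pixel after scaling.
#' @return a `size` x `size` numeric matrix.
#' @examples
#' ph <- shepp_logan(64)
#' range(ph)
#' @export
shepp_logan <- function(size = 256L, intensity_max = 255) {
  if (!is.numeric(size) || length(size) != 1L || size < 16)
    stop("`size` must be a single integer >= 16", call. = FALSE)
  if (!is.numeric(intensity_max) || intensity_max <= 0)
    stop("`intensity_max` must be positive", call. = FALSE)
  size <- as.integer(size)
  y <- seq(1, -1, length.out = size)           # rows, top to bottom
  x <- seq(-1, 1, length.out = size)           # columns, left to right
  X <- matrix(x, size, size, byrow = TRUE)
  Y <- matrix(y, size, size)
  img <- matrix(0, size, size)
  ells <- shepp_logan_ellipses()
  for (e in seq_len(nrow(ells))) {
    p <- ells[e, ]
    th <- p["phi"] * pi / 180
    xr <- (X - p["x0"]) * cos(th) + (Y - p["y0"]) * sin(th)
    yr <- -(X - p["x0"]) * sin(th) + (Y - p["y0"]) * cos(th)
    # accumulate in tenths so overlapping contrasts cancel exactly
    img <- img + (10 * p["A"]) * ((xr / p["a"])^2 + (yr / p["b"])^2 <= 1)
  }
  img <- img - min(img)
  img * (intensity_max / max(img))
}

#' Corrupt an image with compressed speckle noise
#'
#' Draws `I0 = I + sqrt(I) * n` with `n` i.i.d. Gaussian, zero mean and
#' standard deviation `sigma`, from a seeded generator. Negative outputs are
#' kept as-is: clipping would change the noise statistics that the blind
#' stopping criteria rely on, so it is left to [write_image()] at export.
#'
#' @param clean non-negative numeric matrix (or 3-D RGB array).
#' @param sigma noise standard deviation (>= 0), on the intensity scale.
#' @param seed RNG seed; the same `(clean, sigma, seed)` always yields the
#'   same corruption. The caller's RNG stream is not disturbed.
#' @return matrix (or array) of the same shape as `clean`.
#' @export
add_speckle <- function(clean, sigma, seed) {
  if (is.array(clean) && length(dim(clean)) == 3L) {
    out <- clean
    for (ch in seq_len(dim(clean)[3]))
      out[, , ch] <- add_speckle(clean[, , ch], sigma, seed + ch - 1L)
    return(out)
  }
  check_image(clean, "clean", require_nonneg = TRUE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(clean)
  n <- with_seed(seed, stats::rnorm(length(clean), mean = 0, sd = sigma))
  clean + sqrt(clean) * matrix(n, nrow(clean), ncol(clean))
}

#' Extract the normalized noise field from an observation
#'
#' Inverts the compressed speckle model given an estimate of the clean
#' image: `n = (I0 - I) / sqrt(I)`. Pixels where the estimate is at or below
#' `eps_floor` are masked out and excluded from downstream statistics
#' (kurtosis, correlation, histogram specification), since the quotient is
#' not meaningful as the intensity approaches zero.
#'
#' @param observed the noisy image `I0`.
#' @param estimate an estimate of the clean image (e.g. the current diffusion
#'   iterate); must exceed `eps_floor` somewhere.
#' @param eps_floor positivity floor; defaults to `1e-6 * max(estimate)`.
#' @return an object of class `noise_field`: a list with `values` (matrix,
#'   `NA` where masked) and `mask` (logical matrix of valid pixels).
#' @export
extract_noise <- function(observed, estimate, eps_floor = NULL) {
  check_image(observed, "observed")
  check_image(estimate, "estimate")
  check_same_dim(observed, estimate)
  if (is.null(eps_floor)) eps_floor <- 1e-6 * max(estimate)
  mask <- estimate > eps_floor
  if (!any(mask))
    stop("degenerate input: estimate is nowhere above the positivity floor",
         call. = FALSE)
  values <- matrix(NA_real_, nrow(observed), ncol(observed))
  values[mask] <- (observed[mask] - estimate[mask]) / sqrt(estimate[mask])
  structure(list(values = values, mask = mask), class = "noise_field")
}

#' @export
print.noise_field <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<noise_field> %d x %d, %d valid pixels, sd %.4g\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              stats::sd(v)))
  invisible(x)
}
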