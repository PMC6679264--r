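# Restoration quality metrics and the blind stopping statistics.

#' Peak signal-to-noise ratio (dynamic-range form)
#'
#' `PSNR = 10 log10( M N (max(ref) - min(ref))^2 / ||img - ref||^2 )` in dB:
#' the peak is the reference image's dynamic range, not a fixed 255, so the
#' metric is invariant to a common rescaling of both images.
#'
#' @param img restored image.
#' @param reference ground-truth image of the same dimensions.
#' @return PSNR in dB; `Inf` for identical images.
#' @export
psnr <- function(img, reference) {
  check_same_dim(img, reference)
  rng <- max(reference) - min(reference)
  if (rng <= 0) stop("reference has zero dynamic range", call. = FALSE)
  sse <- sum((img - reference)^2)
  if (sse == 0) return(Inf)
  10 * log10(length(reference) * rng^2 / sse)
}

#' Mean absolute error
#'
#' @inheritParams psnr
#' @return mean of |img - reference| in intensity units.
#' @export
mae <- function(img, reference) {
  check_same_dim(img, reference)
  mean(abs(img - reference))
}

#' Structural similarity index (single scale)
#'
#' Standard single-scale SSIM with an 11x11 Gaussian window (sd 1.5),
#' constants K1 = 0.01 and K2 = 0.03, sample-covariance normalization, and
#' dynamic range taken from the reference image by default. The SSIM map is
#' computed with mirror-padded filtering, the window-radius border is
#' cropped, and the mean of the remaining map is returned.
#'
#' @inheritParams psnr
#' @param data_range dynamic range L of the comparison; defaults to
#'   `max(reference) - min(reference)`.
#' @return mean SSIM in \[-1, 1\].
#' @export
ssim <- function(img, reference, data_range = NULL) {
  check_same_dim(img, reference)
  if (is.null(data_range)) data_range <- max(reference) - min(reference)
  if (data_range <= 0) stop("dynamic range must be positive", call. = FALSE)
  sigma_w <- 1.5
  r <- 5L                                 # 11x11 window
  if (min(dim(img)) < 2L * r + 1L)
    stop("images smaller than the 11x11 SSIM window", call. = FALSE)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_w^2))
  k <- k / sum(k)
  filt <- function(m) {
    m <- convolve_rows(m, k, r)
    t(convolve_rows(t(m), k, r))
  }
  np <- (2 * r + 1)^2
  cov_norm <- np / (np - 1)
  ux <- filt(img); uy <- filt(reference)
  vx <- cov_norm * (filt(img * img) - ux^2)
  vy <- cov_norm * (filt(reference * reference) - uy^2)
  vxy <- cov_norm * (filt(img * reference) - ux * uy)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  core <- S[(r + 1L):(nrow(S) - r), (r + 1L):(ncol(S) - r)]
  mean(core)
}

#' Excess kurtosis (population estimator)
#'
#' `k = sum((x - mu)^4) / (n sd^4) - 3` with the population (biased)
#' variance, exactly the fourth-standardized-moment form with no small-
#' sample correction. Zero for a Gaussian sample as n grows; the sampling
#' standard error is about `sqrt(24/n)`.
#'
#' @param x numeric sample (n >= 4, non-constant). `NA`s are dropped.
#' @return excess kurtosis.
#' @export
kurtosis_excess <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 <= 0) stop("degenerate input: zero variance", call. = FALSE)
  mean((x - mu)^4) / s2^2 - 3
}

#' Evaluate the blind stopping criteria
#'
#' Extracts the noise residual `n = (observed - iterate) / sqrt(iterate)`
#' (masked where the iterate is near zero) and computes its excess kurtosis
#' and its Pearson correlation with the iterate. The kurtosis policy fires
#' when |kurtosis| < `kurtosis_tol` (a Gaussian residual has zero excess
#' kurtosis); the correlation policy fires when |correlation| <
#' `correlation_tol` (the model's noise is independent of the image).
#'
#' @param observed the noisy image.
#' @param iterate the current estimate of the clean image.
#' @param policy a [stopping_policy()] of kind `"kurtosis"` or
#'   `"correlation"`.
#' @return list with `fire` (logical) and `stats` (list with `kurtosis`,
#'   `correlation`, `n_valid`).
#' @export
blind_stop <- function(observed, iterate, policy) {
  nf <- extract_noise(observed, iterate)
  v <- nf$values[nf$mask]
  k <- kurtosis_excess(v)
  iv <- iterate[nf$mask]
  r <- if (stats::var(iv) > 0) stats::cor(iv, v) else NA_real_
  fire <- switch(policy$kind,
    kurtosis = abs(k) < policy$kurtosis_tol,
    correlation = !is.na(r) && abs(r) < policy$correlation_tol,
    stop("blind_stop needs a kurtosis or correlation policy", call. = FALSE))
  list(fire = fire, stats = list(kurtosis = k, correlation = r,
                                 n_valid = sum(nf$mask)))
}

#' Quality report for a restored image
#'
#' @inheritParams psnr
#' @return data frame with one row: `psnr`, `mae`, `ssim`.
#' @export
quality_report <- function(img, reference) {
  data.frame(psnr = psnr(img, reference), mae = mae(img, reference),
             ssim = ssim(img, reference))
}
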