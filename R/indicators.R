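# Scalar coefficient fields that steer the diffusion.

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L)
    stop("`beta` must be a single number", call. = FALSE)
  if (beta < 0 || beta > 1)
    warning("`beta` outside [0, 1]; the degeneracy-speed exponent is ",
            "normally in (0, 1)", call. = FALSE)
  beta
}

#' Gray-level / noise-standard-deviation indicator b(I)
#'
#' The per-pixel noise standard deviation of the compressed speckle model is
#' `s(x) = sqrt(I(x)) * sigma`. The indicator
#' `b = 2 s^alpha / (M^alpha + s^alpha)`, with `M = max(s)` over the image,
#' rises from 0 in dark (low-noise) regions to 1 where the noise standard
#' deviation peaks, throttling diffusion where there is little noise to
#' remove. Because sigma enters both `s` and `M`, `b` is invariant to
#' rescaling sigma for any sigma > 0; for sigma = 0 the indicator is
#' identically zero and the diffusion degenerates to the constant operator.
#'
#' @param img non-negative numeric matrix.
#' @param alpha positive exponent (gamma-correction style: smaller values
#'   expand the low end of the indicator's response).
#' @param sigma noise standard deviation (>= 0).
#' @param M optional override of the normalization `max(sqrt(img) * sigma)`.
#' @return matrix of indicator values in \[0, 1\].
#' @export
gray_level_indicator <- function(img, alpha, sigma, M = NULL) {
  check_image(img, require_nonneg = TRUE)
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(matrix(0, nrow(img), ncol(img)))
  s <- sqrt(img) * sigma
  if (is.null(M)) M <- max(s)
  if (M <= 0) return(matrix(0, nrow(img), ncol(img)))
  sa <- s^alpha
  2 * sa / (M^alpha + sa)
}

#' Gray-level indicator d(I) of the doubly degenerate diffusion baseline
#'
#' `d = 2 I^alpha / (M^alpha + I^alpha)` with `M = max(I)`: the same sigmoid
#' gain as [gray_level_indicator()] but driven by the gray level itself, so
#' it does not react to the noise standard deviation.
#'
#' @inheritParams gray_level_indicator
#' @return matrix of indicator values in \[0, 1\]; an all-zero image yields
#'   the zero field.
#' @export
ddnd_indicator <- function(img, alpha) {
  check_image(img, require_nonneg = TRUE)
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  M <- max(img)
  if (M <= 0) return(matrix(0, nrow(img), ncol(img)))
  ia <- img^alpha
  2 * ia / (M^alpha + ia)
}

#' Gradient-driven conduction coefficient c1
#'
#' `c1(s) = (1 + s)^(-(1-beta)/2)` evaluated on the squared gradient
#' magnitude `s = |grad I|^2`. It equals 1 on flat regions and decays toward
#' 0 as the gradient grows, so diffusion stops across strong edges; `beta`
#' controls the speed of that degeneracy (beta = 1 gives the constant 1).
#'
#' @param grad_sq non-negative numeric vector/matrix of squared gradient
#'   magnitudes.
#' @param beta degeneracy-speed exponent, normally in (0, 1).
#' @return values in (0, 1\], same shape as `grad_sq`.
#' @export
pm_coefficient <- function(grad_sq, beta) {
  check_beta(beta)
  if (any(grad_sq < 0)) stop("`grad_sq` must be >= 0", call. = FALSE)
  (1 + grad_sq)^(-(1 - beta) / 2)
}

#' Normal-direction conduction coefficient c2
#'
#' The divergence-form operator `div(c1(|grad I|^2) grad I)` decomposes into
#' a weighted sum of the tangential and normal second derivatives,
#' `c1 I_TT + c2 I_NN`, with `c2(s) = c1(s) + 2 s c1'(s)`:
#' `c2(s) = (1+s)^(-(1-beta)/2) - (1-beta) s (1+s)^(-(1-beta)/2 - 1)`.
#' At `s = 0` the two coefficients coincide (isotropic diffusion); for large
#' gradients `c2` falls below `c1`, i.e. diffusion across the edge is slower
#' than along it.
#'
#' @inheritParams pm_coefficient
#' @return values of `c2`, same shape as `grad_sq`.
#' @export
normal_coefficient <- function(grad_sq, beta) {
  check_beta(beta)
  if (any(grad_sq < 0)) stop("`grad_sq` must be >= 0", call. = FALSE)
  e <- (1 - beta) / 2
  (1 + grad_sq)^(-e) - (1 - beta) * grad_sq * (1 + grad_sq)^(-e - 1)
}

#' Binary edge gate for tangential-only diffusion
#'
#' Produces the gate field theta with theta = 0 at detected edges and
#' theta = 1 elsewhere. The default detector smooths the image with a
#' Gaussian of standard deviation `smooth_sigma`, takes the central-
#' difference gradient magnitude, and marks as edges all pixels whose
#' magnitude exceeds its `quantile`-th sample quantile. Alternatively a
#' user-supplied logical/0-1 `mask` of edge pixels can be given.
#'
#' @param img numeric matrix.
#' @param quantile edge quantile in \[0, 1\]; `quantile = 0` marks everything
#'   above the minimum as edge.
#' @param smooth_sigma presmoothing scale in pixels.
#' @param mask optional explicit edge mask (TRUE/1 = edge) overriding the
#'   gradient detector.
#' @return matrix with values in \{0, 1\} (class `edge_gate` attribute-free).
#' @export
edge_gate <- function(img, quantile = 0.9, smooth_sigma = 1, mask = NULL) {
  check_image(img)
  if (!is.null(mask)) {
    check_same_dim(img, mask)
    return(1 - (matrix(as.numeric(mask), nrow(img), ncol(img)) > 0))
  }
  if (quantile < 0 || quantile > 1)
    stop("`quantile` must be in [0, 1]", call. = FALSE)
  s <- gaussian_smooth(img, smooth_sigma)
  g <- central_gradient_sq(s)
  thr <- stats::quantile(g, probs = quantile, names = FALSE)
  matrix(as.numeric(g <= thr), nrow(img), ncol(img))
}

# squared central-difference gradient magnitude, edge-replicated
central_gradient_sq <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  ((dn - up) / 2)^2 + ((rt - lf) / 2)^2
}
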