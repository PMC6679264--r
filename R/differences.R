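# Finite-difference stencils on the pixel grid (space step h = 1).
# The first matrix index is the row and plays the role of "x" in the
# stencils; boundary handling replicates the edge row/column, which is the
# discrete zero-flux (Neumann) condition.

#' One-sided forward differences
#'
#' `Ux(i,j) = I(i+1,j) - I(i,j)` and `Uy(i,j) = I(i,j+1) - I(i,j)` with the
#' ghost row/column replicated, so the difference is zero on the last
#' row/column (zero-flux boundary).
#'
#' @param img numeric matrix.
#' @return list with matrices `ux`, `uy`.
#' @export
forward_differences <- function(img) {
  check_image(img)
  nr <- nrow(img); nc <- ncol(img)
  ux <- rbind(img[-1L, , drop = FALSE] - img[-nr, , drop = FALSE],
              rep(0, nc))
  uy <- cbind(img[, -1L, drop = FALSE] - img[, -nc, drop = FALSE],
              rep(0, nr))
  list(ux = ux, uy = uy)
}

#' Central second differences and the forward cross difference
#'
#' `Uxx(i,j) = I(i+1,j) + I(i-1,j) - 2 I(i,j)`, similarly `Uyy`, and the
#' cross term `Uxy(i,j) = I(i+1,j+1) + I(i,j) - I(i+1,j) - I(i,j+1)`
#' (exact for bilinear fields). Edge rows/columns are replicated.
#'
#' @param img numeric matrix.
#' @return list with matrices `uxx`, `uyy`, `uxy`.
#' @export
second_differences <- function(img) {
  check_image(img)
  nr <- nrow(img); nc <- ncol(img)
  up <- img[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- img[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  lf <- img[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- img[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  dnrt <- dn[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  list(uxx = dn + up - 2 * img,
       uyy = rt + lf - 2 * img,
       uxy = dnrt + img - dn - rt)
}

#' Second derivatives along the gradient (normal) and level line (tangent)
#'
#' With the squared gradient `D = Ux^2 + Uy^2`:
#' `UNN = (Ux^2 Uxx + Uy^2 Uyy + 2 Ux Uy Uxy) / D` and
#' `UTT = (Ux^2 Uyy + Uy^2 Uxx - 2 Ux Uy Uxy) / D`, so `UNN + UTT` equals
#' the discrete Laplacian `Uxx + Uyy`. The gradient direction is estimated
#' with central differences: a one-sided estimate sees no gradient on the
#' uphill side of a step (the jump lies behind it), which would misclassify
#' edge pixels as flat and diffuse across the edge. Where `D < eps_grad`
#' the direction is undefined and the isotropic limit
#' `UNN = UTT = (Uxx + Uyy)/2` is used.
#'
#' @param img numeric matrix.
#' @param eps_grad threshold below which the squared gradient is treated as
#'   zero.
#' @return list with matrices `unn`, `utt`, and `d` (the squared gradient).
#' @export
directional_curvatures <- function(img, eps_grad = 1e-12) {
  nr <- nrow(img); nc <- ncol(img)
  up <- img[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- img[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  lf <- img[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- img[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  fd <- list(ux = (dn - up) / 2, uy = (rt - lf) / 2)
  sd2 <- second_differences(img)
  D <- fd$ux^2 + fd$uy^2
  flat <- D < eps_grad
  Dsafe <- ifelse(flat, 1, D)
  unn <- (fd$ux^2 * sd2$uxx + fd$uy^2 * sd2$uyy +
            2 * fd$ux * fd$uy * sd2$uxy) / Dsafe
  utt <- (fd$ux^2 * sd2$uyy + fd$uy^2 * sd2$uxx -
            2 * fd$ux * fd$uy * sd2$uxy) / Dsafe
  iso <- 0.5 * (sd2$uxx + sd2$uyy)
  unn[flat] <- iso[flat]
  utt[flat] <- iso[flat]
  list(unn = unn, utt = utt, d = D)
}
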