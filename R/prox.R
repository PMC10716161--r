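#' Singular-value thresholding (proximal operator of the nuclear norm)
#'
#' `U max(S - tau, 0) V^H` for the SVD `M = U S V^H`: the unique
#' minimizer of `0.5 ||Z - M||_F^2 + tau ||Z||_*`. Used on the Casorati
#' reshaping (pixels x frames) of the low-rank component.
#'
#' @param M Complex (or numeric) matrix.
#' @param tau Threshold, >= 0.
#' @return Matrix of the same shape.
#' @export
nuclear_prox <- function(M, tau) {
  stopifnot(tau >= 0)
  if (tau == 0) return(M)
  sv <- svd(M)
  s <- pmax(sv$d - tau, 0)
  keep <- s > 0
  if (!any(keep)) return(matrix(0i, nrow(M), ncol(M)))
  sv$u[, keep, drop = FALSE] %*% (s[keep] * Conj(t(sv$v[, keep, drop = FALSE])))
}

#' Complex soft thresholding (proximal operator of the l1 norm)
#'
#' Elementwise `z * max(|z| - tau, 0) / |z|` (0 where `z = 0`): shrinks
#' the magnitude, preserves the phase.
#'
#' @param z Complex (or numeric) array.
#' @param tau Threshold, >= 0.
#' @return Array of the same shape.
#' @export
soft_threshold <- function(z, tau) {
  stopifnot(tau >= 0)
  if (tau == 0) return(z)
  a <- abs(z)
  scl <- ifelse(a > tau, 1 - tau / a, 0)
  z * scl
}

#' Forward temporal differences (temporal total variation)
#'
#' First differences along the frame axis with zero boundary:
#' `(Dt x)[t] = x[t+1] - x[t]` for `t = 1..nt-1`. A single frame yields
#' an empty difference array.
#'
#' @param x Complex array (N x N x nt) or [image_group()].
#' @return Complex array (N x N x (nt-1)).
#' @export
temporal_diff <- function(x) {
  f <- if (inherits(x, "image_group")) x$frames else x
  nt <- dim(f)[3]
  if (nt == 1) return(array(0i, dim = c(dim(f)[1], dim(f)[2], 0)))
  f[, , 2:nt, drop = FALSE] - f[, , 1:(nt - 1), drop = FALSE]
}

#' Adjoint of [temporal_diff()] (negative temporal divergence)
#'
#' @param u Complex array (N x N x (nt-1)).
#' @param nt Number of frames of the primal domain.
#' @return Complex array (N x N x nt).
#' @export
temporal_diff_adjoint <- function(u, nt) {
  out <- array(0i, dim = c(dim(u)[1], dim(u)[2], nt))
  if (nt == 1 || dim(u)[3] == 0) return(out)
  out[, , 1] <- -u[, , 1]
  if (nt > 2) {
    out[, , 2:(nt - 1)] <- u[, , 1:(nt - 2), drop = FALSE] - u[, , 2:(nt - 1), drop = FALSE]
  }
  out[, , nt] <- u[, , nt - 1]
  out
}

## Undecimated single-level Haar framelet (spatial, per frame).
## 1D filters h = (1/2, 1/2), g = (1/2, -1/2) with periodic boundary:
## |h^(w)|^2 + |g^(w)|^2 = 1, so the four separable 2D subbands form a
## normalized (Parseval) tight frame - synthesis is the plain adjoint and
## synthesis(analysis(x)) = x exactly.

.circ_prev <- function(x, d) {
  # x shifted so y[n] = x[n-1] (periodic) along dim d of a 3D array
  n <- dim(x)[d]
  idx <- c(n, seq_len(n - 1))
  if (d == 1) x[idx, , , drop = FALSE] else x[, idx, , drop = FALSE]
}

.circ_next <- function(x, d) {
  n <- dim(x)[d]
  idx <- c(seq_len(n - 1) + 1, 1)
  if (d == 1) x[idx, , , drop = FALSE] else x[, idx, , drop = FALSE]
}

#' Framelet analysis (undecimated Haar, one level)
#'
#' @param x Complex array (N x N x nt) or [image_group()].
#' @return Complex array (N x N x nt x 4): subbands LL, HL, LH, HH.
#' @export
framelet_analysis <- function(x) {
  f <- if (inherits(x, "image_group")) x$frames else x
  if (length(dim(f)) == 2) dim(f) <- c(dim(f), 1)
  l1 <- (f + .circ_prev(f, 1)) / 2
  h1 <- (f - .circ_prev(f, 1)) / 2
  out <- array(0i, dim = c(dim(f), 4))
  out[, , , 1] <- (l1 + .circ_prev(l1, 2)) / 2
  out[, , , 2] <- (h1 + .circ_prev(h1, 2)) / 2
  out[, , , 3] <- (l1 - .circ_prev(l1, 2)) / 2
  out[, , , 4] <- (h1 - .circ_prev(h1, 2)) / 2
  out
}

#' Framelet synthesis (adjoint of [framelet_analysis()])
#'
#' For this Parseval frame the adjoint inverts analysis exactly.
#'
#' @param coef Complex array (N x N x nt x 4).
#' @return Complex array (N x N x nt).
#' @export
framelet_synthesis <- function(coef) {
  stopifnot(length(dim(coef)) == 4, dim(coef)[4] == 4)
  d3 <- dim(coef)[1:3]
  sub <- function(k) { s <- coef[, , , k]; dim(s) <- d3; s }
  # adjoint of column filtering
  a1 <- (sub(1) + .circ_next(sub(1), 2)) / 2
  a2 <- (sub(2) + .circ_next(sub(2), 2)) / 2
  a3 <- (sub(3) - .circ_next(sub(3), 2)) / 2
  a4 <- (sub(4) - .circ_next(sub(4), 2)) / 2
  l1 <- a1 + a3
  h1 <- a2 + a4
  (l1 + .circ_next(l1, 1)) / 2 + (h1 - .circ_next(h1, 1)) / 2
}
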