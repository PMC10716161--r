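## Non-uniform Fourier transform by Kaiser-Bessel gridding.
##
## Convention: for an N x N image x with centered indices
## n = -N/2 .. N/2-1 and a sample at k (cycles/pixel),
##   (F x)(k) = (1/N) * sum_n x[n] exp(-2i*pi*k.n)
## i.e. the unitary-DFT scaling, DC at the matrix center. The fast path
## uses a 2x oversampled grid, a width-6 Kaiser-Bessel interpolation
## kernel and analytic deapodization; the adjoint is the exact conjugate
## transpose of the implemented forward map, so dot-product tests hold to
## machine precision regardless of the gridding approximation error.

.kb_beta <- function(width = 6, osf = 2) {
  # Beatty et al. choice for oversampling factor osf
  pi * sqrt((width / osf)^2 * (osf - 0.5)^2 - 0.8)
}

.kb_kernel <- function(t, width, beta) {
  # I0 Kaiser-Bessel, support |t| <= width/2 (t in oversampled-grid units)
  u <- 1 - (2 * t / width)^2
  out <- numeric(length(t))
  ok <- u > 0
  out[ok] <- besselI(beta * sqrt(u[ok]), 0)
  out
}

.kb_ft <- function(f, width, beta) {
  # continuous Fourier transform of the kernel at f cycles/grid-sample
  z2 <- beta^2 - (pi * width * f)^2
  ifelse(z2 > 0,
         width * sinh(sqrt(pmax(z2, 0))) / sqrt(pmax(z2, 1e-300)),
         width * sin(sqrt(pmax(-z2, 0))) / sqrt(pmax(-z2, 1e-300)))
}

.fftshift2 <- function(x) {
  d <- dim(x)
  i1 <- c((d[1] %/% 2 + 1):d[1], 1:(d[1] %/% 2))
  i2 <- c((d[2] %/% 2 + 1):d[2], 1:(d[2] %/% 2))
  x[i1, i2, drop = FALSE]
}

.ifftshift2 <- function(x) {
  d <- dim(x)
  i1 <- c((d[1] - d[1] %/% 2 + 1):d[1], 1:(d[1] - d[1] %/% 2))
  i2 <- c((d[2] - d[2] %/% 2 + 1):d[2], 1:(d[2] - d[2] %/% 2))
  x[i1, i2, drop = FALSE]
}

#' Plan a gridding non-uniform Fourier transform
#'
#' Precomputes the sparse interpolation matrix and deapodization weights
#' for repeated forward/adjoint evaluations on a fixed set of k-space
#' coordinates.
#'
#' @param kcoords Numeric matrix (n_samples x 2) of k-space coordinates in
#'   cycles/pixel, each in `[-0.5, 0.5)`, or the `kcoords` array of a
#'   `radial_trajectory` (flattened spoke-major).
#' @param matrix_size Image matrix size N.
#' @param osf Grid oversampling factor (default 2).
#' @param width Interpolation kernel width in oversampled grid units
#'   (default 6).
#' @return A `nufft_plan` object.
#' @export
nufft_plan <- function(kcoords, matrix_size, osf = 2, width = 6) {
  if (length(dim(kcoords)) == 3) {
    # kcoords array is (spokes x readout x 2); flatten spoke-major,
    # readout fastest, matching the k-space data layout
    kc <- cbind(as.vector(t(kcoords[, , 1])), as.vector(t(kcoords[, , 2])))
  } else {
    kc <- as.matrix(kcoords)
  }
  stopifnot(ncol(kc) == 2, max(abs(kc)) <= 0.5 + 1e-12)
  N <- as.integer(matrix_size)
  G <- as.integer(round(osf * N))
  beta <- .kb_beta(width, osf)
  ns <- nrow(kc)
  half <- width / 2
  noff <- as.integer(ceiling(half - 0.5) * 2 + 1) # kernel taps per dim
  offs <- seq_len(noff) - (noff + 1L) / 2L        # symmetric integer offsets

  # continuous grid positions (grid spacing 1/G cycles/pixel, DC at index 0)
  gx <- kc[, 1] * G
  gy <- kc[, 2] * G
  cx <- round(gx); cy <- round(gy)

  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  # accumulate taps offset-pair by offset-pair (vectorized over samples)
  idx1 <- function(c0) ((c0 %% G) + G) %% G  # wrap to 0..G-1 (DC at 0)
  wlist_x <- lapply(offs, function(o) .kb_kernel(gx - (cx + o), width, beta))
  wlist_y <- lapply(offs, function(o) .kb_kernel(gy - (cy + o), width, beta))
  ixl <- lapply(offs, function(o) idx1(cx + o))
  iyl <- lapply(offs, function(o) idx1(cy + o))
  samp <- seq_len(ns)
  for (a in seq_along(offs)) {
    wx <- wlist_x[[a]]
    for (b in seq_along(offs)) {
      w <- wx * wlist_y[[b]]
      keep <- w > 0
      if (!any(keep)) next
      rows <- c(rows, samp[keep])
      cols <- c(cols, ixl[[a]][keep] + G * iyl[[b]][keep] + 1L)
      vals <- c(vals, w[keep])
    }
  }
  P <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(ns, G * G))

  # deapodization over the centered N x N image, folding in the global scale
  n1 <- (seq_len(N) - 1 - N %/% 2)
  c1 <- .kb_ft(n1 / G, width, beta)
  deapod <- (G / N) / outer(c1, c1)   # multiply image by G/(N*c1*c1)
  structure(list(P = P, N = N, G = G, deapod = deapod,
                 ns = ns, width = width, osf = osf, beta = beta),
            class = "nufft_plan")
}

# sparse-real times dense-complex helper
.spmv_cplx <- function(P, v) {
  as.vector(P %*% Re(v)) + 1i * as.vector(P %*% Im(v))
}
.spmv_cplx_t <- function(P, v) {
  as.vector(Matrix::crossprod(P, Re(v))) + 1i * as.vector(Matrix::crossprod(P, Im(v)))
}

#' Forward gridding NUFFT: image to non-uniform k-space samples
#'
#' @param plan A [nufft_plan()].
#' @param img Complex (or numeric) N x N image.
#' @return Complex vector of `plan$ns` samples.
#' @export
nufft_forward <- function(plan, img) {
  N <- plan$N; G <- plan$G
  stopifnot(all(dim(img) == N))
  v <- img * plan$deapod
  pad <- matrix(0i, G, G)
  i0 <- (G - N) %/% 2
  pad[(i0 + 1):(i0 + N), (i0 + 1):(i0 + N)] <- v
  K <- stats::fft(.ifftshift2(pad)) / G     # DC at index [1,1]
  .spmv_cplx(plan$P, as.vector(K))
}

#' Adjoint gridding NUFFT: non-uniform samples to image
#'
#' Exact adjoint (conjugate transpose) of [nufft_forward()]. With
#' `density_compensated = TRUE` a radial ramp weight is applied to the
#' samples first; that variant is a display/initialization aid and is not
#' the adjoint of the forward map.
#'
#' @param plan A [nufft_plan()].
#' @param y Complex sample vector (length `plan$ns`).
#' @param weights Optional per-sample real weights (e.g. a Ram-Lak ramp).
#' @return Complex N x N image.
#' @export
nufft_adjoint <- function(plan, y, weights = NULL) {
  N <- plan$N; G <- plan$G
  stopifnot(length(y) == plan$ns)
  if (!is.null(weights)) y <- y * weights
  Kv <- .spmv_cplx_t(plan$P, y)
  K <- matrix(Kv, G, G)
  pad <- .fftshift2(stats::fft(K, inverse = TRUE)) / G
  i0 <- (G - N) %/% 2
  v <- pad[(i0 + 1):(i0 + N), (i0 + 1):(i0 + N)]
  v * plan$deapod          # deapod is real: self-adjoint
}
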