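#' Simulate smooth coil sensitivity maps
#'
#' Complex Gaussian-profile receive coils centered on a ring around the
#' field of view, with a smooth linear phase per coil, normalized so the
#' pixelwise sum of squared magnitudes is 1 (the SENSE convention for
#' known maps). With a single coil this reduces to a uniform unit map.
#'
#' @param n_coils Number of coils.
#' @param matrix_size Matrix size N.
#' @param fov_frac Radius of the coil ring as a fraction of N (default 0.55).
#' @param sigma_frac Gaussian profile width as a fraction of N (default 0.45).
#' @return Complex array (N x N x n_coils) of class `coil_sensitivities`.
#' @export
simulate_coilmaps <- function(n_coils, matrix_size, fov_frac = 0.55,
                              sigma_frac = 0.45) {
  stopifnot(n_coils >= 1, matrix_size >= 2)
  N <- as.integer(matrix_size)
  if (n_coils == 1) {
    # normalization forces |C| = 1; a single coil is the uniform unit map
    maps <- array(1 + 0i, dim = c(N, N, 1))
    return(structure(maps, class = c("coil_sensitivities", class(maps))))
  }
  n1 <- (seq_len(N) - 1 - N %/% 2)
  X <- matrix(n1, N, N)        # first index
  Y <- matrix(n1, N, N, byrow = TRUE)
  maps <- array(0i, dim = c(N, N, n_coils))
  sig <- sigma_frac * N
  r0 <- fov_frac * N
  for (c in seq_len(n_coils)) {
    th <- 2 * pi * (c - 1) / n_coils
    cx <- r0 * cos(th); cy <- r0 * sin(th)
    mag <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sig^2))
    # smooth per-coil phase ramp toward the coil center
    ph <- 0.5 * pi * (X * cos(th) + Y * sin(th)) / N + th / 3
    maps[, , c] <- mag * exp(1i * ph)
  }
  sos <- sqrt(apply(abs(maps)^2, c(1, 2), sum))
  for (c in seq_len(n_coils)) maps[, , c] <- maps[, , c] / sos
  structure(maps, class = c("coil_sensitivities", class(maps)))
}

#' Image group (one reconstruction unit)
#'
#' @param frames Complex array (N x N x fpg).
#' @param pixel_mm Pixel size in mm.
#' @return Object of class `image_group`.
#' @export
image_group <- function(frames, pixel_mm = 1) {
  if (length(dim(frames)) == 2) dim(frames) <- c(dim(frames), 1)
  stopifnot(length(dim(frames)) == 3, dim(frames)[1] == dim(frames)[2])
  structure(list(frames = frames, pixel_mm = pixel_mm), class = "image_group")
}

#' Multi-coil radial encoding operator E = Omega F C
#'
#' Composition of coil sensitivity weighting (C), the non-uniform Fourier
#' transform (F) and radial sampling (Omega) for one group: spoke i
#' (0-based) belongs to frame `floor(i / spf)`, and frames are encoded
#' independently. One gridding plan per frame is precomputed.
#'
#' @param sens Coil maps from [simulate_coilmaps()] (N x N x n_coils).
#' @param trajectory A `radial_trajectory` from [make_trajectory()].
#' @return Object of class `encoding_operator`.
#' @export
encoding_operator <- function(sens, trajectory) {
  stopifnot(inherits(trajectory, "radial_trajectory"))
  N <- dim(sens)[1]
  sch <- trajectory$scheme
  nr <- trajectory$config$readout_points
  plans <- vector("list", sch$fpg)
  for (t in seq_len(sch$fpg)) {
    sp <- ((t - 1) * sch$spf + 1):(t * sch$spf)
    plans[[t]] <- nufft_plan(trajectory$kcoords[sp, , , drop = FALSE], N)
  }
  structure(list(sens = sens, trajectory = trajectory, scheme = sch,
                 plans = plans, N = N, n_coils = dim(sens)[3],
                 readout = nr, cache = new.env(parent = emptyenv())),
            class = "encoding_operator")
}

#' Forward encoding: image group to multi-coil radial k-space
#'
#' @param op An [encoding_operator()].
#' @param x An [image_group()] (fpg frames) or bare complex array.
#' @return A `kspace_group` (see [kspace_group()]).
#' @export
enc_forward <- function(op, x) {
  frames <- if (inherits(x, "image_group")) x$frames else x
  if (length(dim(frames)) == 2) dim(frames) <- c(dim(frames), 1)
  sch <- op$scheme
  stopifnot(dim(frames)[3] == sch$fpg, dim(frames)[1] == op$N)
  nr <- op$readout
  data <- array(0i, dim = c(op$n_coils, sch$spokes_per_group, nr))
  for (t in seq_len(sch$fpg)) {
    sp <- ((t - 1) * sch$spf + 1):(t * sch$spf)
    for (c in seq_len(op$n_coils)) {
      y <- nufft_forward(op$plans[[t]], op$sens[, , c] * frames[, , t])
      data[c, sp, ] <- matrix(y, sch$spf, nr, byrow = TRUE)
    }
  }
  kspace_group(data, op$trajectory)
}

#' Adjoint encoding: multi-coil radial k-space to image group
#'
#' The exact adjoint E^H of [enc_forward()] (conjugate coil maps, adjoint
#' NUFFT, sum over coils). With `density_compensated = TRUE` a radial
#' ramp (Ram-Lak) weight is applied to the samples first; that variant is
#' used for initialization and zero-filled display only, never inside an
#' objective gradient.
#'
#' @param op An [encoding_operator()].
#' @param d A `kspace_group` or bare complex array (coils x spokes x readout).
#' @param density_compensated Logical (default `FALSE`).
#' @return An [image_group()].
#' @export
enc_adjoint <- function(op, d, density_compensated = FALSE) {
  data <- if (inherits(d, "kspace_group")) d$data else d
  sch <- op$scheme
  stopifnot(dim(data)[1] == op$n_coils, dim(data)[2] == sch$spokes_per_group)
  nr <- op$readout
  kr <- abs((seq_len(nr) - 1 - nr %/% 2) / nr)     # |k| per readout point
  kr[kr == 0] <- 1 / (4 * nr)                      # effective radius of the DC cell
  frames <- array(0i, dim = c(op$N, op$N, sch$fpg))
  for (t in seq_len(sch$fpg)) {
    sp <- ((t - 1) * sch$spf + 1):(t * sch$spf)
    w <- NULL
    if (density_compensated) {
      # golden-angle spokes are not angularly equispaced: weight each
      # spoke by its angular Voronoi gap (diameters: angles modulo 180)
      dth <- .angular_gaps_rad(op$trajectory$angles_deg[sp])
      w <- as.vector(t(outer(dth, kr))) * (op$N^2 / nr)
    }
    acc <- matrix(0i, op$N, op$N)
    for (c in seq_len(op$n_coils)) {
      y <- as.vector(t(matrix(data[c, sp, ], sch$spf, nr)))
      acc <- acc + Conj(op$sens[, , c]) * nufft_adjoint(op$plans[[t]], y, weights = w)
    }
    frames[, , t] <- acc
  }
  image_group(frames)
}

# per-spoke angular Voronoi gaps in radians; spokes are full diameters,
# so orientation lives on [0, 180) and the gaps of the sorted unique
# orientations sum to pi
.angular_gaps_rad <- function(angles_deg) {
  th <- (angles_deg %% 180) * pi / 180
  n <- length(th)
  if (n == 1) return(pi)
  o <- order(th)
  ts <- th[o]
  gaps <- diff(c(ts, ts[1] + pi))          # circular gaps on [0, pi)
  half <- (gaps + c(gaps[n], gaps[-n])) / 2
  out <- numeric(n)
  out[o] <- half
  out
}

#' k-space group container
#'
#' @param data Complex array (coils x spokes_per_group x readout_points).
#' @param trajectory The `radial_trajectory` the data were sampled on.
#' @param timing Optional [acquisition_timing()].
#' @param noise_sd Standard deviation of the complex noise added per
#'   sample (0 for noiseless simulation).
#' @return Object of class `kspace_group`.
#' @export
kspace_group <- function(data, trajectory, timing = NULL, noise_sd = 0) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[2] == trajectory$scheme$spokes_per_group,
            dim(data)[3] == trajectory$config$readout_points,
            all(is.finite(Re(data))), all(is.finite(Im(data))))
  structure(list(data = data, trajectory = trajectory,
                 scheme = trajectory$scheme, timing = timing,
                 noise_sd = noise_sd),
            class = "kspace_group")
}

#' Detangle a stack-of-stars acquisition into per-slice 2D k-space
#'
#' Applies a centered, orthonormal inverse FFT along the partition
#' (z) axis, decoupling the Cartesian through-plane encoding so each
#' slice can be reconstructed independently in 2D. Energy is preserved.
#'
#' @param kdata_3d Complex array (coils x spokes x readout x partitions).
#' @param trajectory Optional `radial_trajectory` used to wrap each slice
#'   into a `kspace_group`; if `NULL`, bare arrays are returned.
#' @return List of per-slice arrays or `kspace_group`s, ordered by slice.
#' @export
detangle_stack_of_stars <- function(kdata_3d, trajectory = NULL) {
  stopifnot(length(dim(kdata_3d)) == 4)
  np <- dim(kdata_3d)[4]
  out <- vector("list", np)
  if (np == 1) {
    sl <- kdata_3d[, , , 1]
    out[[1]] <- if (is.null(trajectory)) sl else kspace_group(sl, trajectory)
    return(out)
  }
  d <- dim(kdata_3d)
  m <- matrix(aperm(kdata_3d, c(4, 1, 2, 3)), nrow = np)
  # centered orthonormal inverse FFT along z
  shift <- c((np - np %/% 2 + 1):np, 1:(np - np %/% 2))
  m <- m[shift, , drop = FALSE]
  m <- stats::mvfft(m, inverse = TRUE) / sqrt(np)
  shift2 <- c((np %/% 2 + 1):np, 1:(np %/% 2))
  m <- m[shift2, , drop = FALSE]
  arr <- aperm(array(m, dim = c(np, d[1], d[2], d[3])), c(2, 3, 4, 1))
  for (s in seq_len(np)) {
    sl <- arr[, , , s]
    if (length(dim(sl)) < 3) dim(sl) <- d[1:3]
    out[[s]] <- if (is.null(trajectory)) sl else kspace_group(sl, trajectory)
  }
  out
}

#' Power-iteration estimate of the squared operator norm of E
#'
#' @param op An [encoding_operator()].
#' @param n_iter Iterations (default 30).
#' @param seed RNG seed for the random start.
#' @return Estimate of `||E||^2` (largest eigenvalue of E^H E).
#' @export
enc_norm_sq <- function(op, n_iter = 30, seed = 1) {
  key <- paste0("norm_sq_", n_iter, "_", seed)
  if (!is.null(op$cache) && !is.null(op$cache[[key]])) return(op$cache[[key]])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  N <- op$N; fpg <- op$scheme$fpg
  x <- array(complex(real = stats::rnorm(N * N * fpg),
                     imaginary = stats::rnorm(N * N * fpg)), dim = c(N, N, fpg))
  lam <- 1
  for (i in seq_len(n_iter)) {
    y <- enc_adjoint(op, enc_forward(op, x))$frames
    lam <- sqrt(sum(abs(y)^2)) / sqrt(sum(abs(x)^2))
    x <- y / sqrt(sum(abs(y)^2))
  }
  if (!is.null(op$cache)) op$cache[[key]] <- lam
  lam
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
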