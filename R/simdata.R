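#' Phantom specification for the synthetic intervention generator
#'
#' Stand-in for the volunteer brain scans behind the simulated
#' intervention study: a nested-ellipse head phantom with smooth random
#' texture, multi-coil radial acquisition, optional complex noise.
#'
#' @param matrix_size Matrix size N (>= 16).
#' @param pixel_mm Pixel size in mm (default 1).
#' @param background `"ellipse-brain"` (default) or `"user-image"`.
#' @param user_image Magnitude array (N x N) when `background = "user-image"`.
#' @param texture_sd Amplitude of the smooth texture (default 0.05).
#' @param n_coils Number of simulated coils (default 11).
#' @param noise_sd Per-sample complex noise sd in k-space (default 0).
#' @param seed RNG seed for texture and noise.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = 128, pixel_mm = 1,
                         background = c("ellipse-brain", "user-image"),
                         user_image = NULL, texture_sd = 0.05,
                         n_coils = 11, noise_sd = 0, seed = 1) {
  background <- match.arg(background)
  stopifnot(matrix_size >= 16, pixel_mm > 0, texture_sd >= 0,
            n_coils >= 1, noise_sd >= 0)
  if (background == "user-image") stopifnot(!is.null(user_image))
  structure(list(matrix_size = as.integer(matrix_size), pixel_mm = pixel_mm,
                 background = background, user_image = user_image,
                 texture_sd = texture_sd, n_coils = as.integer(n_coils),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

.ellipse_mask <- function(N, cx, cy, rx, ry, angle = 0) {
  n1 <- seq_len(N) - (N + 1) / 2
  X <- matrix(n1, N, N); Y <- matrix(n1, N, N, byrow = TRUE)
  ca <- cos(angle); sa <- sin(angle)
  Xr <- (X - cx) * ca + (Y - cy) * sa
  Yr <- -(X - cx) * sa + (Y - cy) * ca
  (Xr / rx)^2 + (Yr / ry)^2 <= 1
}

.smooth_noise <- function(N, sigma_px, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z <- matrix(stats::rnorm(N * N), N, N)
  f <- stats::fft(z)
  fr <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1)) / N
  H <- exp(-2 * (pi * sigma_px)^2 * outer(fr^2, fr^2, `+`))
  s <- Re(stats::fft(f * H, inverse = TRUE)) / (N * N)
  s / stats::sd(s)
}

#' Static background image for the intervention phantom
#'
#' Deterministic given the spec's seed: an elliptical head phantom (bright
#' skull rim, brain parenchyma split into two hemispheres, ventricle-like
#' hypointense regions) plus smooth random texture, clipped to [0, 1].
#' The ellipse geometry depends only on the matrix size; the texture
#' depends on the seed.
#'
#' @param spec A [phantom_spec()].
#' @return Magnitude matrix (N x N) in [0, 1].
#' @export
make_background <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  N <- spec$matrix_size
  if (spec$background == "user-image") {
    img <- spec$user_image
    stopifnot(all(dim(img) == N))
    return(pmin(pmax(img, 0), 1))
  }
  s <- N / 128
  img <- matrix(0, N, N)
  skull <- .ellipse_mask(N, 0, 0, 60 * s, 48 * s)
  brain <- .ellipse_mask(N, 0, 0, 54 * s, 42 * s)
  img[skull] <- 0.95                      # skull rim
  img[brain] <- 0.55                      # parenchyma
  hemiL <- brain & .ellipse_mask(N, 0, -21 * s, 50 * s, 19 * s)
  hemiR <- brain & .ellipse_mask(N, 0, 21 * s, 50 * s, 19 * s)
  img[hemiL] <- 0.62
  img[hemiR] <- 0.58
  ventL <- .ellipse_mask(N, 6 * s, -9 * s, 16 * s, 5 * s, angle = 0.35)
  ventR <- .ellipse_mask(N, 6 * s, 9 * s, 16 * s, 5 * s, angle = -0.35)
  img[ventL | ventR] <- 0.15              # CSF-dark ventricles
  if (spec$texture_sd > 0) {
    tex <- .smooth_noise(N, sigma_px = 3 * s, seed = spec$seed)
    img[brain] <- img[brain] + spec$texture_sd * tex[brain]
  }
  pmin(pmax(img, 0), 1)
}

.default_geometry <- function(setup, N_mm) {
  s <- N_mm / 128
  switch(setup,
    "unilateral-left"  = list(entry = c(20, 44) * s, target = c(110, 44) * s),
    "unilateral-right" = list(entry = c(20, 84) * s, target = c(110, 84) * s),
    "bilateral-A"      = list(entry = c(20, 44) * s, target = c(110, 44) * s),
    "bilateral-B"      = list(entry = c(18, 40) * s, target = c(104, 52) * s),
    stop("unknown setup: ", setup))
}

#' Interventional scenario
#'
#' Four setups mirror the simulated study design: two unilateral and two
#' bilateral needle insertions. Coordinates are in mm, `(row, col)` from
#' the image corner; bilateral setups add a second needle mirrored
#' across the vertical midline. The needle advances a constant
#' `speed_mm_per_frame` each frame until it reaches the target, so the
#' programmed depth at frame `i` (1-based) is
#' `min(i * speed, |target - entry|)` - exactly linear until arrival.
#'
#' @param setup One of `"unilateral-left"`, `"unilateral-right"`,
#'   `"bilateral-A"`, `"bilateral-B"`.
#' @param entry_point_mm,target_point_mm Optional (row, col) mm
#'   overrides of the setup's default geometry.
#' @param speed_mm_per_frame Advance per frame in mm (default 1.525; at
#'   one frame per second this is the uniform insertion speed of the
#'   phantom experiments).
#' @param needle_width_mm Needle diameter (default 1.5, ceramic needle).
#' @param needle_contrast Multiplicative factor applied to pixels under
#'   the needle, in [0, 2] (default 0.1: signal void).
#' @param n_frames Number of frames (default 200).
#' @param matrix_mm FOV extent in mm used for default geometry (default 128).
#' @param seed Scenario seed.
#' @return Object of class `intervention_scenario`.
#' @export
intervention_scenario <- function(setup = c("unilateral-left", "unilateral-right",
                                            "bilateral-A", "bilateral-B"),
                                  entry_point_mm = NULL, target_point_mm = NULL,
                                  speed_mm_per_frame = 1.525,
                                  needle_width_mm = 1.5, needle_contrast = 0.1,
                                  n_frames = 200, matrix_mm = 128, seed = 1) {
  setup <- match.arg(setup)
  stopifnot(speed_mm_per_frame > 0, needle_width_mm > 0,
            needle_contrast >= 0, needle_contrast <= 2, n_frames >= 1)
  geo <- .default_geometry(setup, matrix_mm)
  entry <- if (is.null(entry_point_mm)) geo$entry else entry_point_mm
  target <- if (is.null(target_point_mm)) geo$target else target_point_mm
  stopifnot(!all(entry == target))
  structure(list(setup = setup, entry_point_mm = entry,
                 target_point_mm = target,
                 speed_mm_per_frame = speed_mm_per_frame,
                 needle_width_mm = needle_width_mm,
                 needle_contrast = needle_contrast,
                 n_frames = as.integer(n_frames),
                 bilateral = grepl("^bilateral", setup),
                 matrix_mm = matrix_mm, seed = as.integer(seed)),
            class = "intervention_scenario")
}

#' Programmed needle depth at given frames
#'
#' @param scenario An [intervention_scenario()].
#' @param frames Integer frame indices (1-based).
#' @return Depths in mm, `min(frame * speed, full insertion length)`.
#' @export
needle_depth_mm <- function(scenario, frames = seq_len(scenario$n_frames)) {
  full <- sqrt(sum((scenario$target_point_mm - scenario$entry_point_mm)^2))
  pmin(frames * scenario$speed_mm_per_frame, full)
}

# mask of pixels within width/2 (perpendicular) of the flat-capped
# segment entry -> entry + depth*dir; a zero-length needle is invisible
.needle_mask <- function(N, pixel_mm, entry, target, depth, width) {
  if (depth <= 0) return(matrix(FALSE, N, N))
  dir <- (target - entry) / sqrt(sum((target - entry)^2))
  px <- (seq_len(N) - 0.5) * pixel_mm
  X <- matrix(px, N, N); Y <- matrix(px, N, N, byrow = TRUE)
  vx <- X - entry[1]; vy <- Y - entry[2]
  t <- vx * dir[1] + vy * dir[2]             # projection along the needle
  d2 <- (vx - t * dir[1])^2 + (vy - t * dir[2])^2
  t >= 0 & t <= depth & d2 <= (width / 2)^2
}

#' Simulate an intervention image sequence
#'
#' Frame `i` is the static background with the needle mask applied:
#' pixels within `needle_width_mm / 2` of the segment from the entry
#' point toward the target, of length `min(i * speed, full length)`, are
#' multiplied by `needle_contrast`. Bilateral setups apply a second,
#' mirrored needle. The background never changes across frames, so
#' frame-to-frame differences are confined to the advancing needle tip.
#'
#' @param spec A [phantom_spec()].
#' @param scenario An [intervention_scenario()].
#' @return List: `frames` (N x N x n_frames magnitude array in [0, 1]),
#'   `background` (N x N), `scenario`, `spec`.
#' @export
simulate_intervention <- function(spec, scenario) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(scenario, "intervention_scenario"))
  N <- spec$matrix_size
  N_mm <- N * spec$pixel_mm
  entry <- scenario$entry_point_mm
  target <- scenario$target_point_mm
  full <- sqrt(sum((target - entry)^2))
  tip_end <- entry + (target - entry)  # needle never passes the target
  inside <- function(p) all(p >= 0) && all(p <= N_mm)
  if (!inside(entry) || !inside(tip_end)) {
    stop("needle path leaves the image support")
  }
  bg <- make_background(spec)
  frames <- array(0, dim = c(N, N, scenario$n_frames))
  depths <- needle_depth_mm(scenario)
  mirror <- function(p) c(p[1], N_mm - p[2])
  for (i in seq_len(scenario$n_frames)) {
    m <- .needle_mask(N, spec$pixel_mm, entry, target, depths[i],
                      scenario$needle_width_mm)
    if (scenario$bilateral) {
      m <- m | .needle_mask(N, spec$pixel_mm, mirror(entry), mirror(target),
                            depths[i], scenario$needle_width_mm)
    }
    f <- bg
    f[m] <- f[m] * scenario$needle_contrast
    frames[, , i] <- f
  }
  list(frames = frames, background = bg, scenario = scenario, spec = spec)
}

#' Simulate a DBS-electrode style sequence
#'
#' Same insertion engine with an electrode-style feature: a thin
#' hyperintense shaft with a brighter tip, grouped 5 frames per slice to
#' mirror slice-wise electrode data. Accepts the high-resolution radial
#' protocol (e.g. 512 matrix / 512 readout / 402 spokes) through `spec`
#' and the downstream scheme.
#'
#' @param spec A [phantom_spec()].
#' @param scenario An [intervention_scenario()]; `needle_contrast` > 1 is
#'   typical here (default scenario can pass 1.8).
#' @param frames_per_slice Frames per slice grouping (default 5).
#' @return As [simulate_intervention()], plus `frames_per_slice`.
#' @export
simulate_dbs_sequence <- function(spec, scenario, frames_per_slice = 5) {
  out <- simulate_intervention(spec, scenario)
  N <- spec$matrix_size
  depths <- needle_depth_mm(scenario)
  entry <- scenario$entry_point_mm
  target <- scenario$target_point_mm
  dir <- (target - entry) / sqrt(sum((target - entry)^2))
  # brighter 2 mm tip marker on top of the shaft
  for (i in seq_len(scenario$n_frames)) {
    if (depths[i] <= 0) next
    tip0 <- entry + max(depths[i] - 2, 0) * dir
    m <- .needle_mask(N, spec$pixel_mm, tip0, target,
                      min(2, depths[i]), scenario$needle_width_mm)
    f <- out$frames[, , i]
    f[m] <- pmin(f[m] * 1.25 + 0.1, 1)
    out$frames[, , i] <- f
  }
  out$frames_per_slice <- as.integer(frames_per_slice)
  out
}

#' Acquire multi-coil radial k-space from an image sequence
#'
#' Splits the sequence into groups of `fpg` frames, applies the forward
#' encoding operator (simulated coil maps, group-periodic golden-angle
#' trajectory) and optional i.i.d. circular complex Gaussian noise, and
#' returns paired k-space and ground-truth groups. With `out_dir` set,
#' writes one HDF5 k-space file and one NIfTI truth file per group plus
#' a manifest JSON recording every parameter.
#'
#' @param frames Magnitude (or complex) array (N x N x n_frames); a zero
#'   phase map is assumed for magnitude input.
#' @param spec A [phantom_spec()] (coils, noise, pixel size).
#' @param scheme A [group_scheme()]; `n_frames` must be divisible by
#'   `fpg`.
#' @param timing Optional [acquisition_timing()] stored with the data.
#' @param out_dir Optional output directory.
#' @param seed RNG seed for coil-noise realizations (default: spec seed).
#' @return List with `kspace` (list of `kspace_group`), `truth` (list of
#'   [image_group()]), `sens`, `op`, `manifest`.
#' @export
acquire <- function(frames, spec, scheme, timing = NULL, out_dir = NULL,
                    seed = spec$seed) {
  if (is.list(frames) && !is.null(frames$frames)) frames <- frames$frames
  N <- spec$matrix_size
  nf <- dim(frames)[3]
  if (nf %% scheme$fpg != 0) {
    stop("n_frames (", nf, ") is not divisible by fpg (", scheme$fpg, ")")
  }
  n_groups <- nf %/% scheme$fpg
  cfg <- trajectory_config(N)
  traj <- make_trajectory(cfg, scheme)
  sens <- simulate_coilmaps(spec$n_coils, N)
  op <- encoding_operator(sens, traj)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  kspace <- vector("list", n_groups)
  truth <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    idx <- ((g - 1) * scheme$fpg + 1):(g * scheme$fpg)
    xg <- frames[, , idx, drop = FALSE] + 0i
    kg <- enc_forward(op, xg)
    if (spec$noise_sd > 0) {
      n <- length(kg$data)
      kg$data <- kg$data + complex(
        real = stats::rnorm(n, sd = spec$noise_sd / sqrt(2)),
        imaginary = stats::rnorm(n, sd = spec$noise_sd / sqrt(2)))
    }
    kg$timing <- timing
    kg$noise_sd <- spec$noise_sd
    kspace[[g]] <- kg
    truth[[g]] <- image_group(xg, pixel_mm = spec$pixel_mm)
  }
  manifest <- list(matrix_size = N, pixel_mm = spec$pixel_mm,
                   n_coils = spec$n_coils, noise_sd = spec$noise_sd,
                   spf = scheme$spf, fpg = scheme$fpg, n_groups = n_groups,
                   n_frames = nf, seed = seed,
                   golden_angle_deg = cfg$golden_angle_deg,
                   readout_points = cfg$readout_points)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in seq_len(n_groups)) {
      write_kspace(kspace[[g]], file.path(out_dir, sprintf("kspace_g%03d.h5", g)),
                   pixel_mm = spec$pixel_mm)
      write_image_nifti(truth[[g]], file.path(out_dir, sprintf("truth_g%03d.nii", g)))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(kspace = kspace, truth = truth, sens = sens, op = op,
       manifest = manifest)
}
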