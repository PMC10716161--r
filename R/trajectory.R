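#' Golden-angle increment
#'
#' The azimuthal increment between consecutive radial spokes,
#' `90 * (sqrt(5) - 1)` degrees (~111.25 deg). Any contiguous subset of
#' spokes acquired with this increment covers k-space nearly uniformly,
#' which is what makes golden-angle radial sampling attractive for
#' real-time imaging: the grouping into frames can be chosen after (or
#' independently of) the acquisition.
#'
#' @param precision_decimals Non-negative integer; decimals to round to.
#' @return The golden-angle increment in degrees, rounded.
#' @examples
#' golden_angle_value(2) # 111.25
#' @export
golden_angle_value <- function(precision_decimals = 2) {
  stopifnot(length(precision_decimals) == 1, precision_decimals >= 0)
  round(90 * (sqrt(5) - 1), precision_decimals)
}

# exact increment used internally; the rounded 111.25 is display-only
.golden_angle_exact <- function() 90 * (sqrt(5) - 1)

#' Trajectory configuration
#'
#' @param matrix_size Image matrix size in pixels (square matrix assumed).
#' @param readout_points Samples per spoke; defaults to `matrix_size`.
#' @param golden_angle_deg Angle increment in degrees. `NULL` (default) uses
#'   the exact golden angle `90*(sqrt(5)-1)`.
#' @param angle_modulus_deg 360 (default) or 180; the modulus applied to
#'   accumulated spoke angles.
#' @return An object of class `trajectory_config`.
#' @export
trajectory_config <- function(matrix_size, readout_points = matrix_size,
                              golden_angle_deg = NULL,
                              angle_modulus_deg = 360) {
  stopifnot(matrix_size >= 1, readout_points >= matrix_size,
            angle_modulus_deg %in% c(180, 360))
  if (is.null(golden_angle_deg)) golden_angle_deg <- .golden_angle_exact()
  structure(list(matrix_size = as.integer(as.vector(matrix_size)),
                 readout_points = as.integer(as.vector(readout_points)),
                 golden_angle_deg = as.numeric(golden_angle_deg),
                 angle_modulus_deg = as.numeric(angle_modulus_deg)),
            class = "trajectory_config")
}

#' Group scheme: spokes per frame and frames per group
#'
#' A group of `p = spf * fpg` spokes is reconstructed jointly as `fpg`
#' frames of `spf` spokes each. The sampling trajectory repeats with a
#' period of one group.
#'
#' @param spf Spokes per frame (m).
#' @param fpg Frames per group (n).
#' @return An object of class `group_scheme` with field `spokes_per_group`.
#' @export
group_scheme <- function(spf, fpg) {
  stopifnot(spf >= 1, fpg >= 1)
  structure(list(spf = as.integer(spf), fpg = as.integer(fpg),
                 spokes_per_group = as.integer(spf) * as.integer(fpg)),
            class = "group_scheme")
}

#' Acquisition timing
#'
#' @param tr_ms Repetition time in ms.
#' @param n_partitions z-partitions for stack-of-stars (1 for 2D).
#' @param n_groups Number of acquired groups.
#' @return An object of class `acquisition_timing`.
#' @export
acquisition_timing <- function(tr_ms, n_partitions = 1, n_groups = 1) {
  stopifnot(tr_ms > 0, n_partitions >= 1, n_groups >= 1)
  structure(list(tr_ms = tr_ms, n_partitions = as.integer(n_partitions),
                 n_groups = as.integer(n_groups)),
            class = "acquisition_timing")
}

#' Periodic golden-angle radial trajectory for one group
#'
#' Spoke `i` (0-based) lies at angle `i * golden_angle_deg` modulo the
#' configured modulus; each spoke is a full diameter of `readout_points`
#' samples through the k-space origin, with radial coordinates
#' `(-nr/2):(nr/2-1) / nr` cycles/pixel. Group `g+1` reuses exactly the
#' same angles (the acquisition repeats with a period of one group), so
#' the returned trajectory serves every group.
#'
#' Angle accumulation uses the exact golden-angle increment to avoid
#' drift over many spokes; angles are reduced modulo
#' `config$angle_modulus_deg`.
#'
#' @param config A [trajectory_config()].
#' @param scheme A [group_scheme()].
#' @return An object of class `radial_trajectory` with `angles_deg`
#'   (length p) and `kcoords` (p x readout_points x 2, cycles/pixel in
#'   `[-0.5, 0.5)`).
#' @export
make_trajectory <- function(config, scheme) {
  stopifnot(inherits(config, "trajectory_config"), inherits(scheme, "group_scheme"))
  p <- scheme$spokes_per_group
  ang <- (seq_len(p) - 1) * config$golden_angle_deg
  ang <- ang %% config$angle_modulus_deg
  nr <- config$readout_points
  kr <- (seq_len(nr) - 1 - nr %/% 2) / nr   # radial samples, origin at index nr/2 (0-based)
  th <- ang * pi / 180
  kx <- outer(cos(th), kr)                  # p x nr
  ky <- outer(sin(th), kr)
  kcoords <- array(c(kx, ky), dim = c(p, nr, 2))
  structure(list(angles_deg = ang, kcoords = kcoords,
                 config = config, scheme = scheme, periodic = TRUE),
            class = "radial_trajectory")
}

#' Number of fully sampled radial spokes
#'
#' The Nyquist spoke count for a radial acquisition at a given matrix
#' size, `round(matrix_size * pi / 2)`: 201 spokes at 128, 402 at 256.
#'
#' @param matrix_size Matrix size in pixels.
#' @return Integer spoke count.
#' @export
full_spoke_count <- function(matrix_size) {
  stopifnot(all(matrix_size >= 1))
  as.integer(round(matrix_size * pi / 2))
}

#' Radial acceleration factor
#'
#' Ratio of the Nyquist-required spoke count to the spokes actually used
#' per frame, rounded to the nearest integer: at 128 matrix, SPF = 10
#' gives R = 20; SPF = 5, 8, 20 give R = 40, 25, 10.
#'
#' @param matrix_size Matrix size in pixels.
#' @param spf Spokes per frame.
#' @return Integer acceleration factor.
#' @export
acceleration_factor <- function(matrix_size, spf) {
  stopifnot(all(spf >= 1))
  as.integer(round(full_spoke_count(matrix_size) / spf))
}

#' Temporal resolution per frame (2D) or volume (stack-of-stars)
#'
#' `spf * n_partitions * tr_ms` milliseconds: one frame needs `spf`
#' spokes, each repeated over all z-partitions at one TR apiece.
#'
#' @param timing An [acquisition_timing()].
#' @param scheme A [group_scheme()].
#' @return Duration in ms.
#' @export
frame_duration_ms <- function(timing, scheme) {
  stopifnot(inherits(timing, "acquisition_timing"), inherits(scheme, "group_scheme"))
  scheme$spf * timing$n_partitions * timing$tr_ms
}

#' Group duration and total acquisition time
#'
#' @param timing An [acquisition_timing()] (with `n_groups`).
#' @param scheme A [group_scheme()].
#' @return Named list `group_s`, `total_s` in seconds.
#' @export
group_duration_and_total <- function(timing, scheme) {
  group_s <- scheme$fpg * frame_duration_ms(timing, scheme) / 1000
  list(group_s = group_s, total_s = timing$n_groups * group_s)
}
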