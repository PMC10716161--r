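## k-space HDF5 container.
##
## Layout: datasets /kdata/re, /kdata/im (float, coils x spokes x readout;
## the two real fields of the complex samples), /ktraj (spokes x readout
## x 2, cycles/pixel), /angles_deg (spokes); attributes tr_ms, spf, fpg,
## partitions, matrix_size, readout_points, pixel_mm, noise_sd,
## modulus_deg, golden_angle_deg attached to /kdata.

#' Write a k-space group to an HDF5 container
#'
#' @param kg A `kspace_group` from [kspace_group()] or [enc_forward()].
#' @param path Output file path (overwritten if present).
#' @param pixel_mm Pixel size recorded in the header (default 1).
#' @return `path`, invisibly.
#' @export
write_kspace <- function(kg, path, pixel_mm = 1) {
  stopifnot(inherits(kg, "kspace_group"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "kdata")
  rhdf5::h5write(Re(kg$data), path, "kdata/re")
  rhdf5::h5write(Im(kg$data), path, "kdata/im")
  rhdf5::h5write(kg$trajectory$kcoords, path, "ktraj")
  rhdf5::h5write(kg$trajectory$angles_deg, path, "angles_deg")
  fid <- rhdf5::H5Fopen(path)
  oid <- rhdf5::H5Gopen(fid, "kdata")
  cfg <- kg$trajectory$config
  att <- list(
    spf = kg$scheme$spf, fpg = kg$scheme$fpg,
    matrix_size = cfg$matrix_size, readout_points = cfg$readout_points,
    modulus_deg = cfg$angle_modulus_deg,
    golden_angle_deg = cfg$golden_angle_deg,
    pixel_mm = pixel_mm, noise_sd = kg$noise_sd,
    tr_ms = if (is.null(kg$timing)) NA_real_ else kg$timing$tr_ms,
    partitions = if (is.null(kg$timing)) 1L else kg$timing$n_partitions)
  for (nm in names(att)) rhdf5::h5writeAttribute(att[[nm]], oid, nm)
  rhdf5::H5Gclose(oid)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a k-space group from an HDF5 container
#'
#' @param path File written by [write_kspace()].
#' @return A `kspace_group` with its trajectory, scheme and timing
#'   restored. A legacy file without a `noise_sd` attribute defaults to 0
#'   with a warning.
#' @export
read_kspace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ls <- rhdf5::h5ls(path)
  need <- c("re", "im", "ktraj", "angles_deg")
  have <- ls$name
  for (nm in need) {
    if (!nm %in% have) stop("k-space container is missing dataset '", nm, "': ", path)
  }
  re <- rhdf5::h5read(path, "kdata/re")
  im <- rhdf5::h5read(path, "kdata/im")
  ktraj <- rhdf5::h5read(path, "ktraj")
  ang <- as.vector(rhdf5::h5read(path, "angles_deg"))
  att <- lapply(rhdf5::h5readAttributes(path, "kdata"), as.vector)
  if (is.null(att$noise_sd)) {
    warning("k-space container has no 'noise_sd' attribute; assuming 0")
    att$noise_sd <- 0
  }
  cfg <- trajectory_config(att$matrix_size, att$readout_points,
                           golden_angle_deg = att$golden_angle_deg,
                           angle_modulus_deg = att$modulus_deg)
  sch <- group_scheme(att$spf, att$fpg)
  traj <- make_trajectory(cfg, sch)
  if (max(abs(traj$kcoords - ktraj)) > 1e-5) {
    # non-default trajectory: keep the stored coordinates
    traj$kcoords <- ktraj
    traj$angles_deg <- ang
  }
  timing <- if (is.na(att$tr_ms)) NULL else
    acquisition_timing(att$tr_ms, att$partitions)
  data <- re + 1i * im
  if (length(dim(data)) != 3) dim(data) <- dim(re)
  kg <- kspace_group(data, traj, timing = timing, noise_sd = att$noise_sd)
  attr(kg, "pixel_mm") <- att$pixel_mm
  kg
}

#' Write an image group (or sequence) as NIfTI
#'
#' Magnitude is written to `path`; if `phase = TRUE`, the phase volume
#' goes to a `_phase` sibling file. Axes are (x, y, frame) for a single
#' group. Pixel size is recorded in the header.
#'
#' @param x An [image_group()] or complex/numeric array (N x N x frames).
#' @param path Output `.nii` path.
#' @param phase Also write the phase volume (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_image_nifti <- function(x, path, phase = FALSE) {
  frames <- if (inherits(x, "image_group")) x$frames else x
  pix <- if (inherits(x, "image_group")) x$pixel_mm else 1
  img <- RNifti::asNifti(abs(frames))
  RNifti::pixdim(img) <- c(pix, pix, 1)
  RNifti::writeNifti(img, path)
  if (phase) {
    p <- sub("\\.nii(\\.gz)?$", "_phase.nii", path)
    ph <- RNifti::asNifti(Arg(frames))
    RNifti::pixdim(ph) <- c(pix, pix, 1)
    RNifti::writeNifti(ph, p)
  }
  invisible(path)
}

#' Read a NIfTI magnitude (+ optional phase) image sequence
#'
#' @param path `.nii` path written by [write_image_nifti()] or any NIfTI
#'   volume with axes (x, y, frame) or (x, y, z, frame).
#' @param phase_path Optional phase volume to recombine into complex data.
#' @return An [image_group()] (complex if phase is supplied).
#' @export
read_image_nifti <- function(path, phase_path = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim = dim(arr))  # drop niftiImage attributes
  pix <- RNifti::pixdim(img)[1]
  if (!is.null(phase_path)) {
    ph <- as.array(RNifti::readNifti(phase_path))
    arr <- arr * exp(1i * as.vector(ph))
  }
  image_group(arr, pixel_mm = pix)
}
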