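#' Peak signal-to-noise ratio
#'
#' Magnitudes are normalized so the reference peaks at 1, then
#' `20 * log10(1 / RMSE)`. Identical images are reported at the
#' documented cap (99 dB by default) rather than infinity.
#'
#' @param ref Reference array (magnitude taken if complex).
#' @param rec Reconstruction, same shape.
#' @param cap dB value reported for identical images (default 99).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, rec, cap = 99) {
  ref <- abs(ref); rec <- abs(rec)
  stopifnot(all(dim(ref) == dim(rec)) || length(ref) == length(rec))
  peak <- max(ref)
  if (peak == 0) stop("reference image is identically zero")
  ref <- ref / peak; rec <- rec / peak
  rmse <- sqrt(mean((ref - rec)^2))
  if (rmse == 0) return(cap)
  min(20 * log10(1 / rmse), cap)
}

.gauss_kernel <- function(size = 11, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 'valid' convolution of a matrix with a 1D kernel in both dims
.filter_valid <- function(m, k) {
  n <- length(k)
  nr <- nrow(m) - n + 1; nc <- ncol(m) - n + 1
  out <- matrix(0, nr, ncol(m))
  for (i in seq_len(n)) out <- out + k[i] * m[i:(i + nr - 1), , drop = FALSE]
  out2 <- matrix(0, nr, nc)
  for (j in seq_len(n)) out2 <- out2 + k[j] * out[, j:(j + nc - 1), drop = FALSE]
  out2
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (sd 1.5), K1 = 0.01,
#' K2 = 0.03 and data range 1 (images are normalized to the reference
#' peak first). Local statistics use windows fully inside the image.
#'
#' @param ref Reference array (2D, or 3D processed frame-by-frame).
#' @param rec Reconstruction, same shape.
#' @return SSIM score in [-1, 1] (mean over frames for 3D input).
#' @export
ssim <- function(ref, rec) {
  ref <- abs(ref); rec <- abs(rec)
  if (length(dim(ref)) == 3) {
    return(mean(vapply(seq_len(dim(ref)[3]),
                       function(t) ssim(ref[, , t], rec[, , t]), numeric(1))))
  }
  stopifnot(all(dim(ref) == dim(rec)))
  if (any(dim(ref) < 11)) stop("image smaller than the 11x11 SSIM window")
  peak <- max(ref)
  if (peak == 0) stop("reference image is identically zero")
  x <- ref / peak; y <- rec / peak
  k <- .gauss_kernel(11, 1.5)
  C1 <- 0.01^2; C2 <- 0.03^2
  mx <- .filter_valid(x, k); my <- .filter_valid(y, k)
  sxx <- .filter_valid(x * x, k) - mx^2
  syy <- .filter_valid(y * y, k) - my^2
  sxy <- .filter_valid(x * y, k) - mx * my
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(s)
}

#' Track the needle tip depth along the planned trajectory
#'
#' Per frame, the absolute difference against the baseline image is
#' taken inside a corridor around the planned entry-target line (the
#' corridor confines the measurement to the planned trajectory, so
#' reconstruction artifacts elsewhere in the field of view - aliasing
#' streaks, edge ringing - cannot masquerade as the tip). The
#' difference is reduced to a 1D profile along the line (maximum over
#' the corridor cross-section in bins of one pixel), and the depth is
#' the farthest `threshold_frac`-of-maximum crossing of that profile,
#' linearly interpolated between bins for sub-pixel precision. Frames
#' with no suprathreshold difference yield 0 with a warning.
#'
#' When the acquisition repeats with a period of one group, passing
#' the reconstructed baseline *group* (an array) lets frame `i` be
#' compared against baseline frame `((i - 1) mod fpg) + 1`, whose
#' aliasing pattern matches exactly - systematic reconstruction error
#' then cancels in the difference.
#'
#' @param frames Array (N x N x n_frames), magnitude or complex.
#' @param baseline Baseline (pre-insertion) image (N x N), or a
#'   baseline group (N x N x fpg) used cyclically.
#' @param entry_mm,target_mm Planned line, (row, col) in mm.
#' @param pixel_mm Pixel size in mm (default 1).
#' @param threshold_frac Crossing threshold as a fraction of the
#'   per-frame profile maximum (default 0.5).
#' @param corridor_mm Half-width of the corridor around the planned
#'   line (default 5 mm).
#' @return Numeric vector of per-frame depths in mm.
#' @export
track_tip <- function(frames, baseline, entry_mm, target_mm, pixel_mm = 1,
                      threshold_frac = 0.5, corridor_mm = 5) {
  if (length(dim(frames)) == 2) dim(frames) <- c(dim(frames), 1)
  N <- dim(frames)[1]
  b <- abs(baseline)
  if (length(dim(b)) == 2) dim(b) <- c(dim(b), 1)
  nb <- dim(b)[3]
  dirv <- (target_mm - entry_mm) / sqrt(sum((target_mm - entry_mm)^2))
  seg_len <- sqrt(sum((target_mm - entry_mm)^2))
  px <- (seq_len(N) - 0.5) * pixel_mm
  X <- matrix(px, N, N); Y <- matrix(px, N, N, byrow = TRUE)
  vx <- X - entry_mm[1]; vy <- Y - entry_mm[2]
  proj <- vx * dirv[1] + vy * dirv[2]
  perp <- sqrt(pmax((vx - proj * dirv[1])^2 + (vy - proj * dirv[2])^2, 0))
  corridor <- perp <= corridor_mm & proj >= -pixel_mm & proj <= seg_len + pixel_mm
  bins <- pmin(pmax(floor(proj[corridor] / pixel_mm), 0), ceiling(seg_len / pixel_mm)) + 1L
  nbin <- max(bins)
  centers <- ((seq_len(nbin) - 1) + 0.5) * pixel_mm
  cor_idx <- split(which(corridor), factor(bins, levels = seq_len(nbin)))
  depths <- numeric(dim(frames)[3])
  empty <- 0L
  for (t in seq_len(dim(frames)[3])) {
    d <- abs(abs(frames[, , t]) - b[, , ((t - 1) %% nb) + 1])
    prof <- vapply(cor_idx, function(ix) if (length(ix)) max(d[ix]) else 0,
                   numeric(1))
    M <- max(prof)
    if (M == 0) {
      empty <- empty + 1L
      next
    }
    thr <- threshold_frac * M
    above <- which(prof >= thr)
    if (length(above) == 0) {
      empty <- empty + 1L
      next
    }
    k <- max(above)
    if (k < nbin && prof[k + 1] < thr && prof[k] > prof[k + 1]) {
      # sub-pixel: interpolate the crossing between bin k and k+1
      frac <- (prof[k] - thr) / (prof[k] - prof[k + 1])
      depth <- centers[k] + frac * pixel_mm
    } else {
      depth <- centers[k]
    }
    depths[t] <- min(max(depth, 0), seg_len)
  }
  if (empty > 0) warning(empty, " frame(s) had no suprathreshold difference; depth 0")
  depths
}

#' Per-frame evaluation report
#'
#' Mean and standard deviation use the sample (n-1) convention.
#'
#' @param ref,rec Arrays (N x N x n_frames).
#' @param track Optional list with `baseline`, `entry_mm`, `target_mm`,
#'   `pixel_mm`, `theoretical_mm` to add depth tracking.
#' @return Object of class `eval_report`: per-frame `psnr_db` and
#'   `ssim`, summary statistics, and (when tracked) `depth_series_mm`
#'   and `depth_error_mm`.
#' @export
eval_report <- function(ref, rec, track = NULL) {
  nt <- dim(ref)[3]
  ps <- vapply(seq_len(nt), function(t) psnr(ref[, , t], rec[, , t]), numeric(1))
  ss <- vapply(seq_len(nt), function(t) ssim(ref[, , t], rec[, , t]), numeric(1))
  rep <- list(psnr_db = ps, ssim = ss,
              mean_psnr = mean(ps), sd_psnr = stats::sd(ps),
              mean_ssim = mean(ss), sd_ssim = stats::sd(ss))
  if (!is.null(track)) {
    depth <- track_tip(rec, track$baseline, track$entry_mm, track$target_mm,
                       pixel_mm = track$pixel_mm %||% 1,
                       threshold_frac = track$threshold_frac %||% 0.5)
    rep$depth_series_mm <- depth
    if (!is.null(track$theoretical_mm)) {
      rep$depth_error_mm <- abs(depth - track$theoretical_mm)
    }
  }
  structure(rep, class = "eval_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
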