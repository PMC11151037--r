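#' Rigid translation registration by phase correlation
#'
#' Estimates the integer-voxel translation of `moving` relative to `fixed`
#' from the peak of the phase-correlation surface (normalized cross-power
#' spectrum), restricted to `max_shift_vox` per axis. A positive shift of
#' `(dz, dy, dx)` means `moving` is `fixed` translated forward by that
#' amount; applying the negated shift aligns it back.
#'
#' @param fixed,moving [volume3d()] objects (or 3D arrays) of equal shape.
#' @param max_shift_vox search bound per axis (default 50).
#' @return list with `shift_vox` (integer z, y, x), `peak` (the normalized
#'   cross-correlation coefficient at the recovered shift) and `failed`
#'   (TRUE when that correlation is below 0.2, signalling unreliable
#'   registration).
#' @export
rigid_register_translation <- function(fixed, moving, max_shift_vox = 50L) {
  a <- if (inherits(fixed, "Volume3D")) fixed$data else fixed
  b <- if (inherits(moving, "Volume3D")) moving$data else moving
  if (!identical(dim(a), dim(b))) stop("volumes must have equal shape")
  d <- dim(a)
  Fa <- fft(a - mean(a))
  Fb <- fft(b - mean(b))
  cross <- Fa * Conj(Fb)
  mag <- Mod(cross)
  mag[mag == 0] <- 1
  r <- Re(fft(cross / mag, inverse = TRUE)) / length(a)

  # wrap frequencies to signed shifts and bound the search
  ax_shift <- function(n) {
    s <- 0:(n - 1)
    ifelse(s > n / 2, s - n, s)
  }
  sz <- ax_shift(d[1]); sy <- ax_shift(d[2]); sx <- ax_shift(d[3])
  ok <- outer(outer(abs(sz) <= max_shift_vox, abs(sy) <= max_shift_vox,
                    `&`), abs(sx) <= max_shift_vox, `&`)
  r_ok <- r
  r_ok[!ok] <- -Inf
  i <- arrayInd(which.max(r_ok), d)
  shift <- as.integer(-c(sz[i[1]], sy[i[2]], sx[i[3]]))
  # reliability: normalized cross-correlation at the recovered shift
  peak <- stats::cor(as.vector(a),
                     as.vector(circular_shift3d(b, -shift)))
  failed <- is.na(peak) || peak < 0.2
  if (failed) warning("cross-correlation at the recovered shift below ",
                      "0.2: registration may have failed")
  list(shift_vox = shift, peak = peak, failed = failed)
}

#' Apply an integer translation to a volume
#'
#' Circular (toroidal) shift, the inverse operation of the shift recovered
#' by [rigid_register_translation()] on periodically shifted content.
#'
#' @param vol a [volume3d()] object.
#' @param shift_vox integer (z, y, x) shift.
#' @return shifted `Volume3D`.
#' @export
apply_shift <- function(vol, shift_vox) {
  stopifnot(inherits(vol, "Volume3D"))
  volume3d(circular_shift3d(vol$data, shift_vox), vol$voxel_size_um,
           if (is.null(vol$mask)) NULL else
             circular_shift3d(vol$mask, shift_vox))
}

#' Extract matched subvolumes from an aligned scan pair
#'
#' Crops identically positioned regions from a fixed volume and an aligned
#' moving volume. Default cube size is 300 voxels per side (0.825 mm at
#' 2.75 um/voxel); for full-depth (meniscus-style) comparison pass a z
#' extent covering the whole depth.
#'
#' @param fixed,aligned_moving aligned [volume3d()] objects of equal shape.
#' @param size_vox (z, y, x) crop size, default c(300, 300, 300).
#' @param origin_vox 0-based (z, y, x) crop origin; default centers the
#'   crop.
#' @return list of two `Volume3D` crops `a` and `b` plus the `region`.
#' @export
matched_subvolumes <- function(fixed, aligned_moving,
                               size_vox = c(300, 300, 300),
                               origin_vox = NULL) {
  stopifnot(inherits(fixed, "Volume3D"), inherits(aligned_moving, "Volume3D"))
  d <- dim(fixed$data)
  if (!identical(d, dim(aligned_moving$data))) {
    stop("volumes must have equal shape")
  }
  if (any(size_vox > d)) stop("requested region exceeds the volumes")
  if (is.null(origin_vox)) origin_vox <- floor((d - size_vox) / 2)
  region <- cbind(from = origin_vox, to = origin_vox + size_vox)
  rownames(region) <- c("z", "y", "x")
  list(a = crop_region(fixed, region),
       b = crop_region(aligned_moving, region),
       region = region)
}

#' Compare two repeated analysis runs
#'
#' Difference metrics between the outputs of the same analysis applied to
#' two repeated scans: per-layer absolute density differences for
#' [layer_density_profile()] outputs, and maximum plus mean absolute
#' bin differences for [orientation_histograms()] outputs. Symmetric in
#' its arguments and identically zero for identical inputs.
#'
#' @param analysisA,analysisB two `DensityProfile`s or two
#'   `OrientationHistogram`s.
#' @return An object of class `RepeatReport`: for density profiles, list
#'   with `density_abs_diff_pct` (per layer) and `max_abs_diff_pct`; for
#'   histograms, list with `hist_abs_diff` (per bin), `hist_max_abs_diff`
#'   and `hist_mean_abs_diff`.
#' @export
compare_runs <- function(analysisA, analysisB) {
  if (inherits(analysisA, "DensityProfile") &&
      inherits(analysisB, "DensityProfile")) {
    if (analysisA$n_layers != analysisB$n_layers) {
      stop("density profiles have different layer counts")
    }
    d <- abs(analysisA$layer_fraction_pct - analysisB$layer_fraction_pct)
    out <- list(kind = "density", density_abs_diff_pct = d,
                max_abs_diff_pct = max(d))
  } else if (inherits(analysisA, "OrientationHistogram") &&
             inherits(analysisB, "OrientationHistogram")) {
    if (!identical(analysisA$bin_edges_deg, analysisB$bin_edges_deg) ||
        !identical(analysisA$angle_kind, analysisB$angle_kind)) {
      stop("histograms have incompatible binning")
    }
    d <- abs(analysisA$counts_norm - analysisB$counts_norm)
    out <- list(kind = "histogram", angle_kind = analysisA$angle_kind,
                hist_abs_diff = d, hist_max_abs_diff = max(d),
                hist_mean_abs_diff = mean(d))
  } else {
    stop("unsupported or mismatched analysis types")
  }
  class(out) <- "RepeatReport"
  out
}

#' @export
print.RepeatReport <- function(x, ...) {
  if (x$kind == "density") {
    cat(sprintf("RepeatReport (density): max |diff| = %.4g%%\n",
                x$max_abs_diff_pct))
  } else {
    cat(sprintf("RepeatReport (%s histogram): max |diff| = %.4g, mean = %.4g\n",
                x$angle_kind, x$hist_max_abs_diff, x$hist_mean_abs_diff))
  }
  invisible(x)
}
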