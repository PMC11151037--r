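#' 3D fiber orientation by the structure gradient tensor
#'
#' Classic structure-tensor pipeline for volumetric fiber mapping: the
#' volume is smoothed with a Gaussian (`sigma_grad_px`, default 1), the 3D
#' intensity gradient is computed with a Sobel filter, the outer-product
#' tensor (6 unique components) is smoothed component-wise with a second
#' Gaussian (`sigma_tensor_px`, default 4), and each voxel's symmetric
#' 3x3 tensor is eigendecomposed. Intensity varies least along a fiber, so
#' the eigenvector of the smallest eigenvalue (the "third" eigenvector for
#' eigenvalues sorted descending) is the local fiber direction.
#'
#' Directions are axial: each is mapped to azimuth `phi` in [0, 180)
#' degrees (in-plane x--y angle from +x) and elevation `theta` in
#' [-90, 90] degrees (angle from the x--y plane toward +z, the loading
#' axis). The canonical representative has its in-plane projection in the
#' upper half-plane; for directions along +/-z (no in-plane component)
#' `theta` is +90 and `phi` is reported but meaningless (degenerate).
#'
#' @param vol a [volume3d()] object or 3D array.
#' @param sigma_grad_px pre-smoothing standard deviation (voxels).
#' @param sigma_tensor_px tensor-smoothing standard deviation (voxels).
#' @param coherence_threshold voxels with anisotropy coherence below this
#'   are marked invalid (default 0.01).
#' @return An object of class `OrientationField`: list of 3D arrays
#'   `azimuth_deg`, `elevation_deg`, `coherence`
#'   (`(l1 - l3) / (l1 + l2 + l3)`, 0 where the trace vanishes) and
#'   `valid_mask` (coherence above threshold, non-vanishing gradient
#'   energy, and at least `2 * sigma_tensor_px` voxels from the border).
#' @export
structure_tensor_orientation <- function(vol, sigma_grad_px = 1,
                                         sigma_tensor_px = 4,
                                         coherence_threshold = 0.01) {
  x <- if (inherits(vol, "Volume3D")) vol$data else vol
  d <- dim(x)
  if (any(d < 6 * sigma_tensor_px)) {
    stop("volume must exceed 6 * sigma_tensor in every axis")
  }
  if (!all(is.finite(x))) stop("volume contains non-finite values")

  xs <- gaussian_smooth3d(x, sigma_grad_px)
  g <- sobel_gradient3d(xs)
  jxx <- gaussian_smooth3d(g$gx * g$gx, sigma_tensor_px)
  jyy <- gaussian_smooth3d(g$gy * g$gy, sigma_tensor_px)
  jzz <- gaussian_smooth3d(g$gz * g$gz, sigma_tensor_px)
  jxy <- gaussian_smooth3d(g$gx * g$gy, sigma_tensor_px)
  jxz <- gaussian_smooth3d(g$gx * g$gz, sigma_tensor_px)
  jyz <- gaussian_smooth3d(g$gy * g$gz, sigma_tensor_px)

  eig <- .tensor_eigen3d(jxx, jyy, jzz, jxy, jxz, jyz)
  trace <- eig$l1 + eig$l2 + eig$l3
  coherence <- array(0, dim = d)
  nz <- trace > 0
  coherence[nz] <- (eig$l1[nz] - eig$l3[nz]) / trace[nz]

  ang <- direction_to_angles(eig$vx, eig$vy, eig$vz)

  border <- ceiling(2 * sigma_tensor_px)
  interior <- array(FALSE, dim = d)
  interior[(border + 1):(d[1] - border),
           (border + 1):(d[2] - border),
           (border + 1):(d[3] - border)] <- TRUE
  valid <- interior & nz & (coherence >= coherence_threshold)

  structure(list(azimuth_deg = ang$azimuth_deg,
                 elevation_deg = ang$elevation_deg,
                 coherence = coherence, valid_mask = valid,
                 eigenvalues = eig[c("l1", "l2", "l3")]),
            class = "OrientationField")
}

# Map direction components (any sign, arrays or vectors) to axial angles:
# azimuth in [0, 180) from +x in the x-y plane, elevation in [-90, 90]
# from the x-y plane toward +z. Representative chosen so the in-plane
# projection lies in the upper half-plane (vy >= 0; vx >= 0 when vy == 0),
# which keeps antipodal directions on identical angles.
direction_to_angles <- function(vx, vy, vz) {
  dims <- dim(vx)
  flip <- vy < 0 | (vy == 0 & vx < 0)
  vx <- ifelse(flip, -vx, vx)
  vy <- ifelse(flip, -vy, vy)
  vz <- ifelse(flip, -vz, vz)
  nrm <- sqrt(vx^2 + vy^2 + vz^2)
  nrm[nrm == 0] <- 1
  az <- atan2(vy, vx) * 180 / pi # in [0, 180]
  az[az >= 180] <- 0
  el <- asin(pmax(-1, pmin(1, vz / nrm))) * 180 / pi
  # pure z directions: no in-plane component, elevation +/-90 -> +90
  purez <- abs(vz / nrm) > 1 - 1e-12
  el[purez] <- 90
  az[purez] <- 0
  if (!is.null(dims)) { dim(az) <- dims; dim(el) <- dims }
  list(azimuth_deg = az, elevation_deg = el)
}

#' Normalized orientation histograms
#'
#' Histograms of azimuth and elevation over the masked valid voxels of an
#' [structure_tensor_orientation()] field, with uniform `bin_deg` bins
#' (default 1 degree) and counts normalized to sum to 1. Optional
#' coherence weighting (off by default).
#'
#' @param field an `OrientationField`.
#' @param mask optional logical array restricting the voxels (intersected
#'   with the field's validity mask).
#' @param bin_deg bin width in degrees.
#' @param weight_by_coherence weight each voxel by its coherence.
#' @return list of two `OrientationHistogram` objects, `azimuth` (support
#'   [0, 180)) and `elevation` (support [-90, 90]); each has `bin_edges_deg`,
#'   `bin_centers_deg`, `counts_norm` and `angle_kind`.
#' @export
orientation_histograms <- function(field, mask = NULL, bin_deg = 1,
                                   weight_by_coherence = FALSE) {
  stopifnot(inherits(field, "OrientationField"))
  sel <- field$valid_mask
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) stop("no valid voxels selected")
  w <- if (weight_by_coherence) field$coherence[sel] else
    rep(1, sum(sel))

  hist_one <- function(vals, lo, hi, kind) {
    edges <- seq(lo, hi, by = bin_deg)
    if (edges[length(edges)] < hi) edges <- c(edges, hi)
    b <- findInterval(vals, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    counts <- vapply(seq_len(length(edges) - 1),
                     function(i) sum(w[b == i]), numeric(1))
    structure(list(bin_edges_deg = edges,
                   bin_centers_deg = (edges[-1] + edges[-length(edges)]) / 2,
                   counts_norm = counts / sum(counts),
                   angle_kind = kind),
              class = "OrientationHistogram")
  }
  list(azimuth = hist_one(field$azimuth_deg[sel], 0, 180, "azimuth"),
       elevation = hist_one(field$elevation_deg[sel], -90, 90, "elevation"))
}

#' Average several normalized histograms
#'
#' Bin-wise mean of identically binned normalized histograms (e.g. one per
#' analysis subvolume); the result is again normalized.
#'
#' @param hists list of `OrientationHistogram` objects with identical bins.
#' @return an `OrientationHistogram`.
#' @export
average_histograms <- function(hists) {
  if (length(hists) == 0L) stop("no histograms supplied")
  e1 <- hists[[1]]$bin_edges_deg
  same <- vapply(hists, function(h) identical(h$bin_edges_deg, e1),
                 logical(1))
  if (!all(same)) stop("histograms have mismatched binning")
  m <- rowMeans(vapply(hists, function(h) h$counts_norm,
                       numeric(length(e1) - 1)))
  out <- hists[[1]]
  out$counts_norm <- m / sum(m)
  out
}

#' Track the histogram peak across time points
#'
#' For a sequence of identically binned orientation histograms (one per
#' time point / strain level), reports the maximum normalized count and
#' its bin center. Tied maxima resolve to the bin with the smallest
#' absolute angle and are flagged.
#'
#' @param histograms list of `OrientationHistogram` objects in time order.
#' @param time_points optional labels/values, one per histogram.
#' @return data.frame with `time_point`, `peak_angle_deg`,
#'   `peak_height`, `tied` (logical).
#' @export
track_peak_height <- function(histograms, time_points = NULL) {
  if (length(histograms) == 0L) stop("no histograms supplied")
  e1 <- histograms[[1]]$bin_edges_deg
  same <- vapply(histograms, function(h) identical(h$bin_edges_deg, e1),
                 logical(1))
  if (!all(same)) stop("histograms have mismatched binning")
  if (is.null(time_points)) time_points <- seq_along(histograms)
  rows <- lapply(seq_along(histograms), function(i) {
    h <- histograms[[i]]
    mx <- max(h$counts_norm)
    at <- which(h$counts_norm >= mx - 1e-15)
    tied <- length(at) > 1L
    pick <- at[which.min(abs(h$bin_centers_deg[at]))]
    data.frame(time_point = time_points[i],
               peak_angle_deg = h$bin_centers_deg[pick],
               peak_height = mx, tied = tied)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
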