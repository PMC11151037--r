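#' Segment chondrocyte-like inclusions
#'
#' Deterministic classical segmentation pipeline for cell-scale inclusions:
#' Gaussian smoothing, polarity normalization (cells darker or brighter
#' than the matrix), automatic (Otsu) or manual thresholding inside the
#' tissue mask, morphological opening (radius 1), and a connected-component
#' size filter keeping components whose voxel volume corresponds to a
#' spherical equivalent diameter within `size_range_um`.
#'
#' @param vol a [volume3d()] object; its `mask` (or `tissue_mask`) defines
#'   the tissue region.
#' @param polarity `"dark"` (lacuna-like, default) or `"bright"`.
#' @param smooth_sigma_px Gaussian pre-smoothing standard deviation.
#' @param size_range_um (min, max) spherical-equivalent cell diameter in
#'   micrometres.
#' @param threshold `"otsu"` or a numeric manual threshold (applied to the
#'   polarity-normalized smoothed image).
#' @param tissue_mask optional logical array overriding `vol$mask`.
#' @return logical array of cell voxels; attribute `"degenerate"` flags an
#'   all-or-nothing threshold outcome.
#' @export
segment_chondrocytes <- function(vol, polarity = c("dark", "bright"),
                                 smooth_sigma_px = 1,
                                 size_range_um = c(8, 40),
                                 threshold = "otsu",
                                 tissue_mask = NULL) {
  stopifnot(inherits(vol, "Volume3D"))
  polarity <- match.arg(polarity)
  if (is.null(tissue_mask)) tissue_mask <- vol$mask
  if (is.null(tissue_mask) || !any(tissue_mask)) {
    stop("a non-empty tissue mask is required")
  }
  x <- gaussian_smooth3d(vol$data, smooth_sigma_px)
  if (polarity == "dark") x <- -x # cells become the high tail
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(x[tissue_mask])
  } else {
    as.numeric(threshold)
  }
  cells <- (x > thr) & tissue_mask
  # degenerate threshold guard: chondrocyte volume fractions are bounded
  # well below 30%; a split selecting over 35% of the tissue (or nothing)
  # means the intensity histogram has no cell/matrix separation
  sel_frac <- sum(cells) / sum(tissue_mask)
  degenerate <- sel_frac == 0 || sel_frac > 0.35
  if (degenerate) {
    empty <- array(FALSE, dim = dim(vol$data))
    attr(empty, "threshold") <- thr
    attr(empty, "degenerate") <- TRUE
    warning("degenerate threshold: ",
            sprintf("%.1f%%", 100 * sel_frac),
            " of tissue selected; returning empty mask")
    return(empty)
  }
  cells <- binary_open3d(cells, 1L) & tissue_mask

  # size filter on spherical-equivalent diameter
  vox_vol_um3 <- vol$voxel_size_um^3
  vol_bounds_vox <- (pi / 6) * size_range_um^3 / vox_vol_um3
  lab <- label_components(cells)
  n_comp <- attr(lab, "n_components")
  if (n_comp > 0) {
    sizes <- tabulate(lab[lab > 0L], nbins = n_comp)
    keep <- sizes >= vol_bounds_vox[1] & sizes <= vol_bounds_vox[2]
    cells <- array(lab > 0L & keep[pmax(lab, 1L)], dim = dim(lab))
  }
  attr(cells, "threshold") <- thr
  attr(cells, "degenerate") <- degenerate
  cells
}

#' Depth-resolved chondrocyte density profile
#'
#' Divides the tissue z-extent into `n_layers` equal-thickness layers
#' (layer 1 at 0\% depth = articular surface) and reports the chondrocyte
#' volume percentage per layer: `100 * cell voxels / tissue voxels` within
#' each layer. Voxels are assigned to layers by their z index.
#'
#' @param cell_mask logical array of segmented cell voxels.
#' @param tissue_mask logical array of tissue voxels (same shape).
#' @param n_layers number of depth layers (default 10).
#' @return An object of class `DensityProfile`: list with
#'   `layer_fraction_pct` (length `n_layers`), `layer_bounds_vox`
#'   (`n_layers + 1` cut positions, 0-based), `cell_vox` and `tissue_vox`
#'   per layer. Layers with no tissue get `NA` and are flagged.
#' @export
layer_density_profile <- function(cell_mask, tissue_mask, n_layers = 10L) {
  if (!identical(dim(cell_mask), dim(tissue_mask))) {
    stop("cell and tissue masks must have the same shape")
  }
  # restrict to the z-range actually containing tissue
  zs <- which(apply(tissue_mask, 1, any))
  if (length(zs) == 0L) stop("tissue mask is empty")
  z0 <- min(zs); z1 <- max(zs)
  bounds <- round(seq(z0 - 1, z1, length.out = n_layers + 1)) # 0-based cuts
  frac <- cellv <- tisv <- numeric(n_layers)
  for (l in seq_len(n_layers)) {
    iz <- (bounds[l] + 1):bounds[l + 1]
    tisv[l] <- sum(tissue_mask[iz, , , drop = FALSE])
    cellv[l] <- sum(cell_mask[iz, , , drop = FALSE] &
                      tissue_mask[iz, , , drop = FALSE])
    frac[l] <- if (tisv[l] > 0) 100 * cellv[l] / tisv[l] else NA_real_
  }
  if (anyNA(frac)) warning("layer(s) without tissue voxels: density NA")
  structure(list(layer_fraction_pct = frac, layer_bounds_vox = bounds,
                 cell_vox = cellv, tissue_vox = tisv,
                 n_layers = as.integer(n_layers)),
            class = "DensityProfile")
}

#' @export
print.DensityProfile <- function(x, ...) {
  cat("DensityProfile (", x$n_layers, " layers, surface first):\n", sep = "")
  cat(" ", paste(sprintf("%.2f%%", x$layer_fraction_pct), collapse = " "),
      "\n")
  invisible(x)
}

#' Density-vs-depth table across time points
#'
#' Collects per-subvolume density profiles from several time points (strain
#' levels) into one tidy long-format table. Profiles are layered per
#' subvolume first, then averaged layer-wise across subvolumes.
#'
#' @param profiles_by_time named list; element `t` is a list of
#'   `DensityProfile`s (one per subvolume) for that time point.
#' @param strain_pct optional numeric vector of strain levels, one per time
#'   point.
#' @return data.frame with columns `time_point`, `strain_pct`,
#'   `depth_pct` (layer center, 0 = surface), `mean_density_pct`,
#'   `sd_density_pct`, `n_subvolumes`.
#' @export
profile_series <- function(profiles_by_time, strain_pct = NULL) {
  if (length(profiles_by_time) == 0L) stop("no time points supplied")
  n_layers <- profiles_by_time[[1]][[1]]$n_layers
  all_n <- unlist(lapply(profiles_by_time, function(ps)
    vapply(ps, function(p) p$n_layers, integer(1))))
  if (any(all_n != n_layers)) stop("mismatched layer counts across profiles")
  if (is.null(strain_pct)) strain_pct <- rep(NA_real_,
                                             length(profiles_by_time))
  nm <- names(profiles_by_time)
  if (is.null(nm)) nm <- as.character(seq_along(profiles_by_time))
  rows <- list()
  for (t in seq_along(profiles_by_time)) {
    mat <- vapply(profiles_by_time[[t]],
                  function(p) p$layer_fraction_pct, numeric(n_layers))
    mat <- matrix(mat, nrow = n_layers)
    rows[[t]] <- data.frame(
      time_point = nm[t],
      strain_pct = strain_pct[t],
      depth_pct = (seq_len(n_layers) - 0.5) / n_layers * 100,
      mean_density_pct = rowMeans(mat),
      sd_density_pct = apply(mat, 1, stats::sd),
      n_subvolumes = ncol(mat))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
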