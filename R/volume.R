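#' Construct a 3D grayscale volume
#'
#' The basic container for reconstructed tomographic data. The axis order is
#' fixed as (z, y, x) with z the loading/depth axis: `data[i, j, k]` addresses
#' depth slice `i`, row `j` (y), column `k` (x). All angle conventions
#' downstream reference this order. Indices are 0-free R indices; crop
#' regions use half-open intervals in 0-based voxel coordinates.
#'
#' @param data 3D numeric array, axes (z, y, x).
#' @param voxel_size_um isotropic voxel edge length in micrometres
#'   (default 2.75, the acquisition pixel size).
#' @param mask optional logical array, same shape, marking tissue voxels.
#' @return An object of class `Volume3D`.
#' @export
volume3d <- function(data, voxel_size_um = 2.75, mask = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0) {
    stop("`voxel_size_um` must be a positive scalar")
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data))) {
      stop("`mask` must have the same shape as `data`")
    }
    storage.mode(mask) <- "logical"
  }
  structure(
    list(data = data, voxel_size_um = voxel_size_um, mask = mask),
    class = "Volume3D"
  )
}

#' @export
print.Volume3D <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Volume3D: %d x %d x %d voxels (z,y,x), %.3g um/voxel (%.3g x %.3g x %.3g mm)\n",
    d[1], d[2], d[3], x$voxel_size_um,
    d[1] * x$voxel_size_um / 1000, d[2] * x$voxel_size_um / 1000,
    d[3] * x$voxel_size_um / 1000))
  cat(sprintf("  intensity range [%.4g, %.4g]%s\n",
              min(x$data), max(x$data),
              if (is.null(x$mask)) "" else
                sprintf(", mask covers %.1f%%", 100 * mean(x$mask))))
  invisible(x)
}

#' @export
dim.Volume3D <- function(x) dim(x$data)

#' Convert micrometres to whole voxels
#'
#' Rounds to the nearest integer voxel count; e.g. 500 um at 2.75 um/voxel
#' gives 182 voxels.
#'
#' @param um length in micrometres.
#' @param voxel_size_um voxel edge length in micrometres.
#' @return integer voxel count.
#' @export
um_to_vox <- function(um, voxel_size_um = 2.75) {
  as.integer(round(um / voxel_size_um))
}

#' Read a volume from a TIFF stack
#'
#' Accepts either a directory of single-slice TIFF files (stacked along z in
#' filename-sorted order) or a single multi-page TIFF. Intensities are kept
#' as stored; no rescaling is applied.
#'
#' @param path directory of 2D TIFF slices, or one multi-page TIFF file.
#' @param voxel_size_um voxel size in micrometres.
#' @return A [volume3d()] object.
#' @export
read_volume_stack <- function(path, voxel_size_um = 2.75) {
  # 8/16-bit integer pages are rescaled back to raw integer values;
  # 32-bit pages are IEEE float and used as read.
  restore_units <- function(s) {
    bits <- attr(s, "bits.per.sample")
    if (length(dim(s)) == 3L) s <- s[, , 1] # drop spurious channels
    if (!is.null(bits) && bits %in% c(8L, 16L)) {
      s <- round(s * (2^bits - 1))
    }
    s
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in ", path)
    slices <- lapply(files, function(f)
      restore_units(tiff::readTIFF(f, info = TRUE)))
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    slices <- lapply(pages, restore_units)
  } else {
    stop("path not found: ", path)
  }
  shp <- dim(slices[[1]])
  ok <- vapply(slices, function(s) identical(dim(s), shp), logical(1))
  if (!all(ok)) stop("inconsistent slice shapes in ", path)
  data <- array(0, dim = c(length(slices), shp[1], shp[2]))
  for (i in seq_along(slices)) data[i, , ] <- slices[[i]]
  sidecar <- paste0(path, ".scale")
  if (!dir.exists(path) && file.exists(sidecar)) {
    sc <- read.table(sidecar, row.names = 1)
    data <- data * sc["slope", 1] + sc["intercept", 1]
  }
  volume3d(data, voxel_size_um = voxel_size_um)
}

#' Write a volume as a multi-page 32-bit float TIFF
#'
#' Inverse of [read_volume_stack()]: slice `i` along z becomes page `i`.
#' Data are written as 32-bit float. TIFF float storage covers [0, 1];
#' volumes with intensities outside that range are affinely rescaled and
#' the transform is recorded in a plain-text sidecar file
#' (`<path>.scale`), which [read_volume_stack()] uses to restore the
#' original intensities.
#'
#' @param vol a [volume3d()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_stack <- function(vol, path) {
  stopifnot(inherits(vol, "Volume3D"))
  d <- dim(vol$data)
  x <- vol$data
  rng <- range(x)
  sidecar <- paste0(path, ".scale")
  if (rng[1] < 0 || rng[2] > 1) {
    slope <- if (diff(rng) > 0) diff(rng) else 1
    x <- (x - rng[1]) / slope # stored = (orig - intercept) / slope
    writeLines(sprintf("slope %.17g\nintercept %.17g", slope, rng[1]),
               sidecar)
  } else if (file.exists(sidecar)) {
    unlink(sidecar)
  }
  pages <- lapply(seq_len(d[1]), function(i) x[i, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Crop full-depth analysis subvolumes
#'
#' Crops `count` subvolumes that span the full z (depth) extent with a square
#' lateral footprint of `lateral_size_um` per side (default 500 um, i.e. 182
#' voxels at 2.75 um/voxel). Lateral placement is uniform-random
#' non-overlapping rejection sampling, deterministic under `seed`; if
#' non-overlapping placement fails within the retry budget the function
#' falls back to overlapping placement with a warning.
#'
#' @param vol a [volume3d()] object.
#' @param lateral_size_um lateral footprint edge length in micrometres.
#' @param count number of subvolumes (default 5 per tomogram).
#' @param seed integer seed controlling placement.
#' @param margin_vox keep-out margin from the lateral volume borders.
#' @return An object of class `SubvolumeSet`: list with `regions` (each a
#'   3x2 matrix of 0-based half-open (z, y, x) intervals) and `volumes`
#'   (list of `Volume3D`).
#' @export
crop_full_depth_subvolumes <- function(vol, lateral_size_um = 500,
                                       count = 5L, seed = 1L,
                                       margin_vox = 0L) {
  stopifnot(inherits(vol, "Volume3D"))
  d <- dim(vol$data)
  side <- um_to_vox(lateral_size_um, vol$voxel_size_um)
  if (side > d[2] - 2 * margin_vox || side > d[3] - 2 * margin_vox) {
    stop("lateral size (", side, " voxels) exceeds the volume extent")
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)

  ymax <- d[2] - side - margin_vox
  xmax <- d[3] - side - margin_vox
  placed <- matrix(numeric(0), ncol = 2) # y0, x0
  budget <- 2000L
  overlapping_fallback <- FALSE
  while (nrow(placed) < count && budget > 0L) {
    y0 <- if (ymax > margin_vox) sample(margin_vox:ymax, 1L) else margin_vox
    x0 <- if (xmax > margin_vox) sample(margin_vox:xmax, 1L) else margin_vox
    clash <- FALSE
    if (!overlapping_fallback && nrow(placed) > 0) {
      clash <- any(abs(placed[, 1] - y0) < side & abs(placed[, 2] - x0) < side)
    }
    if (!clash) placed <- rbind(placed, c(y0, x0))
    budget <- budget - 1L
    if (budget == 0L && nrow(placed) < count && !overlapping_fallback) {
      warning("cannot place ", count, " non-overlapping subvolumes; ",
              "falling back to overlapping placement")
      overlapping_fallback <- TRUE
      budget <- 2000L
    }
  }
  if (nrow(placed) < count) stop("subvolume placement failed")

  regions <- lapply(seq_len(count), function(i) {
    y0 <- placed[i, 1]; x0 <- placed[i, 2]
    m <- rbind(z = c(0, d[1]), y = c(y0, y0 + side), x = c(x0, x0 + side))
    colnames(m) <- c("from", "to")
    m
  })
  volumes <- lapply(regions, function(r) crop_region(vol, r))
  structure(list(regions = regions, volumes = volumes,
                 lateral_size_vox = side, seed = seed),
            class = "SubvolumeSet")
}

#' Extract a region from a volume
#'
#' @param vol a [volume3d()] object.
#' @param region 3x2 matrix of 0-based half-open (z, y, x) intervals.
#' @return A `Volume3D` crop (mask cropped alongside when present).
#' @export
crop_region <- function(vol, region) {
  stopifnot(inherits(vol, "Volume3D"))
  d <- dim(vol$data)
  if (any(region[, 1] < 0) || any(region[, 2] > d) ||
      any(region[, 2] <= region[, 1])) {
    stop("region exceeds parent volume bounds")
  }
  iz <- (region[1, 1] + 1):region[1, 2]
  iy <- (region[2, 1] + 1):region[2, 2]
  ix <- (region[3, 1] + 1):region[3, 2]
  m <- if (is.null(vol$mask)) NULL else vol$mask[iz, iy, ix, drop = FALSE]
  volume3d(vol$data[iz, iy, ix, drop = FALSE], vol$voxel_size_um, m)
}

# Preserve the caller's RNG state around seeded internals.
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
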