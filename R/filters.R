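#' Separable 3D Gaussian smoothing
#'
#' Convolves a 3D array with a sampled Gaussian kernel along each axis,
#' symmetric (mirror) boundary handling. The kernel is truncated at
#' `4 * sigma` and renormalized to unit sum.
#'
#' @param x 3D numeric array.
#' @param sigma standard deviation in voxels; 0 returns `x` unchanged.
#' @return smoothed array, same shape.
#' @export
gaussian_smooth3d <- function(x, sigma) {
  if (sigma == 0) return(x)
  stopifnot(length(dim(x)) == 3L, sigma > 0)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  for (ax in 1:3) x <- .conv_axis3d(x, k, ax)
  x
}

# 3D Sobel gradient. Returns list(gx, gy, gz) where x is the third array
# axis, y the second, z the first. Separable: central difference along the
# derivative axis, [1 2 1]/4 smoothing along the two others.
sobel_gradient3d <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  d <- c(-1, 0, 1) / 2
  s <- c(1, 2, 1) / 4
  gz <- .conv_axis3d(.conv_axis3d(.conv_axis3d(x, d, 1L), s, 2L), s, 3L)
  gy <- .conv_axis3d(.conv_axis3d(.conv_axis3d(x, s, 1L), d, 2L), s, 3L)
  gx <- .conv_axis3d(.conv_axis3d(.conv_axis3d(x, s, 1L), s, 2L), d, 3L)
  list(gx = gx, gy = gy, gz = gz)
}

# Binary morphological erosion/dilation/opening. `se = "cross"` uses the
# 6-connected cross (the minimal 3D structuring element, least erosive on
# small rounded objects); `se = "box"` uses the separable (2r+1)^3 cube.
binary_erode3d <- function(mask, radius = 1L, se = c("cross", "box")) {
  se <- match.arg(se)
  x <- array(as.numeric(mask), dim = dim(mask))
  if (se == "box") {
    for (ax in 1:3) x <- .minmax_axis3d(x, radius, ax, FALSE)
  } else {
    for (r in seq_len(radius)) {
      acc <- x
      for (ax in 1:3) acc <- pmin(acc, .minmax_axis3d(x, 1L, ax, FALSE))
      x <- acc
    }
  }
  array(x > 0.5, dim = dim(mask))
}
binary_dilate3d <- function(mask, radius = 1L, se = c("cross", "box")) {
  se <- match.arg(se)
  x <- array(as.numeric(mask), dim = dim(mask))
  if (se == "box") {
    for (ax in 1:3) x <- .minmax_axis3d(x, radius, ax, TRUE)
  } else {
    for (r in seq_len(radius)) {
      acc <- x
      for (ax in 1:3) acc <- pmax(acc, .minmax_axis3d(x, 1L, ax, TRUE))
      x <- acc
    }
  }
  array(x > 0.5, dim = dim(mask))
}
binary_open3d <- function(mask, radius = 1L, se = c("cross", "box")) {
  se <- match.arg(se)
  binary_dilate3d(binary_erode3d(mask, radius, se), radius, se)
}

# Connected-component labeling (6-connectivity); returns an integer array
# with attribute "n_components".
label_components <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  .label_components3d(mask)
}

# Otsu threshold on a numeric vector (256-bin histogram): maximizes
# between-class variance. Used by the deterministic chondrocyte segmenter.
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  centers[which.max(sigma_b2)]
}
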