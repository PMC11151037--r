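# Shared fixtures and independent oracles used across the suite.

dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Circular median distance to a reference azimuth on the 180-degree
# (axial) circle.
axial_diff_deg <- function(angle_deg, ref_deg) {
  d <- (angle_deg - ref_deg) %% 180
  pmin(d, 180 - d)
}

# Band-limited white-noise volume with a hard isotropic frequency cutoff
# (cycles/pixel) plus a small additive noise floor; the constructed-cutoff
# oracle for the resolution estimator.
make_bandlimited_volume <- function(dims, cutoff, noise_sd = 0.02) {
  x <- array(rnorm(prod(dims)), dim = dims)
  Fx <- fft(x)
  ff <- function(n) { k <- 0:(n - 1); ifelse(k <= n / 2, k / n, k / n - 1) }
  fmag <- sqrt(outer(outer(ff(dims[1])^2, ff(dims[2])^2, `+`),
                     ff(dims[3])^2, `+`))
  Fx[fmag > cutoff] <- 0
  y <- Re(fft(Fx, inverse = TRUE)) / prod(dims)
  y <- y / sd(y)
  y + array(rnorm(prod(dims), 0, noise_sd), dim = dims)
}

# Anti-aliased solid cylinder along z: bright inside `radius_vox` of the
# (y0, x0) axis, on a zero background. Used as the barrel phantom for the
# lateral-strain (Poisson) oracle.
make_cylinder_volume <- function(dims, radius_vox,
                                 center = (dims[2:3] + 1) / 2) {
  dy <- (seq_len(dims[2]) - center[1])
  dx <- (seq_len(dims[3]) - center[2])
  r2d <- sqrt(outer(dy^2, dx^2, `+`))
  sl <- pmin(1, pmax(0, radius_vox + 0.5 - r2d))
  data <- array(0, dim = dims)
  for (i in seq_len(dims[1])) data[i, , ] <- sl
  volume3d(data)
}

# Mode (bin center of the maximum) of a vector of angles with 1-degree
# binning on the given support.
modal_angle <- function(angles_deg, lo, hi) {
  edges <- seq(lo, hi, by = 1)
  b <- findInterval(angles_deg, edges, rightmost.closed = TRUE,
                    all.inside = TRUE)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  centers[which.max(tabulate(b, nbins = length(centers)))]
}
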