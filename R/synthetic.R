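#' Angle distributions for phantom fibers
#'
#' Helper constructors for the azimuth/elevation distributions accepted by
#' [gen_fiber_phantom()]. Angles are in degrees; azimuth lives on [0, 180)
#' (axial data), elevation on [-90, 90].
#'
#' `angle_delta()` concentrates all fibers at one angle. `angle_uniform()`
#' is flat on the support. `angle_isotropic()` (elevation only) draws the
#' elevation with the spherical area-element weight, i.e. density
#' proportional to cos(theta); combined with a uniform azimuth this yields
#' fiber axes uniform on the projective sphere. `angle_normal()` is a
#' wrapped/clipped normal (von-Mises-like) around a mean.
#'
#' @param value_deg,mean_deg,sd_deg parameters in degrees.
#' @return a distribution description (list) consumed by the generators.
#' @name angle_distributions
NULL

#' @rdname angle_distributions
#' @export
angle_delta <- function(value_deg) list(kind = "delta", value = value_deg)

#' @rdname angle_distributions
#' @export
angle_uniform <- function() list(kind = "uniform")

#' @rdname angle_distributions
#' @export
angle_isotropic <- function() list(kind = "isotropic")

#' @rdname angle_distributions
#' @export
angle_normal <- function(mean_deg, sd_deg) {
  list(kind = "normal", mean = mean_deg, sd = sd_deg)
}

# Sample n angles from a distribution description on the given support.
sample_angles <- function(n, dist, support = c("azimuth", "elevation")) {
  support <- match.arg(support)
  switch(dist$kind,
    delta = rep(dist$value, n),
    uniform = if (support == "azimuth") runif(n, 0, 180)
              else runif(n, -90, 90),
    isotropic = {
      if (support == "azimuth") stop("isotropic applies to elevation only")
      asin(runif(n, -1, 1)) * 180 / pi # density proportional to cos(theta)
    },
    normal = {
      a <- rnorm(n, dist$mean, dist$sd)
      if (support == "azimuth") a %% 180 else pmax(-90, pmin(90, a))
    },
    stop("unknown distribution kind: ", dist$kind)
  )
}

# (azimuth, elevation) in degrees -> unit direction (x, y, z).
angles_to_direction <- function(azimuth_deg, elevation_deg) {
  phi <- azimuth_deg * pi / 180
  theta <- elevation_deg * pi / 180
  cbind(x = cos(theta) * cos(phi),
        y = cos(theta) * sin(phi),
        z = sin(theta))
}

#' Generate a fiber phantom volume
#'
#' Emulates the appearance of meniscus tissue in phase-contrast micro-CT:
#' bright straight collagen-like fibers on a darker matrix plus additive
#' Gaussian noise. Fibers are rasterized from anti-aliased cylinder
#' distance fields (coverage ramps linearly over one voxel at the surface),
#' which avoids stair-step bias in downstream orientation estimates. The
#' per-fiber ground-truth angles are returned alongside and must never be
#' consumed by an analysis stage.
#'
#' @param shape voxel dimensions (z, y, x).
#' @param n_fibers number of fibers.
#' @param fiber_radius_um fiber radius range in micrometres (length 2).
#' @param azimuth,elevation angle distributions (see
#'   [angle_distributions]).
#' @param fiber_intensity,matrix_intensity gray values of fiber and matrix.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param voxel_size_um voxel size in micrometres.
#' @param seed integer seed; generation is bit-reproducible.
#' @return list with `volume` (a [volume3d()]), `truth` (data.frame of
#'   per-fiber azimuth/elevation/radius) and `coverage` (the noise-free
#'   fiber coverage array in [0,1]).
#' @export
gen_fiber_phantom <- function(shape = c(128, 128, 128),
                              n_fibers = 40,
                              fiber_radius_um = c(8, 8),
                              azimuth = angle_uniform(),
                              elevation = angle_isotropic(),
                              fiber_intensity = 1,
                              matrix_intensity = 0.2,
                              noise_sd = 0.05,
                              voxel_size_um = 2.75,
                              seed = 1L) {
  if (n_fibers < 1) stop("at least one fiber is required")
  if (fiber_intensity == matrix_intensity) {
    stop("fiber and matrix intensity must differ")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)

  radius_vox <- runif(n_fibers, fiber_radius_um[1], fiber_radius_um[2]) /
    voxel_size_um
  if (any(radius_vox < 1)) {
    warning("fiber radius below one voxel: sub-resolution fibers")
  }
  az <- sample_angles(n_fibers, azimuth, "azimuth")
  el <- sample_angles(n_fibers, elevation, "elevation")
  u <- angles_to_direction(az, el)
  # each fiber axis passes through a uniform random point of the volume,
  # coordinates (x, y, z) 0-based
  p0 <- cbind(runif(n_fibers, 0, shape[3] - 1),
              runif(n_fibers, 0, shape[2] - 1),
              runif(n_fibers, 0, shape[1] - 1))
  cov <- .raster_cylinders(as.integer(shape), p0, u, radius_vox)
  data <- matrix_intensity + (fiber_intensity - matrix_intensity) * cov
  if (noise_sd > 0) {
    data <- data + array(rnorm(length(data), 0, noise_sd), dim = shape)
  }
  truth <- data.frame(fiber = seq_len(n_fibers),
                      azimuth_deg = az, elevation_deg = el,
                      radius_vox = radius_vox,
                      x0 = p0[, 1], y0 = p0[, 2], z0 = p0[, 3])
  list(volume = volume3d(data, voxel_size_um, mask = cov > 0.5),
       truth = truth, coverage = cov)
}

#' Generate a cellular cartilage phantom volume
#'
#' Emulates articular cartilage in phase-contrast micro-CT: dark (or
#' bright) ellipsoidal chondrocyte-like inclusions in a brighter matrix,
#' with a prescribed per-layer volume-percentage across 10 equal depth
#' layers and depth-dependent cell shape (flattened near the articular
#' surface at z = 0, rounder in the deep zone). Cells are placed fully
#' inside their layer by rejection sampling with an overlap budget; the
#' realized label-mask density per layer lands within one percentage point
#' of the target.
#'
#' @param shape voxel dimensions (z, y, x).
#' @param depth_density_profile 10 target volume percentages, surface first.
#' @param cell_axes_surface_um,cell_axes_deep_um ellipsoid semi-axes
#'   (z, y, x) in micrometres at the surface and at full depth; linearly
#'   interpolated with depth.
#' @param cell_intensity,matrix_intensity gray values.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param voxel_size_um voxel size in micrometres.
#' @param seed integer seed.
#' @param max_attempts placement retry budget per cell.
#' @return list with `volume` (a [volume3d()] whose mask is all-tissue) and
#'   `label` (logical ground-truth cell mask).
#' @export
gen_cartilage_phantom <- function(shape = c(200, 120, 120),
                                  depth_density_profile = rep(5, 10),
                                  cell_axes_surface_um = c(5, 12, 12),
                                  cell_axes_deep_um = c(12, 9, 9),
                                  cell_intensity = 0.25,
                                  matrix_intensity = 0.65,
                                  noise_sd = 0.05,
                                  voxel_size_um = 2.75,
                                  seed = 1L,
                                  max_attempts = 5000L) {
  n_layers <- length(depth_density_profile)
  if (any(depth_density_profile < 0 | depth_density_profile > 30)) {
    stop("target densities must lie in [0, 30] percent")
  }
  if (cell_intensity == matrix_intensity) {
    stop("cell and matrix intensity must differ")
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)

  label <- array(FALSE, dim = shape)
  bounds <- round(seq(0, shape[1], length.out = n_layers + 1))
  ax_surf <- cell_axes_surface_um / voxel_size_um
  ax_deep <- cell_axes_deep_um / voxel_size_um

  for (l in seq_len(n_layers)) {
    z0 <- bounds[l] + 1L; z1 <- bounds[l + 1]
    layer_vox <- (z1 - z0 + 1L) * shape[2] * shape[3]
    target <- depth_density_profile[l] / 100
    if (target == 0) next
    placed_vox <- 0L
    attempts <- 0L
    while (placed_vox / layer_vox < target - 0.001) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("cell placement budget exhausted in layer ", l,
             " (infeasible density?)")
      }
      depth_frac <- (l - 0.5) / n_layers
      ax <- ax_surf + depth_frac * (ax_deep - ax_surf) # (z, y, x) semi-axes
      cz <- runif(1, z0 + ax[1], z1 - ax[1])
      if (cz <= z0 || cz >= z1) next # layer thinner than the cell
      cy <- runif(1, 1 + ax[2], shape[2] - ax[2])
      cx <- runif(1, 1 + ax[3], shape[3] - ax[3])
      gap <- 1 # clearance so neighboring cells never 6-connect
      iz <- max(1, floor(cz - ax[1] - gap)):min(shape[1],
                                                ceiling(cz + ax[1] + gap))
      iy <- max(1, floor(cy - ax[2] - gap)):min(shape[2],
                                                ceiling(cy + ax[2] + gap))
      ix <- max(1, floor(cx - ax[3] - gap)):min(shape[3],
                                                ceiling(cx + ax[3] + gap))
      dz2 <- ((iz - cz) / ax[1])^2
      dy2 <- ((iy - cy) / ax[2])^2
      dx2 <- ((ix - cx) / ax[3])^2
      inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
      cz2 <- ((iz - cz) / (ax[1] + gap))^2
      cy2 <- ((iy - cy) / (ax[2] + gap))^2
      cx2 <- ((ix - cx) / (ax[3] + gap))^2
      clearance <- outer(outer(cz2, cy2, `+`), cx2, `+`) <= 1
      sub <- label[iz, iy, ix, drop = FALSE]
      if (any(sub & clearance)) next # would overlap or touch a cell
      label[iz, iy, ix] <- sub | inside
      placed_vox <- placed_vox + sum(inside)
    }
  }

  data <- array(matrix_intensity, dim = shape)
  data[label] <- cell_intensity
  if (noise_sd > 0) {
    data <- data + array(rnorm(length(data), 0, noise_sd), dim = shape)
  }
  list(volume = volume3d(data, voxel_size_um,
                         mask = array(TRUE, dim = shape)),
       label = label)
}

#' Standard-linear-solid parameters
#'
#' The SLS (Zener) model is the simplest viscoelastic solid with distinct
#' instantaneous and equilibrium moduli, making recovery of both analytic.
#'
#' @param E0_MPa instantaneous modulus (MPa).
#' @param Einf_MPa equilibrium modulus (MPa); requires `E0 >= Einf > 0`.
#' @param tau_s relaxation time constant (s).
#' @param noise_sd_N standard deviation of additive force noise (N).
#' @return An object of class `SLSParams`.
#' @export
sls_params <- function(E0_MPa, Einf_MPa, tau_s, noise_sd_N = 0) {
  if (!(E0_MPa >= Einf_MPa && Einf_MPa > 0)) stop("need E0 >= Einf > 0")
  if (tau_s <= 0) stop("tau must be positive")
  structure(list(E0_MPa = E0_MPa, Einf_MPa = Einf_MPa, tau_s = tau_s,
                 noise_sd_N = noise_sd_N), class = "SLSParams")
}

#' Closed-form SLS stress responses
#'
#' For a step strain `eps0` applied at t = 0:
#' `sigma(t) = eps0 * (Einf + (E0 - Einf) * exp(-t / tau))`.
#' For a ramp at strain rate `r` (fraction/s) from t = 0:
#' `sigma(t) = r * (Einf * t + (E0 - Einf) * tau * (1 - exp(-t / tau)))`.
#'
#' @param t_s time since the step/ramp start (s).
#' @param eps0 step strain (fraction).
#' @param rate strain rate (fraction per second).
#' @param params an [sls_params()] object.
#' @return stress in MPa.
#' @name sls_closed_forms
NULL

#' @rdname sls_closed_forms
#' @export
sls_step_stress <- function(t_s, eps0, params) {
  eps0 * (params$Einf_MPa +
            (params$E0_MPa - params$Einf_MPa) * exp(-t_s / params$tau_s))
}

#' @rdname sls_closed_forms
#' @export
sls_ramp_stress <- function(t_s, rate, params) {
  rate * (params$Einf_MPa * t_s +
            (params$E0_MPa - params$Einf_MPa) * params$tau_s *
              (1 - exp(-t_s / params$tau_s)))
}

#' Simulate a rheometer loading record from an SLS material
#'
#' Builds the strain history of a [protocol_spec()] (CL ramp, or StR ramps
#' and holds) sampled at `dt` and integrates the standard-linear-solid
#' response exactly: with `sigma = Einf * eps + q`, the overstress `q`
#' obeys `dq/dt = -q/tau + (E0 - Einf) * deps/dt`, which has an exact
#' exponential update over each constant-rate interval (no discretization
#' error beyond the sampling grid itself). Stress is converted to force via
#' the sample cross-section and Gaussian force noise is added.
#'
#' @param protocol a [protocol_spec()].
#' @param params an [sls_params()] object.
#' @param sample_height_mm post-preload sample height (mm).
#' @param sample_diameter_mm sample diameter (mm, default 4).
#' @param dt sampling interval (s).
#' @param seed integer seed for the force noise.
#' @return A [loading_record()] with the protocol attached; the generating
#'   parameters are stored in attribute `"truth"`.
#' @export
gen_loading_curve <- function(protocol, params, sample_height_mm = 2,
                              sample_diameter_mm = 4, dt = 0.1, seed = 1L) {
  stopifnot(inherits(protocol, "ProtocolSpec"), inherits(params, "SLSParams"))
  if (any(protocol$target_strains_pct < 0)) stop("negative strain target")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)

  tim <- protocol_timings(protocol)
  t_total <- tim$t_end[nrow(tim)]
  tt <- seq(0, t_total, by = dt)
  rate_pct <- protocol$strain_rate_pct_per_s
  # strain (fraction) at each sample: piecewise linear ramps + holds
  eps <- numeric(length(tt))
  for (k in seq_len(nrow(tim))) {
    prev <- if (k == 1) 0 else tim$strain_pct[k - 1] / 100
    ramp <- tt >= tim$t_start[k] & tt < tim$t_peak[k]
    hold <- tt >= tim$t_peak[k] & tt <= tim$t_end[k]
    eps[ramp] <- prev + (tt[ramp] - tim$t_start[k]) * rate_pct / 100
    eps[hold] <- tim$strain_pct[k] / 100
  }
  # exact exponential update of the overstress per sampling interval
  q <- numeric(length(tt))
  dE <- params$E0_MPa - params$Einf_MPa
  for (i in seq_along(tt)[-1]) {
    h <- tt[i] - tt[i - 1]
    r <- (eps[i] - eps[i - 1]) / h
    decay <- exp(-h / params$tau_s)
    q[i] <- q[i - 1] * decay + dE * r * params$tau_s * (1 - decay)
  }
  stress <- params$Einf_MPa * eps + q
  area_mm2 <- pi * (sample_diameter_mm / 2)^2
  force <- stress * area_mm2
  if (params$noise_sd_N > 0) {
    force <- force + rnorm(length(force), 0, params$noise_sd_N)
  }
  rec <- loading_record(tt, force, eps * sample_height_mm,
                        sample_diameter_mm = sample_diameter_mm,
                        sample_height_mm = sample_height_mm,
                        protocol = protocol)
  attr(rec, "truth") <- params
  rec
}

#' Generate a repeated-scan pair
#'
#' Emulates removing a sample from the rheometer, replacing it and
#' re-scanning: the second volume is the first rigidly translated by an
#' integer voxel shift (circular/toroidal shift, so no content is lost),
#' and each volume receives an independent Gaussian noise realization.
#'
#' @param vol a noise-free [volume3d()] (e.g. a phantom volume).
#' @param shift_vox integer (z, y, x) translation of the second scan.
#' @param noise_sd standard deviation of the independent additive noise.
#' @param seed integer seed.
#' @return list of two `Volume3D` objects `a` and `b`.
#' @export
gen_repeat_pair <- function(vol, shift_vox = c(0, 0, 0), noise_sd = 0,
                            seed = 1L) {
  stopifnot(inherits(vol, "Volume3D"))
  d <- dim(vol$data)
  if (any(abs(shift_vox) >= d / 2)) {
    stop("shift must be smaller than half the volume extent")
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  shifted <- circular_shift3d(vol$data, shift_vox)
  a <- vol$data; b <- shifted
  if (noise_sd > 0) {
    a <- a + array(rnorm(length(a), 0, noise_sd), dim = d)
    b <- b + array(rnorm(length(b), 0, noise_sd), dim = d)
  }
  list(a = volume3d(a, vol$voxel_size_um),
       b = volume3d(b, vol$voxel_size_um))
}

# Integer circular shift of a 3D array: element (i) moves to (i + shift).
circular_shift3d <- function(x, shift_vox) {
  d <- dim(x)
  idx <- lapply(1:3, function(ax) {
    s <- shift_vox[ax] %% d[ax]
    if (s == 0) seq_len(d[ax]) else c((d[ax] - s + 1):d[ax], 1:(d[ax] - s))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
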