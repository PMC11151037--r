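test_that("axis-aligned fiber phantoms are constant along their axis", {
  # azimuth 0, elevation 0: fibers parallel to +x (third array axis)
  ph <- gen_fiber_phantom(shape = c(24, 24, 24), n_fibers = 4,
                          azimuth = angle_delta(0),
                          elevation = angle_delta(0),
                          noise_sd = 0, seed = 2)
  cov <- ph$coverage
  for (k in 2:24) expect_equal(cov[, , k], cov[, , 1])
  expect_true(all(ph$truth$azimuth_deg == 0 & ph$truth$elevation_deg == 0))

  # azimuth 90: fibers parallel to +y (second array axis)
  ph90 <- gen_fiber_phantom(shape = c(24, 24, 24), n_fibers = 4,
                            azimuth = angle_delta(90),
                            elevation = angle_delta(0),
                            noise_sd = 0, seed = 2)
  for (j in 2:24) expect_equal(ph90$coverage[, j, ], ph90$coverage[, 1, ])
})

test_that("isotropic fiber directions have cos-weighted elevations", {
  ph <- gen_fiber_phantom(shape = c(16, 16, 16), n_fibers = 400,
                          fiber_radius_um = c(4, 4),
                          azimuth = angle_uniform(),
                          elevation = angle_isotropic(),
                          noise_sd = 0, seed = 11)
  # area element: sin(theta) uniform on [-1, 1] exactly when the elevation
  # density is proportional to cos(theta)
  ks <- suppressWarnings(
    ks.test(sin(ph$truth$elevation_deg * pi / 180), "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  # azimuths flat on [0, 180)
  ks2 <- suppressWarnings(ks.test(ph$truth$azimuth_deg, "punif", 0, 180))
  expect_gt(ks2$p.value, 0.01)
})

test_that("fiber phantom generation is bit-reproducible and validates inputs", {
  a <- gen_fiber_phantom(shape = c(16, 16, 16), n_fibers = 5, seed = 3)
  b <- gen_fiber_phantom(shape = c(16, 16, 16), n_fibers = 5, seed = 3)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth, b$truth)
  expect_error(gen_fiber_phantom(n_fibers = 0), "at least one")
  expect_error(gen_fiber_phantom(fiber_intensity = 0.5,
                                 matrix_intensity = 0.5), "differ")
  expect_warning(gen_fiber_phantom(shape = c(16, 16, 16), n_fibers = 2,
                                   fiber_radius_um = c(1, 1), seed = 1),
                 "sub-resolution")
})

test_that("cartilage phantom hits per-layer density targets", {
  flat <- gen_cartilage_phantom(shape = c(120, 80, 80),
                                depth_density_profile = rep(5, 10),
                                seed = 4)
  prof <- layer_density_profile(flat$label, flat$volume$mask)
  expect_true(all(abs(prof$layer_fraction_pct - 5) <= 1))

  empty <- gen_cartilage_phantom(shape = c(60, 40, 40),
                                 depth_density_profile = rep(0, 10),
                                 seed = 4)
  expect_false(any(empty$label))

  lin <- gen_cartilage_phantom(shape = c(150, 90, 90),
                               depth_density_profile =
                                 seq(2, 12, length.out = 10), seed = 5)
  lp <- layer_density_profile(lin$label, lin$volume$mask)
  expect_false(is.unsorted(lp$layer_fraction_pct))
  expect_error(gen_cartilage_phantom(depth_density_profile = rep(40, 10)),
               "\\[0, 30\\]")
})

test_that("SLS closed forms match their limits and an ODE oracle", {
  p <- sls_params(2, 1, 30)
  # step: sigma(0+) = eps0 * E0, sigma(inf) = eps0 * Einf
  expect_equal(sls_step_stress(0, 0.15, p), 0.30)
  expect_equal(sls_step_stress(1e6, 0.15, p), 0.15)
  # ramp slope tends to Einf at t >> tau
  r <- 0.01
  slope <- (sls_ramp_stress(2000, r, p) - sls_ramp_stress(1990, r, p)) /
    (r * 10)
  expect_equal(slope, 1, tolerance = 1e-8)
  # ramp formula against numerical integration of the overstress ODE
  skip_if_not_installed("deSolve")
  ode_fn <- function(t, y, parms) {
    list(-y / parms$tau + (parms$E0 - parms$Einf) * parms$rate)
  }
  tt <- seq(0, 120, by = 0.5)
  sol <- deSolve::lsoda(c(q = 0), tt, ode_fn,
                        parms = list(tau = 30, E0 = 2, Einf = 1, rate = r),
                        rtol = 1e-10, atol = 1e-12)
  sigma_ode <- p$Einf_MPa * r * tt + sol[, "q"]
  expect_lt(max(abs(sigma_ode - sls_ramp_stress(tt, r, p))), 1e-6)
})

test_that("simulated CL loading curves equal the closed-form ramp response", {
  p <- sls_params(2, 1, 30)
  prot <- protocol_spec("CL") # 0.03 %/s to 15%
  rec <- gen_loading_curve(prot, p, sample_height_mm = 2, dt = 0.5, seed = 1)
  rec <- to_stress_strain(rec)
  expected <- sls_ramp_stress(rec$time_s, 0.0003, p)
  expect_lt(max(abs(rec$stress_MPa - expected)), 1e-9)
})

test_that("repeated-scan pairs behave as constructed", {
  ph <- gen_fiber_phantom(shape = c(32, 32, 32), n_fibers = 8,
                          noise_sd = 0, seed = 6)
  same <- gen_repeat_pair(ph$volume, c(0, 0, 0), noise_sd = 0, seed = 1)
  expect_identical(same$a$data, same$b$data)

  pair <- gen_repeat_pair(ph$volume, c(3, -2, 1), noise_sd = 0, seed = 1)
  reg <- rigid_register_translation(pair$a, pair$b)
  expect_equal(reg$shift_vox, c(3L, -2L, 1L))

  noisy <- gen_repeat_pair(ph$volume, c(0, 0, 0), noise_sd = 0.1, seed = 2)
  # difference is zero-mean noise: |mean| within 4 standard errors
  se <- 0.1 * sqrt(2) / sqrt(length(noisy$a$data))
  expect_lt(abs(mean(noisy$a$data - noisy$b$data)), 4 * se)
  expect_gt(sd(noisy$a$data - noisy$b$data), 0.1) # independent realizations

  expect_error(gen_repeat_pair(ph$volume, c(20, 0, 0)), "half the volume")
})
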