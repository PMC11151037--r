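test_that("stress-strain conversion uses the 4 mm constant-diameter area", {
  rec <- loading_record(0:2, c(0, 6.2832, 12.566371), c(0, 0.15, 0.30),
                        sample_height_mm = 2)
  rec <- to_stress_strain(rec)
  expect_equal(rec$stress_MPa[3], 1.0, tolerance = 1e-6) # pi * 2^2 mm^2
  expect_equal(rec$stress_MPa[1], 0)
  expect_equal(rec$strain_frac, c(0, 0.075, 0.15))
  bad <- loading_record(0:2, 1:3, 1:3, sample_height_mm = -1)
  expect_error(to_stress_strain(bad), "height")
})

test_that("instantaneous modulus is exact for elastic input and matches the SLS oracle", {
  elastic <- sls_params(1.5, 1.5, 10)
  rec <- gen_loading_curve(protocol_spec("CL"), elastic,
                           sample_height_mm = 2, dt = 1, seed = 1)
  Ei <- instantaneous_modulus(rec)
  expect_equal(unname(Ei[1]), 1.5, tolerance = 1e-9)

  # viscoelastic ramp: expected value from a least-squares fit to the
  # closed-form ramp stress over the same window, independent of the
  # generator's integrator
  p <- sls_params(2, 1, 30)
  prot <- protocol_spec("CL")
  rec2 <- to_stress_strain(gen_loading_curve(prot, p, sample_height_mm = 2,
                                             dt = 1, seed = 1))
  idx <- rec2$strain_frac >= 0.13 & rec2$strain_frac <= 0.15
  oracle <- unname(coef(lm(sls_ramp_stress(rec2$time_s[idx], 3e-4, p) ~
                             rec2$strain_frac[idx]))[2])
  expect_equal(unname(instantaneous_modulus(rec2)[1]), oracle,
               tolerance = 1e-6)
  expect_error(instantaneous_modulus(rec2, step_window_strain_pct = 0.01),
               "fewer than 3")
})

test_that("quasi-equilibrium modulus and relaxation ratios recover SLS truth", {
  p <- sls_params(2, 1, 20) # relaxations are 30 and 45 tau: fully relaxed
  rec <- gen_loading_curve(protocol_spec("StR"), p, sample_height_mm = 2,
                           dt = 0.25, seed = 1)
  qe <- quasi_equilibrium_modulus(rec)
  expect_equal(qe$E_qeq_MPa, 1, tolerance = 1e-6)
  expect_equal(qe$eq_stress_MPa, c(0.15, 0.30), tolerance = 1e-6)

  # purely elastic: equilibrium equals peak, ratio exactly 1, E_qeq = E
  el <- gen_loading_curve(protocol_spec("StR"), sls_params(1, 1, 20),
                          sample_height_mm = 2, dt = 0.25, seed = 1)
  qel <- quasi_equilibrium_modulus(el)
  expect_equal(qel$E_qeq_MPa, 1, tolerance = 1e-9)
  expect_equal(relaxation_ratio(peak_stress(el), qel$eq_stress_MPa),
               c(1, 1), tolerance = 1e-9)

  # CL records have no defined quasi-equilibrium modulus
  cl <- gen_loading_curve(protocol_spec("CL"), p, sample_height_mm = 2,
                          dt = 1, seed = 1)
  expect_error(quasi_equilibrium_modulus(cl), "StR")
  # a single-step record fails
  one <- gen_loading_curve(protocol_spec("StR", target_strains_pct = 15,
                                         relaxation_s = 600),
                           p, sample_height_mm = 2, dt = 0.5, seed = 1)
  expect_error(quasi_equilibrium_modulus(one), "two completed")
})

test_that("relaxation ratio arithmetic and flags", {
  expect_equal(relaxation_ratio(2, 1), 0.5)
  expect_equal(relaxation_ratio(c(2, 4), c(1, 3)), c(0.5, 0.75))
  expect_warning(relaxation_ratio(1, 1.2), "non-physical")
  expect_error(relaxation_ratio(0, 0.5), "positive")
  # SLS step: ratio is exactly Einf/E0 by the closed form
  p <- sls_params(3, 1.2, 10)
  expect_equal(sls_step_stress(1e9, 0.15, p) / sls_step_stress(0, 0.15, p),
               1.2 / 3)
})

test_that("Poisson's ratio from strains and from volume edge profiles", {
  expect_equal(poisson_ratio(0.05, 0.15), 1 / 3, tolerance = 1e-9)
  expect_equal(poisson_ratio(0, 0.15), 0)
  expect_warning(poisson_ratio(0.09, 0.15), ">= 0.5")
  expect_error(poisson_ratio(0.05, 0), "positive")

  # barrel phantom: 4% widening at 10% axial compression -> nu = 0.40
  ref <- make_cylinder_volume(c(60, 120, 120), radius_vox = 40)
  def <- make_cylinder_volume(c(54, 120, 120), radius_vox = 41.6)
  ls <- lateral_strain_from_volumes(ref, def, threshold = 0.5)
  nu <- poisson_ratio(ls$lateral_strain, 0.10)
  expect_lt(abs(nu - 0.40), 0.02)
})

test_that("aggregate modulus follows the closed form and its limits", {
  expect_equal(aggregate_modulus(1, 0), 1)
  expect_equal(aggregate_modulus(2.5, 0), 2.5)
  expect_equal(aggregate_modulus(1, 0.3), 0.7 / (1.3 * 0.4))
  expect_error(aggregate_modulus(1, 0.5), "diverges")
  expect_error(aggregate_modulus(1, 0.7), "diverges")
  # strictly increasing in nu for fixed E
  nus <- seq(0, 0.49, by = 0.01)
  expect_true(all(diff(aggregate_modulus(1, nus)) > 0))
})

test_that("absorbed dose matches analytic limits and Monte-Carlo chords", {
  # optically thin: dose -> Psi * (mu/rho)
  thin <- absorbed_dose_cylinder(1, mu_over_rho_cm2_per_g = 0.01,
                                 radius_mm = 0.01)
  expect_equal(thin, 0.01 * 0.1, tolerance = 1e-4)
  # opaque: dose -> 2 Psi / (rho pi R)
  opaque <- absorbed_dose_cylinder(1, mu_over_rho_cm2_per_g = 1e5)
  expect_equal(opaque, 2 / (1060 * pi * 0.002), tolerance = 1e-4)
  # linear in fluence, bounded by the two limits
  d1 <- absorbed_dose_cylinder(1); d7 <- absorbed_dose_cylinder(7)
  expect_equal(d7, 7 * d1, tolerance = 1e-12)
  expect_lt(d1, 0.7786 * 0.1)
  expect_gt(d1, 0) # and below the opaque bound
  expect_lt(d1, 2 / (1060 * pi * 0.002))

  # Monte-Carlo chord oracle at default parameters
  set.seed(55)
  mu <- 0.7786 * 0.1 * 1060; R <- 0.002
  x <- runif(4e6, -R, R)
  mc <- mean(1 - exp(-mu * 2 * sqrt(R^2 - x^2))) * 2 * R / (1060 * pi * R^2)
  expect_equal(d1, mc, tolerance = 1e-3)
})

test_that("scan schedules match the protocol definitions", {
  cl <- build_scan_schedule(protocol_spec("CL"))
  expect_equal(nrow(cl), 7)
  expect_equal(max(cl$time_s), 500) # 15% at 0.03%/s
  expect_equal(unique(round(diff(cl$time_s), 9)), 500 / 7)

  st <- build_scan_schedule(protocol_spec("StR"))
  expect_equal(nrow(st), 14) # 2 steps x (peak + 6 offsets)
  st16 <- build_scan_schedule(protocol_spec("StR"),
                              include_end_of_relaxation = TRUE)
  expect_equal(nrow(st16), 16)
  # peaks at 15 s and 630 s for the default StR protocol
  expect_true(all(c(15, 630) %in% st$time_s))
  expect_error(build_scan_schedule(
    protocol_spec("StR", relaxation_s = c(500, 900))), "exceeds")
})

test_that("summarize_mechanics assembles a consistent report", {
  p <- sls_params(2, 1, 20)
  rec <- gen_loading_curve(protocol_spec("StR"), p, sample_height_mm = 2,
                           dt = 0.25, seed = 1)
  s <- summarize_mechanics(rec, nu_s = 0.3)
  expect_s3_class(s, "MechanicalSummary")
  expect_equal(s$E_qeq_MPa, 1, tolerance = 1e-6)
  expect_true(all(s$relax_ratio > 0 & s$relax_ratio <= 1))
  expect_equal(s$H_A_MPa, aggregate_modulus(s$E_qeq_MPa, 0.3))
})
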