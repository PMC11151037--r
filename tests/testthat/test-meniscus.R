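test_that("structure tensor recovers axis-aligned fiber orientations", {
  ph <- gen_fiber_phantom(shape = c(64, 64, 64), n_fibers = 15,
                          azimuth = angle_delta(0),
                          elevation = angle_delta(0),
                          noise_sd = 0, seed = 31)
  f <- structure_tensor_orientation(ph$volume)
  sel <- ph$volume$mask & f$valid_mask
  expect_gt(sum(sel), 1000)
  expect_lt(median(axial_diff_deg(f$azimuth_deg[sel], 0)), 2)
  expect_lt(median(abs(f$elevation_deg[sel])), 2)
})

test_that("fibers along the loading axis give |elevation| near 90", {
  ph <- gen_fiber_phantom(shape = c(64, 64, 64), n_fibers = 15,
                          azimuth = angle_uniform(),
                          elevation = angle_delta(90),
                          noise_sd = 0, seed = 32)
  f <- structure_tensor_orientation(ph$volume)
  sel <- ph$volume$mask & f$valid_mask
  expect_lt(median(90 - abs(f$elevation_deg[sel])), 2)
})

test_that("azimuth estimation is rotation-equivariant in the x-y plane", {
  base_az <- 20
  ph1 <- gen_fiber_phantom(shape = c(64, 64, 64), n_fibers = 15,
                           azimuth = angle_delta(base_az),
                           elevation = angle_delta(0),
                           noise_sd = 0.02, seed = 33)
  ph2 <- gen_fiber_phantom(shape = c(64, 64, 64), n_fibers = 15,
                           azimuth = angle_delta(base_az + 45),
                           elevation = angle_delta(0),
                           noise_sd = 0.02, seed = 33)
  m1 <- local({
    f <- structure_tensor_orientation(ph1$volume)
    sel <- ph1$volume$mask & f$valid_mask
    modal_angle(f$azimuth_deg[sel], 0, 180)
  })
  m2 <- local({
    f <- structure_tensor_orientation(ph2$volume)
    sel <- ph2$volume$mask & f$valid_mask
    modal_angle(f$azimuth_deg[sel], 0, 180)
  })
  expect_lt(axial_diff_deg(m2 - m1, 45), 2)
})

test_that("orientation is invariant to intensity scaling and inversion", {
  ph <- gen_fiber_phantom(shape = c(48, 48, 48), n_fibers = 10,
                          azimuth = angle_delta(70),
                          elevation = angle_delta(-20),
                          noise_sd = 0.02, seed = 34)
  f0 <- structure_tensor_orientation(ph$volume)
  fs <- structure_tensor_orientation(volume3d(ph$volume$data * 3.5))
  fi <- structure_tensor_orientation(volume3d(1 - ph$volume$data))
  sel <- f0$valid_mask
  expect_lt(max(abs(f0$azimuth_deg[sel] - fs$azimuth_deg[sel])), 1e-6)
  expect_lt(max(abs(f0$elevation_deg[sel] - fi$elevation_deg[sel])), 1e-6)
})

test_that("eigenvalues are ordered and coherence is bounded", {
  ph <- gen_fiber_phantom(shape = c(48, 48, 48), n_fibers = 10,
                          noise_sd = 0.05, seed = 35)
  f <- structure_tensor_orientation(ph$volume)
  ev <- f$eigenvalues
  expect_true(all(ev$l1 >= ev$l2 - 1e-12 & ev$l2 >= ev$l3 - 1e-12))
  expect_true(all(f$coherence >= 0 & f$coherence <= 1 + 1e-12))
  expect_true(all(f$azimuth_deg >= 0 & f$azimuth_deg < 180))
  expect_true(all(f$elevation_deg >= -90 & f$elevation_deg <= 90))
})

test_that("antipodal directions map to identical axial angles", {
  v <- matrix(rnorm(300), ncol = 3)
  a1 <- rheoCT:::direction_to_angles(v[, 1], v[, 2], v[, 3])
  a2 <- rheoCT:::direction_to_angles(-v[, 1], -v[, 2], -v[, 3])
  expect_equal(a1$azimuth_deg, a2$azimuth_deg)
  expect_equal(a1$elevation_deg, a2$elevation_deg)
  expect_true(all(a1$azimuth_deg >= 0 & a1$azimuth_deg < 180))
  expect_true(all(abs(a1$elevation_deg) <= 90))
})

test_that("orientation histograms are normalized and concentrated for delta phantoms", {
  ph <- gen_fiber_phantom(shape = c(64, 64, 64), n_fibers = 15,
                          azimuth = angle_delta(55),
                          elevation = angle_delta(15),
                          noise_sd = 0.02, seed = 36)
  f <- structure_tensor_orientation(ph$volume)
  h <- orientation_histograms(f, mask = ph$volume$mask)
  expect_equal(sum(h$azimuth$counts_norm), 1, tolerance = 1e-9)
  expect_equal(sum(h$elevation$counts_norm), 1, tolerance = 1e-9)
  in_az <- abs(h$azimuth$bin_centers_deg - 55) <= 3
  in_el <- abs(h$elevation$bin_centers_deg - 15) <= 3
  expect_gte(sum(h$azimuth$counts_norm[in_az]), 0.9)
  expect_gte(sum(h$elevation$counts_norm[in_el]), 0.9)
  expect_error(orientation_histograms(f, mask = array(FALSE, dim(f$coherence))),
               "no valid voxels")
})

test_that("histogram averaging preserves binning and normalization", {
  ph <- gen_fiber_phantom(shape = c(48, 48, 48), n_fibers = 10, seed = 37)
  f <- structure_tensor_orientation(ph$volume)
  h <- orientation_histograms(f)
  avg <- average_histograms(list(h$azimuth, h$azimuth))
  expect_equal(avg$counts_norm, h$azimuth$counts_norm)
  h5 <- orientation_histograms(f, bin_deg = 5)
  expect_error(average_histograms(list(h$azimuth, h5$azimuth)), "mismatched")
})

test_that("compression-emulating sequences sharpen the elevation peak monotonically", {
  spreads <- c(40, 25, 10) # decreasing dispersion around the x-y plane
  hists <- lapply(seq_along(spreads), function(i) {
    ph <- gen_fiber_phantom(shape = c(48, 48, 48), n_fibers = 40,
                            fiber_radius_um = c(6, 6),
                            azimuth = angle_uniform(),
                            elevation = angle_normal(0, spreads[i]),
                            noise_sd = 0.02, seed = 40 + i)
    f <- structure_tensor_orientation(ph$volume)
    orientation_histograms(f, mask = ph$volume$mask, bin_deg = 5)$elevation
  })
  trk <- track_peak_height(hists)
  expect_true(all(diff(trk$peak_height) > 0))
  # fraction of near-plane voxels increases as fibers flatten
  near_plane <- vapply(hists, function(h) {
    sum(h$counts_norm[abs(h$bin_centers_deg) < 5])
  }, numeric(1))
  expect_true(all(diff(near_plane) > 0))
})

test_that("peak tracking handles constant, single and tied inputs", {
  mk <- function(counts) {
    structure(list(bin_edges_deg = seq(-90, 90, 10),
                   bin_centers_deg = seq(-85, 85, 10),
                   counts_norm = counts / sum(counts),
                   angle_kind = "elevation"),
              class = "OrientationHistogram")
  }
  flat_peak <- mk(c(rep(1, 8), 5, 5, rep(1, 8)))
  trk <- track_peak_height(list(flat_peak, flat_peak))
  expect_equal(trk$peak_height[1], trk$peak_height[2])
  expect_true(all(trk$tied))
  expect_equal(trk$peak_angle_deg[1], -5) # lowest |angle| among the tie
  one <- track_peak_height(list(mk(c(rep(1, 9), 9, rep(1, 8)))))
  expect_equal(nrow(one), 1)
  expect_false(one$tied)
})
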