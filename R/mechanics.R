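#' Define a mechanical loading protocol
#'
#' Two protocols are supported, mirroring typical in situ unconfined
#' compression experiments on knee connective tissue:
#' \describe{
#'   \item{CL (continuous loading)}{after a 2 N preload, a constant strain
#'     rate (default 0.03 \%/s) is applied until the target strain (15\% for
#'     cartilage or 30\% for meniscus); seven tomographic scans are spread
#'     equidistantly along the ramp.}
#'   \item{StR (stress-relaxation)}{two compression steps of 15\% strain
#'     each at 1 \%/s ramp speed, followed by 600 s and 900 s of relaxation
#'     respectively; scans are triggered at each compression peak and at
#'     fixed relaxation offsets (20, 40, 60, 100, 300, 600 s).}
#' }
#'
#' @param kind `"CL"` or `"StR"`.
#' @param preload_N preload force in newtons (default 2).
#' @param strain_rate_pct_per_s ramp speed in percent strain per second;
#'   defaults to 0.03 for CL and 1 for StR.
#' @param target_strains_pct cumulative strain targets in percent; defaults
#'   to 15 for CL and c(15, 30) for StR.
#' @param relaxation_s relaxation duration after each StR step.
#' @param scan_count_cl number of equidistant CL scans.
#' @param scan_offsets_s scan trigger offsets after each StR peak; 0 is the
#'   peak itself.
#' @return An object of class `ProtocolSpec`.
#' @export
protocol_spec <- function(kind = c("StR", "CL"),
                          preload_N = 2,
                          strain_rate_pct_per_s = NULL,
                          target_strains_pct = NULL,
                          relaxation_s = c(600, 900),
                          scan_count_cl = 7L,
                          scan_offsets_s = c(0, 20, 40, 60, 100, 300, 600)) {
  kind <- match.arg(kind)
  if (is.null(strain_rate_pct_per_s)) {
    strain_rate_pct_per_s <- if (kind == "CL") 0.03 else 1
  }
  if (is.null(target_strains_pct)) {
    target_strains_pct <- if (kind == "CL") 15 else c(15, 30)
  }
  if (any(target_strains_pct <= 0)) stop("strain targets must be positive")
  if (is.unsorted(target_strains_pct, strictly = TRUE)) {
    stop("strain targets must be increasing")
  }
  if (kind == "StR") {
    if (length(relaxation_s) != length(target_strains_pct)) {
      stop("one relaxation duration per compression step is required")
    }
    if (any(relaxation_s <= 0)) stop("relaxation times must be positive")
    if (is.unsorted(scan_offsets_s)) stop("scan offsets must be sorted")
  }
  structure(list(kind = kind, preload_N = preload_N,
                 strain_rate_pct_per_s = strain_rate_pct_per_s,
                 target_strains_pct = target_strains_pct,
                 relaxation_s = if (kind == "StR") relaxation_s else numeric(0),
                 scan_count_cl = as.integer(scan_count_cl),
                 scan_offsets_s = scan_offsets_s),
            class = "ProtocolSpec")
}

# Per-step timing of a protocol: ramp start, peak time, end of hold.
protocol_timings <- function(protocol) {
  r <- protocol$strain_rate_pct_per_s
  tg <- protocol$target_strains_pct
  if (protocol$kind == "CL") {
    return(data.frame(step = 1L, t_start = 0, t_peak = tg[1] / r,
                      t_end = tg[1] / r, strain_pct = tg[1]))
  }
  steps <- length(tg)
  t <- 0
  out <- vector("list", steps)
  prev <- 0
  for (k in seq_len(steps)) {
    ramp <- (tg[k] - prev) / r
    out[[k]] <- data.frame(step = k, t_start = t, t_peak = t + ramp,
                           t_end = t + ramp + protocol$relaxation_s[k],
                           strain_pct = tg[k])
    t <- t + ramp + protocol$relaxation_s[k]
    prev <- tg[k]
  }
  do.call(rbind, out)
}

#' Build the tomographic scan trigger schedule of a protocol
#'
#' CL: `n` equidistant triggers at `t_i = i * T / n` where `T` is the ramp
#' duration (e.g. 15\% at 0.03 \%/s gives the last trigger at 500 s).
#' StR: one trigger at each compression peak plus each relaxation offset;
#' with `include_end_of_relaxation` an extra trigger is added at the end of
#' each step's relaxation.
#'
#' @param protocol a [protocol_spec()].
#' @param include_end_of_relaxation add an end-of-relaxation trigger per
#'   StR step (default FALSE).
#' @return data.frame with columns `time_s`, `step`, `label`.
#' @export
build_scan_schedule <- function(protocol, include_end_of_relaxation = FALSE) {
  stopifnot(inherits(protocol, "ProtocolSpec"))
  tim <- protocol_timings(protocol)
  if (protocol$kind == "CL") {
    n <- protocol$scan_count_cl
    T_ramp <- tim$t_peak[1]
    tt <- seq_len(n) * T_ramp / n
    return(data.frame(time_s = tt, step = 1L,
                      label = sprintf("cl_scan_%02d", seq_len(n))))
  }
  rows <- list()
  for (k in seq_len(nrow(tim))) {
    off <- protocol$scan_offsets_s
    off <- off[off <= protocol$relaxation_s[k]]
    if (length(off) < length(protocol$scan_offsets_s)) {
      stop("scan offset exceeds relaxation duration of step ", k)
    }
    tt <- tim$t_peak[k] + off
    lab <- ifelse(off == 0, sprintf("peak_%d", k),
                  sprintf("relax_%d_t%04d", k, off))
    if (include_end_of_relaxation) {
      tt <- c(tt, tim$t_end[k])
      lab <- c(lab, sprintf("relax_%d_end", k))
    }
    rows[[k]] <- data.frame(time_s = tt, step = k, label = lab)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert force--displacement to stress--strain
#'
#' Engineering stress assumes a constant sample diameter (default 4 mm,
#' area pi * 4 mm^2 = 12.566 mm^2); engineering strain is displacement over
#' the post-preload sample height. Compression is positive.
#'
#' @param rec a [loading_record()] with diameter and height set.
#' @return the record with `stress_MPa` and `strain_frac` filled.
#' @export
to_stress_strain <- function(rec) {
  stopifnot(inherits(rec, "LoadingRecord"))
  if (!is.finite(rec$sample_height_mm) || rec$sample_height_mm <= 0) {
    stop("post-preload sample height must be positive")
  }
  area_mm2 <- pi * (rec$sample_diameter_mm / 2)^2
  rec$stress_MPa <- rec$force_N / area_mm2 # N/mm^2 = MPa
  rec$strain_frac <- rec$displacement_mm / rec$sample_height_mm
  rec
}

# Locate the relaxation plateaus of a stress-relaxation record. Uses the
# attached protocol when present; otherwise detects constant-displacement
# runs at positive strain.
str_step_intervals <- function(rec) {
  if (!is.null(rec$protocol) && rec$protocol$kind == "StR") {
    tim <- protocol_timings(rec$protocol)
    return(data.frame(step = tim$step, t_peak = tim$t_peak,
                      t_end = tim$t_end, strain_pct = tim$strain_pct))
  }
  d <- rec$displacement_mm
  tol <- max(abs(d), 1e-12) * 1e-8
  plateau <- c(FALSE, abs(diff(d)) < tol) & d > tol
  r <- rle(plateau)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (rec$time_s[ends] - rec$time_s[starts]) >= 1
  if (!any(keep)) stop("no relaxation plateaus found in the record")
  data.frame(step = seq_len(sum(keep)),
             t_peak = rec$time_s[starts[keep]],
             t_end = rec$time_s[ends[keep]],
             strain_pct = 100 * d[ends[keep]] /
               rec$sample_height_mm)
}

#' Instantaneous Young's modulus per load step
#'
#' Least-squares slope of the stress--strain curve over the final
#' `step_window_strain_pct` percent of strain of the loading ramp before
#' each strain target.
#'
#' @param rec a stress/strain-converted [loading_record()].
#' @param step_window_strain_pct width of the fit window in percent strain.
#' @param target_strains_pct strain targets; defaults to the attached
#'   protocol's targets.
#' @return named numeric vector of moduli in MPa, one per step.
#' @export
instantaneous_modulus <- function(rec, step_window_strain_pct = 2,
                                  target_strains_pct = NULL) {
  stopifnot(inherits(rec, "LoadingRecord"))
  if (is.null(rec$stress_MPa)) rec <- to_stress_strain(rec)
  if (is.null(target_strains_pct)) {
    if (is.null(rec$protocol)) stop("strain targets required")
    target_strains_pct <- rec$protocol$target_strains_pct
  }
  eps <- rec$strain_frac
  w <- step_window_strain_pct / 100
  out <- numeric(length(target_strains_pct))
  for (k in seq_along(target_strains_pct)) {
    et <- target_strains_pct[k] / 100
    i_peak <- which(eps >= et - 1e-12)[1]
    if (is.na(i_peak)) stop("record never reaches ", target_strains_pct[k],
                            "% strain")
    idx <- which(seq_along(eps) <= i_peak & eps >= et - w)
    if (length(idx) < 3L) stop("fewer than 3 samples in the fit window of ",
                               "step ", k)
    fit <- stats::lm(rec$stress_MPa[idx] ~ eps[idx])
    out[k] <- unname(stats::coef(fit)[2])
  }
  names(out) <- sprintf("E_i_%g pct", target_strains_pct)
  out
}

#' Quasi-equilibrium Young's modulus of a stress-relaxation record
#'
#' The equilibrium stress of each step is the mean stress over the last
#' `eq_window_s` seconds of its relaxation; the quasi-equilibrium modulus is
#' the slope between the fully relaxed stresses of the first and last steps
#' (for the default protocol: between 15\% and 30\% strain). Termed
#' quasi-equilibrium because long relaxation times may still leave slow
#' transients, especially in meniscus.
#'
#' @param rec a stress/strain-converted StR [loading_record()].
#' @param eq_window_s averaging window at the end of each relaxation.
#' @return list with `eq_stress_MPa` (per step), `eq_strain_frac` and
#'   `E_qeq_MPa`.
#' @export
quasi_equilibrium_modulus <- function(rec, eq_window_s = 10) {
  stopifnot(inherits(rec, "LoadingRecord"))
  if (!is.null(rec$protocol) && rec$protocol$kind != "StR") {
    stop("quasi-equilibrium modulus is defined for StR records only")
  }
  if (is.null(rec$stress_MPa)) rec <- to_stress_strain(rec)
  iv <- str_step_intervals(rec)
  if (nrow(iv) < 2L) stop("need two completed relaxation steps")
  eq_stress <- eq_strain <- numeric(nrow(iv))
  for (k in seq_len(nrow(iv))) {
    idx <- rec$time_s >= iv$t_end[k] - eq_window_s & rec$time_s <= iv$t_end[k]
    if (!any(idx)) stop("no samples in the equilibrium window of step ", k)
    eq_stress[k] <- mean(rec$stress_MPa[idx])
    eq_strain[k] <- mean(rec$strain_frac[idx])
  }
  k1 <- 1L; k2 <- nrow(iv)
  list(eq_stress_MPa = eq_stress, eq_strain_frac = eq_strain,
       E_qeq_MPa = (eq_stress[k2] - eq_stress[k1]) /
         (eq_strain[k2] - eq_strain[k1]))
}

#' Peak stress per stress-relaxation step
#'
#' @param rec a stress/strain-converted StR [loading_record()].
#' @return numeric vector, maximum stress within each step in MPa.
#' @export
peak_stress <- function(rec) {
  stopifnot(inherits(rec, "LoadingRecord"))
  if (is.null(rec$stress_MPa)) rec <- to_stress_strain(rec)
  iv <- str_step_intervals(rec)
  t0 <- c(0, iv$t_end[-nrow(iv)])
  vapply(seq_len(nrow(iv)), function(k) {
    max(rec$stress_MPa[rec$time_s >= t0[k] & rec$time_s <= iv$t_end[k]])
  }, numeric(1))
}

#' Relaxation ratio
#'
#' Ratio of equilibrium to peak stress at a load step; 1 for a purely
#' elastic response, smaller the more the material relaxes.
#'
#' @param peak_stress_MPa peak stress per step.
#' @param eq_stress_MPa equilibrium stress per step.
#' @return numeric vector of ratios; ratios above 1 (non-physical for
#'   relaxation) raise a warning.
#' @export
relaxation_ratio <- function(peak_stress_MPa, eq_stress_MPa) {
  if (any(peak_stress_MPa <= 0)) stop("peak stress must be positive")
  r <- eq_stress_MPa / peak_stress_MPa
  if (any(r > 1 + 1e-9)) {
    warning("equilibrium stress exceeds peak stress (non-physical)")
  }
  r
}

#' Equilibrium Poisson's ratio from lateral and axial strains
#'
#' @param lateral_strain relative lateral (diameter) strain magnitude(s).
#' @param axial_strain corresponding axial strain magnitude(s).
#' @return mean ratio across measurements; values outside [0, 0.5) raise a
#'   warning.
#' @export
poisson_ratio <- function(lateral_strain, axial_strain) {
  if (any(axial_strain <= 0)) stop("axial strain must be positive")
  nu <- mean(abs(lateral_strain) / abs(axial_strain))
  if (nu >= 0.5) warning("Poisson's ratio >= 0.5 (outside physical range ",
                         "for compressible equilibrium response)")
  nu
}

#' Measure lateral strain between two volumes
#'
#' Estimates the sample diameter in a mid-height slab of each volume from
#' the area-equivalent diameter of the thresholded cross-section, and
#' returns the relative diameter change. This replaces manual caliper
#' measurements on slice images.
#'
#' @param ref_vol,def_vol reference (e.g. preload) and deformed volumes.
#' @param slab_frac z-range of the measurement slab as fractions of depth.
#' @param threshold intensity threshold separating sample from background;
#'   `NULL` uses Otsu's threshold of the reference volume.
#' @return list with `diameter_ref_vox`, `diameter_def_vox`,
#'   `lateral_strain` (positive = widening).
#' @export
lateral_strain_from_volumes <- function(ref_vol, def_vol,
                                        slab_frac = c(0.4, 0.6),
                                        threshold = NULL) {
  stopifnot(inherits(ref_vol, "Volume3D"), inherits(def_vol, "Volume3D"))
  if (is.null(threshold)) threshold <- otsu_threshold(as.vector(ref_vol$data))
  eq_diam <- function(vol) {
    d <- dim(vol$data)
    iz <- max(1, floor(slab_frac[1] * d[1])):min(d[1],
                                                 ceiling(slab_frac[2] * d[1]))
    areas <- vapply(iz, function(i) sum(vol$data[i, , ] > threshold),
                    numeric(1))
    2 * sqrt(mean(areas) / pi)
  }
  d_ref <- eq_diam(ref_vol); d_def <- eq_diam(def_vol)
  list(diameter_ref_vox = d_ref, diameter_def_vox = d_def,
       lateral_strain = (d_def - d_ref) / d_ref)
}

#' Aggregate modulus from equilibrium modulus and Poisson's ratio
#'
#' Confined-compression (aggregate) modulus
#' `H_A = (1 - nu) * E / ((1 + nu) * (1 - 2 nu))`. Reduces to `E` at
#' `nu = 0` and diverges as `nu -> 0.5`.
#'
#' @param E_qeq_MPa quasi-equilibrium Young's modulus in MPa.
#' @param nu_s equilibrium Poisson's ratio in [0, 0.5).
#' @return aggregate modulus in MPa.
#' @export
aggregate_modulus <- function(E_qeq_MPa, nu_s) {
  if (any(nu_s < 0) || any(nu_s >= 0.5)) {
    stop("nu_s must lie in [0, 0.5); the formula diverges at 0.5")
  }
  (1 - nu_s) * E_qeq_MPa / ((1 + nu_s) * (1 - 2 * nu_s))
}

#' Mean absorbed dose in a uniformly illuminated rotating cylinder
#'
#' Approximates the sample as a soft-tissue cylinder fully covered by the
#' beam and rotation-averaged, with Beer--Lambert absorption along each
#' chord:
#' `D = Psi * Int_{-R}^{R} (1 - exp(-mu * 2 sqrt(R^2 - x^2))) dx / (rho pi R^2)`
#' with `mu = (mu/rho) * rho`. Bounded between the optically thin limit
#' `Psi * (mu/rho)` and the opaque limit `2 Psi / (rho pi R)`.
#'
#' @param energy_fluence_J_per_m2 incident energy fluence in J/m^2.
#' @param mu_over_rho_cm2_per_g mass attenuation coefficient (default
#'   0.7786 cm^2/g, soft tissue at 21 keV).
#' @param density_g_per_cm3 tissue density (default 1.06).
#' @param radius_mm cylinder radius (default 2, i.e. 4 mm diameter).
#' @return mean absorbed dose in gray (J/kg).
#' @export
absorbed_dose_cylinder <- function(energy_fluence_J_per_m2,
                                   mu_over_rho_cm2_per_g = 0.7786,
                                   density_g_per_cm3 = 1.06,
                                   radius_mm = 2) {
  stopifnot(energy_fluence_J_per_m2 >= 0, mu_over_rho_cm2_per_g > 0,
            density_g_per_cm3 > 0, radius_mm > 0)
  mu_over_rho <- mu_over_rho_cm2_per_g * 0.1 # m^2/kg
  rho <- density_g_per_cm3 * 1000            # kg/m^3
  mu <- mu_over_rho * rho                    # 1/m
  R <- radius_mm / 1000                      # m
  chord <- function(x) 1 - exp(-mu * 2 * sqrt(pmax(R^2 - x^2, 0)))
  q <- stats::integrate(chord, -R, R, rel.tol = 1e-10)
  if (q$message != "OK") stop("chord integral did not converge")
  energy_fluence_J_per_m2 * q$value / (rho * pi * R^2)
}

#' Full mechanical summary of a stress-relaxation record
#'
#' Convenience wrapper computing the instantaneous moduli, equilibrium
#' stresses, quasi-equilibrium modulus, relaxation ratios and (when a
#' Poisson's ratio is supplied) the aggregate modulus.
#'
#' @param rec a StR [loading_record()].
#' @param nu_s optional equilibrium Poisson's ratio.
#' @param eq_window_s,step_window_strain_pct analysis windows.
#' @return An object of class `MechanicalSummary` (a list).
#' @export
summarize_mechanics <- function(rec, nu_s = NA_real_, eq_window_s = 10,
                                step_window_strain_pct = 2) {
  rec <- to_stress_strain(rec)
  qe <- quasi_equilibrium_modulus(rec, eq_window_s = eq_window_s)
  pk <- peak_stress(rec)
  out <- list(
    E_i_MPa = instantaneous_modulus(rec, step_window_strain_pct),
    eq_stress_MPa = qe$eq_stress_MPa,
    peak_stress_MPa = pk,
    E_qeq_MPa = qe$E_qeq_MPa,
    relax_ratio = relaxation_ratio(pk, qe$eq_stress_MPa),
    nu_s = nu_s,
    H_A_MPa = if (is.finite(nu_s)) aggregate_modulus(qe$E_qeq_MPa, nu_s)
              else NA_real_
  )
  class(out) <- "MechanicalSummary"
  out
}

#' @export
print.MechanicalSummary <- function(x, ...) {
  cat("MechanicalSummary\n")
  cat("  E_i [MPa]:      ", paste(sprintf("%.4g", x$E_i_MPa),
                                  collapse = ", "), "\n")
  cat("  E_qeq [MPa]:    ", sprintf("%.4g", x$E_qeq_MPa), "\n")
  cat("  relax ratio:    ", paste(sprintf("%.4g", x$relax_ratio),
                                  collapse = ", "), "\n")
  if (is.finite(x$nu_s)) {
    cat("  nu_s:           ", sprintf("%.4g", x$nu_s), "\n")
    cat("  H_A [MPa]:      ", sprintf("%.4g", x$H_A_MPa), "\n")
  }
  invisible(x)
}
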