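#' Rotationally averaged power spectral density
#'
#' Removes the volume mean, Fourier-transforms, and averages the power
#' `|F|^2` over shells of constant spatial-frequency magnitude up to the
#' Nyquist frequency (0.5 cycles/pixel). In `"2d"` mode the spectrum is
#' computed per z-slice and radially averaged in-plane, then averaged over
#' slices; `"3d"` (default) uses the full 3D transform with spherical
#' shells.
#'
#' @param vol a [volume3d()] object or 3D array.
#' @param mode `"3d"` or `"2d"`.
#' @return data.frame with columns `freq` (bin centers, cycles/pixel),
#'   `power` (mean power in the bin) and `n_samples` (Fourier samples per
#'   bin, used for the resolution estimator's noise allowance); attribute
#'   `"constant"` flags an all-constant input (all-zero spectrum).
#' @export
radial_psd <- function(vol, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  x <- if (inherits(vol, "Volume3D")) vol$data else vol
  if (!all(is.finite(x))) stop("volume contains non-finite values")
  d <- dim(x)
  x <- x - mean(x)
  constant <- all(x == 0)

  fft_freqs <- function(n) {
    k <- 0:(n - 1)
    ifelse(k <= n / 2, k / n, k / n - 1)
  }
  if (mode == "3d") {
    pw <- abs(fft(x))^2 / length(x)
    fz <- fft_freqs(d[1]); fy <- fft_freqs(d[2]); fx <- fft_freqs(d[3])
    fmag <- sqrt(outer(outer(fz^2, fy^2, `+`), fx^2, `+`))
    n_bins <- max(16L, floor(min(d) / 2))
  } else {
    fy <- fft_freqs(d[2]); fx <- fft_freqs(d[3])
    fmag2d <- sqrt(outer(fy^2, fx^2, `+`))
    pw2d <- 0
    for (i in seq_len(d[1])) {
      sl <- x[i, , ]
      pw2d <- pw2d + abs(fft(sl))^2 / length(sl)
    }
    pw <- pw2d / d[1]
    fmag <- fmag2d
    n_bins <- max(16L, floor(min(d[2:3]) / 2))
  }
  edges <- seq(0, 0.5, length.out = n_bins + 1)
  bin <- findInterval(fmag, edges, rightmost.closed = TRUE)
  keep <- bin >= 1 & bin <= n_bins & fmag <= 0.5
  fb <- factor(bin[keep], levels = 1:n_bins)
  power <- as.numeric(tapply(pw[keep], fb, mean))
  power[is.na(power)] <- 0
  counts <- as.numeric(table(fb))
  out <- data.frame(freq = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    power = power, n_samples = counts)
  attr(out, "constant") <- constant
  out
}

#' Estimate spatial resolution from a power spectral density
#'
#' Fourier-criterion resolution: the radially averaged power spectrum of a
#' band-limited image converges to a flat noise baseline at some cutoff
#' frequency; its reciprocal is the resolution in pixels. The baseline is
#' the mean power over the top `baseline_fraction` of frequency bins (at
#' least 4), and the cutoff is the lowest frequency beyond which power
#' stays below `threshold_factor * baseline` for all higher bins, with a
#' per-bin allowance of three relative standard deviations of the shell's
#' chi-square sampling scatter (`3/sqrt(samples per bin)`) so a single
#' fluctuating noise bin cannot displace the cutoff.
#'
#' @param psd output of [radial_psd()].
#' @param baseline_fraction fraction of the highest frequencies used for
#'   the noise baseline (default 0.1).
#' @param threshold_factor multiple of the baseline defining convergence
#'   (default 1.1).
#' @param voxel_size_um optional voxel size to also report micrometres.
#' @return list with `resolution_px`, `resolution_um` (NA if no voxel size
#'   given), `cutoff_freq_cyc_per_px`, `baseline_power` and `degenerate`
#'   (TRUE when the spectrum sits at the baseline everywhere, i.e. pure
#'   noise; resolution is then the image extent).
#' @export
estimate_resolution <- function(psd, baseline_fraction = 0.1,
                                threshold_factor = 1.1,
                                voxel_size_um = NA_real_) {
  if (nrow(psd) < 16L) stop("PSD needs at least 16 bins")
  n <- nrow(psd)
  n_base <- max(4L, round(baseline_fraction * n))
  base_bins <- psd$power[(n - n_base + 1):n]
  baseline <- mean(base_bins)
  # per-bin convergence threshold: the stated factor over the baseline,
  # plus an allowance for each bin's own chi-square sampling scatter
  # (relative sd ~ 1/sqrt(samples in the shell))
  margin <- if (!is.null(psd$n_samples)) {
    3 / sqrt(pmax(psd$n_samples, 1))
  } else {
    rep(2 * stats::sd(base_bins) / max(baseline, .Machine$double.xmin), n)
  }
  thr <- baseline * (threshold_factor + margin)
  # no signal band: the low-frequency end already sits at the baseline
  low_power <- mean(psd$power[seq_len(n_base)])
  if (baseline <= 0 || low_power < mean(thr[seq_len(n_base)])) {
    res_px <- n * 2
    return(list(resolution_px = res_px,
                resolution_um = res_px * voxel_size_um,
                cutoff_freq_cyc_per_px = NA_real_,
                baseline_power = baseline, degenerate = TRUE))
  }
  below <- psd$power < thr
  # lowest frequency from which all higher bins stay below threshold
  all_above_ok <- rev(cumprod(rev(below))) > 0
  if (all(all_above_ok)) {
    # spectrum at the baseline everywhere: no resolvable signal band
    res_px <- n * 2 # image extent in pixels (bins cover up to Nyquist)
    return(list(resolution_px = res_px,
                resolution_um = res_px * voxel_size_um,
                cutoff_freq_cyc_per_px = NA_real_,
                baseline_power = baseline, degenerate = TRUE))
  }
  idx <- which(all_above_ok)[1]
  if (is.na(idx)) {
    # power above baseline up to Nyquist: resolution at the 2-px limit
    return(list(resolution_px = 2, resolution_um = 2 * voxel_size_um,
                cutoff_freq_cyc_per_px = 0.5,
                baseline_power = baseline, degenerate = TRUE))
  }
  # the true convergence point lies between the last above-threshold bin
  # and this one: report the lower bin edge, not the center
  bw <- psd$freq[2] - psd$freq[1]
  f_c <- max(psd$freq[idx] - bw / 2, bw / 2)
  list(resolution_px = 1 / f_c, resolution_um = (1 / f_c) * voxel_size_um,
       cutoff_freq_cyc_per_px = f_c, baseline_power = baseline,
       degenerate = FALSE)
}

#' Signal-to-noise ratio
#'
#' Mean foreground intensity over the standard deviation (unbiased, n-1)
#' of the background. Scale-invariant, but not invariant to intensity
#' offsets (the numerator is a mean, not a contrast).
#'
#' @param vol a [volume3d()] or array.
#' @param fg_mask,bg_mask disjoint non-empty logical masks.
#' @return SNR scalar; `Inf` (with a warning) when the background is
#'   perfectly uniform.
#' @export
compute_snr <- function(vol, fg_mask, bg_mask) {
  x <- if (inherits(vol, "Volume3D")) vol$data else vol
  if (!any(fg_mask) || !any(bg_mask)) stop("masks must be non-empty")
  if (any(fg_mask & bg_mask)) stop("masks must be disjoint")
  s <- stats::sd(x[bg_mask])
  if (s == 0) {
    warning("background standard deviation is zero; SNR undefined")
    return(Inf)
  }
  mean(x[fg_mask]) / s
}

#' Contrast-to-noise ratio between two image features
#'
#' `CNR(A, B) = (I_A - I_B) / sqrt((sigma_A^2 + sigma_B^2) / 2)` where `I`
#' and `sigma` are the mean and standard deviation over each feature mask.
#' Antisymmetric in its arguments and invariant to global intensity scale
#' and offset.
#'
#' @param vol a [volume3d()] or array.
#' @param maskA,maskB disjoint non-empty logical masks.
#' @return CNR scalar; `NaN` (with a warning) when both features are
#'   perfectly uniform.
#' @export
compute_cnr <- function(vol, maskA, maskB) {
  x <- if (inherits(vol, "Volume3D")) vol$data else vol
  if (!any(maskA) || !any(maskB)) stop("masks must be non-empty")
  if (any(maskA & maskB)) stop("masks must be disjoint")
  sA <- stats::sd(x[maskA]); sB <- stats::sd(x[maskB])
  denom <- sqrt((sA^2 + sB^2) / 2)
  if (denom == 0) {
    warning("both feature standard deviations are zero; CNR undefined")
    return(NaN)
  }
  (mean(x[maskA]) - mean(x[maskB])) / denom
}

#' Aggregate image-quality report
#'
#' Computes the Fourier-criterion resolution, SNR, and CNR for each
#' requested feature pair of a volume.
#'
#' @param vol a [volume3d()] object.
#' @param fg_mask,bg_mask foreground/background masks for SNR.
#' @param cnr_pairs named list; each element a list of two masks `(A, B)`.
#' @param psd_mode `"3d"` or `"2d"` (see [radial_psd()]).
#' @param baseline_fraction,threshold_factor see [estimate_resolution()].
#' @return An object of class `QualityReport` (a list).
#' @export
quality_report <- function(vol, fg_mask, bg_mask, cnr_pairs = list(),
                           psd_mode = "3d", baseline_fraction = 0.1,
                           threshold_factor = 1.1) {
  stopifnot(inherits(vol, "Volume3D"))
  psd <- radial_psd(vol, mode = psd_mode)
  res <- estimate_resolution(psd, baseline_fraction, threshold_factor,
                             voxel_size_um = vol$voxel_size_um)
  cnr <- lapply(cnr_pairs, function(p) compute_cnr(vol, p[[1]], p[[2]]))
  out <- list(resolution_px = res$resolution_px,
              resolution_um = res$resolution_um,
              cutoff_freq_cyc_per_px = res$cutoff_freq_cyc_per_px,
              baseline_power = res$baseline_power,
              degenerate_resolution = res$degenerate,
              snr = compute_snr(vol, fg_mask, bg_mask),
              cnr_pairs = cnr)
  class(out) <- "QualityReport"
  out
}

#' @export
print.QualityReport <- function(x, ...) {
  cat("QualityReport\n")
  cat(sprintf("  resolution: %.2f px (%.2f um)%s\n", x$resolution_px,
              x$resolution_um,
              if (x$degenerate_resolution) " [degenerate]" else ""))
  cat(sprintf("  SNR: %.3g\n", x$snr))
  for (nm in names(x$cnr_pairs)) {
    cat(sprintf("  CNR(%s): %.3g\n", nm, x$cnr_pairs[[nm]]))
  }
  invisible(x)
}
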