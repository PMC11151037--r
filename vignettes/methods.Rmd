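---
title: "Methods: quantifying loaded cartilage and meniscus tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying loaded cartilage and meniscus tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheoCT)
```

## Scope and data model

rheoCT analyses time-resolved phase-contrast micro-CT experiments in which
a cylindrical articular-cartilage (AC) or meniscus (MM) sample is
compressed in a rheometer while being imaged. Two inputs exist per
experiment: a reconstructed grayscale volume per time point, and the
rheometer's time/force/displacement table. Volumes are held as `Volume3D`
objects with a fixed (z, y, x) axis order — z is the loading/depth axis —
and an isotropic voxel size defaulting to 2.75 µm, the acquisition pixel
size of the setup this pipeline was built around. Crop regions are 0-based
half-open voxel intervals. Intensities are kept as stored; the TIFF writer
rescales out-of-range floats to [0, 1] and records the affine transform in
a plain-text sidecar so reads restore the original units.

Five full-depth subvolumes with a 500 × 500 µm² lateral footprint are
cropped per tomogram for analysis (182 voxels per side after rounding
µm → voxels to the nearest integer). The placement strategy is not dictated
by the experimental design, so the package uses seed-fixed uniform-random
non-overlapping placement, reusing the same positions across time points;
overlapping placement is a warned fallback when the footprints cannot be
packed.

## Image quality

The spatial-resolution estimate follows a Fourier criterion: the radially
averaged power spectral density (PSD) of a band-limited image falls to a
flat noise baseline at a cutoff frequency whose reciprocal is the
resolution in pixels. Two parameters operationalize the criterion and are
exposed as arguments: the baseline is the mean power over the top decile of
frequency bins (`baseline_fraction = 0.1`), and the cutoff is the lowest
frequency beyond which power stays below `threshold_factor = 1.1` times
that baseline. The reported cutoff is the lower edge of the first
converged bin, since the true convergence point lies between the last
above-threshold bin and the first below-threshold one; on constructed
hard-cutoff phantoms this centers the estimate within one frequency bin of
truth. Two degenerate regimes are flagged: a spectrum already at the
baseline in its lowest-frequency bins (pure noise — resolution is reported
as the image extent) and power above baseline all the way to Nyquist
(resolution at the 2-pixel limit). The PSD is computed on the 3D transform
with spherical-shell binning by default; a per-slice 2D mode is available
because it is ambiguous whether ROI-based quality metrics of this kind of
experiment are evaluated on slices or volumes.

SNR is mean foreground intensity over the standard deviation of the
background (unbiased estimator); it is invariant to intensity scaling but
not to offsets, which is why any intensity normalization in the I/O layer
is explicit. CNR between features A and B is
`(I_A − I_B) / sqrt((σ_A² + σ_B²)/2)`, antisymmetric and offset-invariant.
Feature ROIs must be supplied as masks: no automatic ROI choice is
attempted, as none is defensible without seeing the specific
reconstruction.

## Chondrocyte density

Chondrocytes appear as cell-scale inclusions whose contrast does not allow
separating individual cells when they stack in columns, so density is
quantified as segmented volume percentage, never as a cell count. The
segmenter is deliberately a deterministic classical pipeline rather than a
trained classifier: Gaussian smoothing (σ = 1 px), polarity normalization
(cells darker than the matrix by default), Otsu or manual thresholding
inside the tissue mask, morphological opening with radius 1, and a
connected-component size filter keeping spherical-equivalent diameters of
8–40 µm. Two choices deserve note. First, the opening uses the 6-connected
cross structuring element: the 3³ box erodes roughly a quarter of the
volume of cell-sized ellipsoids and biases deep-layer densities low by
several percentage points. Second, a degenerate-threshold guard returns an
empty mask (with a warning) when the threshold selects over 35 % of the
tissue: physiological chondrocyte volume fractions are far below that, and
such a split only occurs when the histogram has no cell/matrix separation
(e.g. pure noise), where smoothed-noise percolation would otherwise leak
blobs through the size filter.

The density profile divides the tissue z-extent into 10 equal-thickness
layers (layer 1 at 0 % depth = articular surface) and reports
`100 · cell voxels / tissue voxels` per layer. The per-layer counts sum
exactly to the segmented total (conservation), and the profile is invariant
to lateral translation. Profiles from several time points are layered per
subvolume first and then averaged layer-wise — the alternative order
(pooling voxels before layering) is equivalent for equal-size subvolumes
but not in general, and the per-subvolume order also yields a spread
estimate.

## Collagen fiber orientation

The structure gradient tensor is computed per voxel: smooth the volume
with a Gaussian (σ = 1 px), take the 3D Sobel gradient g, form the outer
product g·gᵀ (6 unique components), smooth each component with a second
Gaussian (σ = 4 px), and eigendecompose the symmetric 3 × 3 tensor.
Intensity changes least along a fiber, so the eigenvector of the smallest
eigenvalue (eigenvalues sorted λ1 ≥ λ2 ≥ λ3) is the local fiber direction.
Both Gaussian stages use symmetric (mirror) boundary handling, and voxels
within 2σ of the volume border are marked invalid, as are voxels with
vanishing tensor trace or coherence `(λ1 − λ3)/(λ1 + λ2 + λ3)` below 0.01
(all exposed as arguments).

Fiber directions are axial, so each is mapped to a canonical
representative: azimuth ϕ ∈ [0, 180)° measured from +x in the x–y
(cross-sectional) plane and elevation θ ∈ [−90, 90]° from that plane
toward +z (the loading axis). The representative keeps the in-plane
projection in the upper half-plane, which makes antipodal directions
identical and keeps θ's sign meaningful. Directions along ±z have no
in-plane component; they report θ = +90 with an arbitrary (flagged
meaningless) azimuth. Histograms use 1° bins by default and are normalized
to sum to one; multi-subvolume summaries average per-subvolume normalized
histograms bin-wise. Peak tracking across strain levels reports the
maximum normalized count and its bin center, resolving ties toward the
smallest absolute angle and flagging them.

On straight-fiber phantoms the pipeline recovers modal angles well within
1° at contrast-to-noise 5 and 3-voxel fiber radius; the acceptance suite
asserts 3°. Elevation draws for those checks stay within ±70° because the
azimuth mode is undefined near the pole, where the in-plane projection
vanishes.

## Mechanics, protocols and dose

Force–displacement records convert to engineering stress and strain with a
constant 4 mm sample diameter (area π·4 mm² = 12.566 mm²) and the
post-preload height measured from the static tomogram; compression is
positive. The instantaneous modulus is the least-squares slope of stress
vs strain over the final 2 % of strain before each step's peak, and the
quasi-equilibrium modulus is the slope between the fully relaxed stresses
of the first and last steps, with the equilibrium stress per step averaged
over the last 10 s of its relaxation. Both windows are unstated in typical
experimental write-ups and are exposed as arguments with those defaults.
"Quasi"-equilibrium reflects that meniscus can keep relaxing beyond the
protocol's hold times. Relaxation ratios are equilibrium over peak stress
per step. Poisson's ratio divides the lateral (diameter) strain by the
axial strain; the lateral strain is measured from volumes as the relative
change of the area-equivalent diameter in a mid-height slab of the
thresholded cross-section, replacing manual caliper measurements on slice
images. The aggregate modulus is the closed form
`H_A = (1 − ν) E / ((1 + ν)(1 − 2ν))`, increasing in ν, equal to E at
ν = 0, and divergent at ν = 0.5 (a domain error).

The two protocol models are CL — ramp at 0.03 %/s to the target strain
with 7 equidistant scan triggers (15 % gives the last trigger at 500 s) —
and StR — two 15 % steps at 1 %/s with 600 s and 900 s relaxations and
triggers at each peak plus offsets of 20, 40, 60, 100, 300 and 600 s.
Enumerating peaks and offsets gives 14 triggers although such protocols
are sometimes described as 15 scans; rather than silently absorbing the
discrepancy, an `include_end_of_relaxation` flag adds one trigger per step
(16 total) and the count is the user's choice.

Absorbed dose approximates the sample as a uniformly illuminated rotating
soft-tissue cylinder (µ/ρ = 0.7786 cm²/g at 21 keV, 4 mm diameter):
`D = Ψ ∫ (1 − e^(−µ·2√(R²−x²))) dx / (ρπR²)` by adaptive quadrature, with
the tissue density ρ = 1.06 g/cm³ a package default (configurable), since
only the mass attenuation coefficient is standard. The dose is linear in
the energy fluence Ψ and bounded by the optically thin limit Ψ·(µ/ρ) and
the opaque limit 2Ψ/(ρπR); no attempt is made to reproduce any particular
facility's flux, so Ψ is always user-supplied.

## Repeatability

Repeated scans of a remounted sample are aligned by integer-voxel
phase-correlation registration (translation only — remounting rotations
are assumed negligible; the correlation is computed on mean-subtracted
volumes and the search is bounded at ±50 voxels per axis). The reported
reliability score is the normalized cross-correlation at the recovered
shift, flagged below 0.2 — the raw phase-correlation peak itself is not a
useful score since spectral whitening makes it small even for successful
alignments under noise. Matched cubes of 300 voxels per side (0.825 mm;
full-depth variants for meniscus) are then cropped at identical positions
and pushed through the density or orientation analysis, and runs are
compared with per-layer absolute density differences and both the maximum
and mean absolute histogram bin differences (the maximum corresponds to a
peak-height difference; the mean is less sensitive to a single sharp
mode). The comparison is symmetric and identically zero for identical
inputs.

## The phantom generator

The synthetic module defines the study conditions for every test. Fiber
phantoms rasterize straight cylinders from anti-aliased distance fields
(coverage ramps linearly over one voxel at the surface), which avoids
stair-step bias in orientation estimates; fiber axes pass through uniform
random points with angles drawn from delta, uniform, cosine-weighted
(isotropic-axis) or wrapped-normal distributions. Default contrast is
fiber 1.0 on matrix 0.2 with additive Gaussian noise — no quantitative
intensity statistics exist for the real tissue, so these are free
parameters chosen to give realistic contrast-to-noise ratios (noise
σ = 0.16 gives CNR 5, the level used in the recovery suites). Cartilage
phantoms place ellipsoidal cells with depth-dependent shape (flattened
near the surface, rounder and larger in the deep zone, 10–30 µm scale)
fully inside their target layer, strictly non-overlapping with a 1-voxel
clearance so distinct cells never 6-connect; realized per-layer label
densities land within one percentage point of the requested profile. Cells
never straddling layer boundaries slightly depletes density at the cuts;
this does not affect layer-resolved comparisons, which use the same cuts.

Loading curves come from the standard linear solid (Zener) model — the
simplest viscoelastic solid with distinct instantaneous and equilibrium
moduli, which makes parameter recovery analytic: step response
`σ(t) = ε₀[E∞ + (E₀ − E∞)e^(−t/τ)]`, ramp response
`σ(t) = r[E∞t + (E₀ − E∞)τ(1 − e^(−t/τ))]`. The simulator integrates the
overstress exactly per constant-rate sampling interval, so CL records
reproduce the closed form to 1e−9 MPa. Repeated-scan pairs apply an
integer circular shift plus independent noise realizations; the circular
shift keeps content identical, so noise-free registration must be exact.
All generators are bit-reproducible under a fixed seed, and ground truth
travels alongside each phantom without ever being read by an analysis
stage.

Two SLS subtleties matter for validation. First, under the default 1 %/s
StR ramp the 15-s ramp time is not negligible against typical relaxation
times, so the measured relaxation ratio exceeds E∞/E₀ by about
(ΔE/E₀)·T/(2τ); the parameter-recovery suite therefore uses a fast-ramp
protocol (50 %/s, relaxations of 8τ) as an idealized step while the
default protocol keeps the experimental rates. Second, for two equal
consecutive steps measured on absolute stress the second step's
equilibrium-to-peak ratio is `2r/(1 + r)` with `r = E∞/E₀`, not `r`; the
suite checks each step against its own closed form.

## What the phantoms do and do not show

Phantom tests establish that each estimator recovers known ground truth
under additive Gaussian noise. Real phase-contrast reconstructions differ
in ways the generator deliberately does not model: edge-enhancement
fringes, ring and motion artefacts, spatially correlated noise, curved and
bundled fibers, and intensity inhomogeneity. Passing the suite therefore
demonstrates correctness of the numerics and conventions, not robustness
to every acquisition artefact; the image-quality module exists precisely
to characterize real inputs before trusting downstream numbers.

## Problem sizes

The validation suites run at desk scale by choice: orientation recovery on
eight 128³ phantoms (40 fibers, radius 3 voxels, CNR 5), the isotropic
cosine-law check on a 96³ phantom with 400 thin fibers, density recovery
on a 200 × 120 × 120 phantom with a 2→12 % linear profile, SLS recovery on
a 12-point grid (E₀ ∈ {1, 2, 4} MPa, E∞/E₀ ∈ {0.3, 0.6}, τ ∈ {20, 60} s),
20 band-limited 48³ phantoms for the resolution estimator, and a 4-million
sample Monte-Carlo chord oracle for the dose model.
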