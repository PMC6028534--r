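---
title: "Quantitative mapping of Condensins on mitotic chromosomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative mapping of Condensins on mitotic chromosomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensinmap)
```

# Scope

`condensinmap` implements the quantitative-imaging computations needed to
map SMC complexes (Condensins I and II) on mitotic chromosomes in human
cells: absolute protein counting from calibrated confocal stacks, exchange
kinetics from half-plate FRAP, chromatid-axis geometry from STED
super-resolution stacks, localization clustering and spacing statistics,
whole-cell chromatid-length estimation, and the arithmetic that converts
subunit censuses into genomic and physical loop-spacing tables. Every
stage has a synthetic-data generator with known ground truth, so the whole
pipeline is testable without microscopy data.

# Units and conventions

All physical coordinates are nanometers at voxel centers (1-based index
`i` maps to `(i - 0.5) * voxel_size_nm`); volumes are µm³ and
concentrations nM. The single unit-conversion constant is

$$N = c\,[\mathrm{nM}] \times V\,[\mu m^3] \times 10^{-24} N_A
    \approx 0.6022 \; c V$$

molecules per nM·µm³, tested against closed-form cases.

# Protein counting from calibrated images

Fluorescence intensity is converted to concentration through a linear
calibration measured by fluorescence correlation spectroscopy (FCS):
`conc = slope * (intensity - background)`. The calibration line is fitted
by iteratively reweighted robust regression (`MASS::rlm`), so a minority
of outlying calibration points does not tilt the factor; exactly
collinear input degenerates M-estimation and falls back to ordinary least
squares, which is exact there. Negative calibrated concentrations (noise
below background) are floored at zero — the flooring decision is recorded
on the result because the alternative (allowing negative bound pools)
propagates unphysical counts.

Compartments come from two nested masks: the cell volume and the
chromatin volume; the cytoplasm is their set difference. Volumes are
voxel counts times voxel volume — no surface meshing, which keeps the
estimator simple and exactly testable on ellipsoid phantoms.

The chromatin signal mixes chromatin-*bound* protein with protein that
merely diffuses within the chromatin volume. The correction depends on
the phase of mitosis, supplied as an explicit label:

* **NEBD to anaphase** (open nuclear envelope): the free pool inside
  chromatin has the cytoplasmic concentration, so
  $[Chr]_c = [Chr] - [Cyt]$, $N^c_{Chr} = [Chr]_c V_{Chr} N_A$, and the
  soluble count adds the free pool inside the chromatin volume,
  $N_{Cyt} = ([Cyt]V_{Cyt} + [Cyt]V_{Chr}) N_A$. Bound plus soluble
  exactly partition the whole-cell count (tested as a conservation law).
* **Prophase** (closed envelope): a binding equilibrium is assumed with
  $K_d = [Cyt]^{meta} / [Chr]_c^{meta}$ estimated from a metaphase cell
  of the same experiment; then $[Chr]_{bg} = \frac{K_d}{1+K_d}[Chr]$ and
  $[Chr]_c = \frac{[Chr]}{1+K_d}$.
* **After nuclear-envelope reformation**: no equilibrium constant is
  measurable; only the total nuclear count is reported.

The synthetic cell generator builds nested ellipsoids, a free pool of
known concentration, and a bound pool of known copy number, rendered
through the same affine calibration with Poisson photon noise (scaled by
`photons_per_intensity`) plus Gaussian read noise — a qualitative match
to photon-counting detection with all parameters exposed. Parameter
recovery is tested noise-free (within 0.5%) and under realistic noise
(within 5%).

# FRAP exchange model

Half of the metaphase plate is bleached; per frame, the DNA-weighted mean
protein intensity is computed in the bleached and unbleached halves along
the chromatin's major 2D axis (principal axis of the mask's second
moments, oriented deterministically), excluding a 14-pixel gap around the
bleach boundary. The readout is the normalized difference between the
halves. We normalize the per-frame *contrast*
$(F_{ub} - F_b)/(F_{ub} + F_b)$, anchored to 1 at $t = 0$: a
multiplicative photobleaching factor common to both halves then cancels
exactly (verified by injecting an exponential decay in the round-trip
test), and without bleaching this coincides with dividing by the initial
difference alone. The readout follows the two-state exchange model

$$d(t) = a + (1 - a)\, e^{-(\kappa + k_{off}) t},$$

where $a$ is the immobile fraction and $\kappa = k_{on} B$; only the
combined rate is identifiable, with residence time
$\tau = 1/(\kappa + k_{off})$. Fitting uses Levenberg-Marquardt
(`minpack.lm::nlsLM`) initialized at $a = 0.5$, rate 1/min, with loose
box constraints; a fitted $a$ outside $[0,1]$ is clipped and flagged
rather than silently accepted. Uncertainty comes from bootstrap over
cells (resample cells with replacement, refit the pooled data, 300
resamples by default). The fraction of the mobile pool exchanged by time
$T$ is $(1-a)(1-e^{-T/\tau})$; for the fast regime
($\tau = 2$ min, $a = 0.15$) this evaluates to ≈0.84 at 10 minutes.

Simulated acquisitions default to 40 frames at 20-s intervals, matching
typical half-plate bleach series, with i.i.d. Gaussian noise of SD 0.03
on the normalized scale — about the scatter of per-cell difference curves
in such experiments. The benchmark regimes ($\tau = 2$ min / $a = 0.15$
vs. $\tau = 6$ min / $a = 0.65$) are separated with non-overlapping
bootstrap interquartile ranges at 20 cells each. Note one caveat the
tests quantify: with per-frame noise the nonlinear fit carries a small
(~1%) bias, so the very tight bootstrap IQR of pooled fits does not
necessarily bracket truth; recovery is asserted at the few-percent level.

# Chromatid-axis geometry from STED stacks

STED acquisitions here are laterally super-resolved only (2D depletion),
with 20-nm xy pixels and 140-nm z steps. Preprocessing (i) removes
slice-to-slice drift — estimated as a pure translation by normalized
cross-correlation with parabolic sub-pixel refinement, a deliberate
simplification of full rigid registration since inter-slice drift in
these short acquisitions is translational; (ii) linearly interpolates z
to an isotropic 20-nm grid; (iii) applies a σ = 0.5 voxel Gaussian.

The centerline tracer works in two passes: cross sections orthogonal to
the principal eigenvector of the segmented voxel cloud at 100-nm
spacing give coarse centroids; the coarse polyline is then resampled at
20 nm and each point re-centered on the centroid of a thin orthogonal
slab, so slicing follows local curvature. Three numerical details
matter. Terminal coarse bins cut the tube obliquely and are clipped by
the volume ends, so they are dropped and the tips recovered by walking
outward along the end tangents until the slab empties. Voxel
quantization makes raw slab centroids wobble by a few nanometers, which
would inflate the polyline length quadratically; a 5-point moving
average removes the wobble without flattening 20-nm-scale curvature.
Masks without a dominant axis (aspect ratio < 2) are rejected. Straight
tubes are recovered to one fine step; quarter-circle arcs to within
2.5% of $\pi r/2$; the trace is rotation-invariant within 2%.

Widths are measured in 2-µm sliding windows shifted by 200 nm: cross
sections accumulate, are sum-projected along z to a 1D lateral profile,
and the FWHM is read by linear interpolation at the half maximum after
subtracting the profile's tail median (without that subtraction, any
offset biases FWHM upward). Windows whose profile never crosses the half
maximum are skipped. A Gaussian tube of σ = 100 nm yields
FWHM $= 2\sqrt{2\ln 2}\,\sigma = 235.5$ nm to well within 2%.

Radial distributions accumulate all cross sections into one 2D image,
find the reference point maximizing total intensity in a window 0.4× the
chromatid width laterally and 0.6× axially, take the lateral profile
through it, and symmetrize by averaging left and right halves.
Containment radii treat the symmetrized profile as a radially symmetric
2D distribution (mass element $f(r)\, r\, dr$), truncated at the
chromatid radius. The end trim applied before these measurements
defaults to zero here and is exposed (`end_trim_nm`); chromatid ends are
structurally atypical and a window half-length (1 µm) is a reasonable
choice on real data.

# Colocalization

High-density segmentation combines a global Otsu threshold with a local
mean threshold in a 9×9 in-plane window (AND), which curbs both over-
and under-segmentation of dense spot fields. The nonoverlap percentage
is defined symmetrically,
$100\,(n_A + n_B - 2 n_{AB})/\sqrt{n_A n_B}$: 0% means identical masks
and fully disjoint equal masks give 200%. The per-channel reading
$100\,(n_A - n_{AB})/n_A$ is also reported; on synthetic two-color data
in which 18% of spots coincide, the per-channel nonoverlap lands at
~82%, whereas the symmetric statistic reads ~164% — the two definitions
answer different questions and both are exposed. Normalized
cross-correlation is the Pearson correlation of the two intensity
channels over the union of positive voxels; per-channel mean subtraction
keeps offsets from masquerading as correlation.

# Spot detection, clustering and spacing

Per-slice detection follows the standard single-molecule pipeline: an
à-trous B-spline wavelet decomposition separates a pixel-noise plane
(F1) from a band-pass plane (F2) in which spot-sized structures peak;
local maxima of F2 above 3·SD(F1) become candidates (this rule gives
essentially zero false positives on pure noise — tested at ≤1 per
megapixel); each candidate is refined by a least-squares
integrated-Gaussian fit (σ initialized at 2.2 px, fit radius 2 px),
reaching sub-10-nm localization at SNR 10. The wavelet `scale`
parameter should match the spot footprint in pixels; kernel-sampling
conventions differ between tools, and with this package's
parameterization scale 2 reproduces the classic 5-tap à-trous kernel
appropriate for 1-2 px PSFs.

Detections from adjacent z slices of one emitter are merged by DBSCAN
(`eps = 45`, `minPts = 2`) in a scaled space where z is compressed 8×
to reflect the ~8× poorer axial resolution: same-emitter neighbors 140 nm
apart in z sit at 17.5 scaled nm and merge, while complexes ~56 nm apart
along the axis stay distinct. Coordinates are nm by default
(`coord_unit_nm` rescales); note that interpreting `eps = 45` in
20-nm-pixel units instead would collapse every localization on a
chromatid into one cluster, contradicting the per-µm densities these
data show. DBSCAN noise points are kept as singleton clusters — an
isolated detection is a valid single complex — and the visiting order is
lexicographic in the coordinates, making clustering independent of input
row order. Clusters brighter than the single-complex intensity unit
(default 3,000 AU) count as
$\max(1, \lceil I/3000 \rceil)$ complexes.

Three distance readouts are computed from cluster centroids: nearest
neighbor (in the scaled space by default), distance from the chromatid
axis, and axial spacing — successive differences of the sorted
arc-length projections onto the axis. Uniform random placements
reproduce exponential spacings (KS test); a 56-nm truth spacing with
realistic lateral scatter (σ = 110 nm, matching the observed ~115-130-nm
axis distances) and 10-nm localization jitter is recovered to within a
few percent. A caveat quantified by the tests: at this density,
emitters placed *exactly on* the axis are closer than the
lateral resolution limit, and image-based per-slice detection then
merges neighbors; the lateral scatter present in real data is what
makes them separable.

# Whole-cell chromatid length

Total chromatid length per cell is extrapolated from a few manually
segmented stretches: each region's central-axis length (farthest
boundary pair sets the slicing direction; 50-nm cross-section centroids
form the axis) is multiplied by the ratio of total background-subtracted
signal in the DNA volume to the region's signal, and regions are
combined by arithmetic mean. The estimator is exactly unbiased when
signal per unit axis length is uniform — an identity the tests assert to
machine precision — and its bias under local intensity differences is
quantified: a region twice as bright as average yields an estimate of
$(1+f)/2$ of truth, where $f$ is the region's intensity fraction.
Background is estimated from a rim around the object (diamond dilation
radius 9 minus erosion radius 7 on the slice with most object voxels),
averaging rim intensities after discarding the lowest 10% and highest
50%; an object touching the border falls back to a global low
percentile, flagged. Channel alignment is an integer-voxel
cross-correlation search in a 350 × 350 × 600-nm neighborhood. A
synthetic cell of 128 straight tubes with uniform intensity per length
is recovered within 5% from 4 sampled regions.

# Loop-spacing arithmetic

The census of chromosome-bound subunit copy numbers per phase (SMC4,
CAP-D2, CAP-H, CAP-D3, CAP-H2; totals per replicated genome with SDs)
and total chromatid-axis lengths ships as a plain-CSV fixture. With the
genome model — 7.9 Gb hypotriploid genome, ~64 chromosomes, replicated
into 128 sister chromatids of 123.4 Mb — `build_loop_table()` derives,
for each subunit and phase: counts per chromatid, per µm of axis and per
Mb; mean genomic spacing $2 \times 7.9\,\mathrm{Gb} / N$ under the
equidistant-spacing assumption; and mean physical spacing
$L_{axis}/N$. The kleisins (CAP-H, CAP-H2) close the pentameric ring and
are treated as limiting for holocomplexes, so the combined kleisin pool
bounds the number of loop-extruding complexes; under the one-complex-
per-loop-base assumption the Condensin II loop size is the CAP-H2
genomic spacing (~434 kb in prometaphase) and the combined subloop size
the combined-kleisin spacing (~87 kb). Reported tables round to one
decimal for kb/nm and integers for counts (raw values are retained);
every derivable cell of the packaged census is regression-tested at that
printed precision for all three phases.

# Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure* each analysis
assumes: two-compartment concentration geometry with photon noise;
exchange-model recovery trajectories; tube-like chromatids decorated
with point emitters under an anisotropic Gaussian PSF (σ_xy 30 nm STED /
100 nm confocal, σ_z 250 nm; radial-Gaussian DNA tube, making FWHMs
analytically checkable); and two-color spot fields with a controlled
coincident fraction. They do not attempt optical simulation beyond
Gaussian PSFs, camera-specific noise calibration, chromatin texture, or
mitotic progression dynamics. Passing tests therefore demonstrate
correctness of the estimators under their stated assumptions, not
robustness to every real-data artifact (uneven labeling, fixation
effects, overlapping chromatids). SiR-DNA channel noise characteristics
are not modeled beyond the exposed parameters.

# Problem sizes and determinism

Test and acceptance runs use deliberately compact problem sizes — cells
of ~50k voxels, chromatids of 2-4 µm, 20 cells per FRAP regime, 3
chromatids for spacing statistics, 128 tubes for the length estimator —
chosen so each property is tested with adequate statistical power while
the whole suite stays fast. All stochastic steps take explicit seeds;
regenerating with the same seed is bit-identical, and the acceptance
script derives all of its sub-seeds from one command-line seed.
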