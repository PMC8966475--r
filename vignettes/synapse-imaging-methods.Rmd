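---
title: "Methods: quantitative imaging of the cytotoxic T-cell synapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative imaging of the cytotoxic T-cell synapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapseflow)
```

When a cytotoxic T lymphocyte (CTL) meets a stimulatory surface it builds
an immune synapse: the cell spreads, actin flows centripetally, lytic
granules traffic toward the membrane along microtubules, and the cell
pulls measurably on its substrate. `synapseflow` implements the
measurement chain for each of these behaviours, plus a synthetic-scene
generator so every stage can be validated by recovering known parameters.
This vignette records the models, the parameters that matter, the
numerical choices, and what the green test suite does and does not
establish.

## Conventions

Rasters are `H x W (x T)` arrays with row-major, 0-based pixel indexing in
physical units: a pixel's position is its center and position (µm) =
index × `pixel_size`. `x` runs along columns, `y` along rows. All
intensities become doubles on read; the source bit depth is recorded but
derived outputs are floating point. Tabular outputs are plain CSV with a
one-line header (tracks: `track_id, frame, t_s, x_um, y_um`). TIFF I/O is
a minimal built-in reader/writer for uncompressed grayscale baseline
TIFF, because no TIFF package is assumed; it round-trips `float64`
losslessly and reads 8/16-bit integer and 32/64-bit float data in either
byte order.

## Cell footprint and spreading kinetics

IRM shows the contact footprint as a dark patch. `segment_cell()` runs a
Canny detector (Gaussian σ = 1.4 px; borders replicate-padded so the frame
edge generates no spurious gradients), seals the contour by
dilate–fill–erode with a disk of radius 5 px, and keeps the largest
connected component. Two automatic choices matter:

* **Thresholds.** The high hysteresis threshold is Otsu's threshold on
  the gradient magnitude (a fixed percentile fails when the edge-pixel
  fraction varies with cell size); low = 0.4 × high. Both can be
  overridden. A frame whose high threshold is less than 4× the median
  gradient magnitude has no edge contrast and raises a `no_cell` error —
  a blank frame must fail loudly, not segment noise.
* **Digitisation bias.** The filled region includes the outer half of the
  edge line (≈ +0.5 px of radius). The reported area is the mean of the
  mask area and its 1-px-eroded area, which removes the bias; across
  disks of radius 20–100 px at SNR ≥ 10 the area error stays below 3%.

Non-maximum suppression interpolates the gradient magnitude along the
true gradient direction (bilinear between the two flanking pixels).
The quantised 4-sector variant punches multi-pixel holes into contours
near 22.5° orientations, which no closing radius reliably heals.

Spreading follows `A(t) = A0 tanh(α (t − t_contact))`. `fit_spreading()`
profiles `A0` out linearly, leaving a 1-D golden-section search in
`log α` — no starting values, and a zero-residual series is recovered to
~1e-8 relative error. `t_contact` defaults to the frame *before* the
first exceedance of 5% of the maximal area: the model has
`A(t_contact) = 0`, so the first frame already above 5% is systematically
one frame late. It can instead be fit as a free offset
(`fit_t_contact = TRUE`). Constant series make α unidentifiable and raise
an error rather than returning a default.

For fixed-cell actin images, the mask is eroded by a disk of radius
0.3 × the cell radius to split center from annulus. Masks are not
circular, so "the radius" is the equivalent circular radius
`sqrt(area/π)` — a declared convention, not the only possible reading.
The published quantity is the ratio of mean fluorescence intensities
(MFI = total intensity / pixel count); the raw total-intensity ratio is
reported alongside. The partition is exactly conservative
(`|center| + |annulus| = |cell|`), and the MFI ratio is invariant under
positive rescaling of the image.

## STICS flow mapping

For each 16 × 16-px subregion (shifted by 4 px) inside the mask and each
sliding time-of-interest window (20 s / 2 s shift for actin; 60 s / 6 s
for myosin), the normalized spatial cross-correlation between frame pairs
separated by lags 1..5 is computed by FFT after subtracting the TOI-mean
image (the immobile filter). The correlation-peak displacement versus lag
time, fit by least squares through the origin, gives the velocity;
vectors are rejected when the lag-1 peak falls below 0.2 × the lag-0
peak or the peak leaves the central half of the subregion.
Directionality is the cosine of the angle between a vector and the line
from its subregion center to the cell center (the centroid of the
maximum-spread mask, fixed across TOIs); directionality > 0.9 defines
inward flow.

Sub-pixel peak localisation is a per-axis 3-point log-parabola, exact for
a Gaussian-shaped peak of any width. A 2-D log-Gaussian fit over a 5 × 5
window was rejected: immobile-filtered correlation maps have negative
side lobes, the log fit then silently degrades to a centroid, and the
centroid is biased toward the integer peak (~35% speed underestimates in
testing).

**Resolvable regime.** With the actin settings (1-s frames, 0.1067 µm/px,
PSF σ ≈ 1.3 px) a flow must displace the pattern by clearly more than the
PSF within one TOI to survive the immobile filter. Flows ≥ ~2 µm/min are
recovered within a few percent; below ~1.5 µm/min the TOI-mean carries a
smeared copy of the speckle pattern whose subtraction repels the
correlation peak outward, biasing speeds up. This is a property of
immobile-filtered STICS, not of this implementation (it persists across
lag ranges and estimators). The tests therefore probe linearity at
2 → 4 µm/min; the generator's aliasing guard caps per-frame displacement
at a quarter subregion.

## Particle tracking

Detection is a scale-normalised Laplacian-of-Gaussian filter at
σ = (diameter/2)/√2 with strict 8-neighbourhood maxima above a quality
threshold and per-axis quadratic sub-pixel refinement (the default
threshold 0.5 mirrors the usual spot-detector setting; its absolute
meaning is detector-specific and it is exposed as a parameter). Comet
anisotropy of microtubule plus-end markers is ignored: the tip position,
not the comet shape, feeds the speed statistic.

Linking is greedy global-minimum-cost nearest-neighbour (cost = squared
distance) under a hard 0.6-µm gate, then gap closing joins a track end to
a later track start within 0.6 µm and ≤ 2 missing frames, iterated until
no join remains; tracks spanning < 2 s are discarded. A Hungarian/LAP
assignment option was considered and dropped: no LAP solver is available
in the supported dependency set, and on the contract scenes
(inter-particle spacing > 5 × the gate) greedy and optimal assignment
coincide. Dense, ambiguous scenes are the known limitation.

Instantaneous speed is the inter-frame displacement divided by the frame
interval, defined only for consecutive-frame pairs; pairs spanning a
closed gap are excluded.

## Granules

Frames are thresholded at 1.5 × the mean in-cell intensity — the
multiplier is a declared convention (only "based on the mean, automated"
is stated for the original pipeline); because the threshold is relative,
counts and area fractions are invariant under intensity rescaling, and
photobleaching or expression differences cancel. Components under 3 px
are discarded; clumps are not watershed-split (the published counts are
of "granules or clumps"). The cell edge comes from the maximum-intensity
projection of the movie. Each component's radial position is the distance
from the cell centroid to the component centroid divided by the distance
to the mask boundary along the same ray (marched in 0.25-px steps), so
position 1 is the cell edge even for irregular masks. Five equal bins
summarise area fraction (bins sum exactly to the frame's total, a tested
invariant) and mean component MFI.

## MSD and motion classes

Per-track time-averaged MSD over all frame pairs `n` apart whose interval
contains no closed gap. The first `ceil(0.25 × n_lags)` lags — "first 25%
of the curve" is read as 25% of available lags — are fit by OLS of
`log MSD` on `log lag`; the slope is α, the intercept `log B`, and r² is
computed on the same log-log points because that is the space the fit
lives in. Fits with r² ≤ 0.8 are rejected with a reason, as are curves
with a zero MSD inside the window. α > 1.2 is super-diffusive, α < 0.8
sub-diffusive; the boundary values themselves — left open by the strict
published inequalities — are assigned to "normal" (a measure-zero
choice). The ensemble MSD averages per-track MSDs at each lag and reports
the contributing-track count.

## Traction force microscopy

Displacements are estimated by normalized cross-correlation of 32-px
reference templates against the deformed image within ±16 px on a
template/2-spaced grid, with per-axis quadratic sub-pixel refinement. The
NCC normalisation varies with shift, so even a self-match carries a
~0.05 px sub-pixel residual; rigid integer shifts are recovered exactly
at the integer level.

The inversion is regularized Fourier-transform traction cytometry with
the Boussinesq kernel of a semi-infinite, homogeneous, isotropic,
linear-elastic half space,

$$ G(k) = \frac{2(1+\nu)}{E\,k}\left[(1-\nu)\,I + \nu\,(I - \hat k \hat
k^T)\right], $$

diagonalised per wave vector into longitudinal and transverse responses.
`T(k) = (G² + λ² s² I)^{-1} G u(k)` with `s` the largest kernel
eigenvalue on the grid, making λ (default 1e-4) dimensionless — the
convention of regularising the normalized operator, since λ's units
otherwise depend on operator scaling. The zero-frequency mode is set to
zero: the recovered field carries no net force, which is why synthetic
scenes use balanced (ring) tractions. Poisson ratio defaults to 0.5
(incompressible polyacrylamide). Gel thickness is stored as metadata but
the kernel is always semi-infinite: at gel heights of tens of µm against
displacement features of a cell radius (~7 µm), `kh ≫ 1` and the
correction is negligible, whereas a mis-stated finite-thickness factor
would not be. `forward_displacement()` is the same kernel run forward and
serves as the independent oracle for round-trip tests (relative L2 stress
error < 15% at λ = 1e-4 noise-free; error → 0 as λ → 0).

Forces integrate as Σ|T| × node area with 1 Pa·µm² = 1 pN = 1e-3 nN, a
unit-tested constant. Note the integral of |T| over a window smaller than
the field of view, computed from a coarse interior node grid, carries
spectral-leakage bias (~30% on the bundled scenes); the round-trip
criteria are therefore stated on the forward-oracle path, and the image
pipeline is held to monotonicity (Spearman ρ > 0.95 on amplitude ramps)
and the displacement-level RMS bound (< 0.2 px).

## The synthetic world

Every generator seeds a single global RNG (`set.seed(seed)`), so scenes
are bit-reproducible. Emitters are isotropic Gaussians with
σ = diameter/2.355 (FWHM convention, matching the detector's scale
assumption); noise is applied last. Defaults follow the imaging
conditions the pipeline targets: 0.1067 µm/px TIRF pixels, 1-s actin
frames, 5-s IRM frames, 15-s bead frames, ~1 kPa gels, spreading to
~300 µm² at α = 0.02 s⁻¹, 1-µm granules, 50 Pa ring tractions whose peak
bead displacement (~1.5 px) sits inside the recoverable window of the
±16 px search. Speckle emitters are permanent by default: an explored
turnover option (`lifetime_s`) remains available, but turnover's number
fluctuations inflate the non-negative median recovered speed far more
than the immobile-filter smear it removes — with turnover a static scene
reads ~0.8 µm/min, without it, zero.

What the generators do **not** emulate: optical aberrations, uneven
illumination, camera gain structure, emitter photophysics beyond
presence/absence, 3-D motion and defocus, cell-shape irregularity beyond
low-order boundary roughness, and spatially correlated noise. A green
suite therefore establishes that each estimator recovers the parameters
of its own stated model at realistic SNR — not that it is robust to every
artifact of real microscopy.

## Degenerate inputs, ties, tolerances

Blank or constant frames: `no_cell` errors. Empty detection tables: empty
track sets, not errors. Single-point tracks, short MSD windows, zero MSD
at fitted lags: explicit rejections with reasons. Correlation-peak ties:
first maximum in column-major order (measure-zero under noise).
Statistical tests are two-sided by default; the Wilcoxon wrapper uses
exact enumeration for n ≤ 10 without ties, the KS wrapper the exact small-
sample distribution where R provides it (the plain asymptotic formula is
conservative at n ≈ 50, with type-I error below 0.03). Monte-Carlo
calibration checks run 1000 simulations under fixed seeds and accept
[0.03, 0.07] at nominal 0.05.
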