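---
title: "Measuring primary cilium length in confocal Z-stacks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring primary cilium length in confocal Z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliometry)
```

## The measurement problem

Primary cilia are single microtubule-based protrusions, typically 1–9 µm
long depending on cell type, whose length modulates mechano- and
chemo-sensing. Lengths are usually read off confocal Z-stacks of
immunofluorescently stained cells. The difficulty is orientation: a cilium
lying in the imaging plane ("flat") is fully visible in one or a few
optical sections, but most cilia protrude at an angle ("angled"), and a
length measured on the maximum intensity projection (MIP) of an angled
cilium is only the *projection* of the true length — an underestimate by a
factor of roughly `cos(elevation)`. Restricting analysis to flat cilia
avoids the bias per cilium but introduces a selection bias over the
population.

`ciliometry` implements three measurement methods on calibrated 8-bit
stacks (voxel sizes `dxy` in-plane, `dz` axial, both in µm):

* **MIP** — the Euclidean length of the operator's (or generator's)
  polyline on the projection: `a = Σ |Δp| · dxy`.
* **PyT** — the Pythagorean estimate `c = sqrt(a² + b²)`, where
  `b = (z_last − z_first) · dz` is the axial extent read from the first
  and last slice showing signal. Valid for *straight* cilia (constant
  slope along the length); for a single-slice cilium `b = 0` and PyT
  reduces exactly to MIP.
* **DAAS** — direct measurement on a "side view": a vertical plane through
  the volume along the cilium's in-plane direction, built by bilinear
  interpolation within each slice (`reslice()`), on which endpoints are
  picked (automatically here) and the length is summed
  anisotropy-aware: `Σ sqrt((Δs·ds)² + (Δz·dz)²)`.

Cilia are classified **FLAT** when their entire signal spans at most
`flat_max_slices` (default 4) slices, and **ANGLED** when it spans more.
The boundary is inclusive: a span of exactly 4 slices is flat.

## Agreement statistics

Methods are compared on the same cilia with:

* **ICC(A,1)** — two-way, single-measure, *absolute agreement* intraclass
  correlation, computed from the mean squares of the subjects × methods
  layout: `ICC = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)(MSC − MSE))`.
  The absolute-agreement variant is deliberate: it penalises the
  systematic offset that projection-based measurement introduces, which
  consistency variants (and Pearson correlation) ignore. No choice of SPSS
  model is documented for the original protocol this mirrors; ICC(A,1) is
  the only variant whose interpretation matches reading the value as
  agreement. Values are interpreted on the Landis–Koch scale
  (≤0.2 slight, ≤0.4 fair, ≤0.6 moderate, ≤0.8 substantial,
  >0.8 almost perfect; boundaries fall in the lower band to match the
  conventional strict inequalities).
* **Bland–Altman** — bias = mean of per-cilium differences, with 95%
  limits of agreement `bias ± 1.96·SD` (sample SD, n−1; the multiplier is
  configurable).
* **t-tests** — flat vs angled population means per method, Student's
  pooled-variance two-sided test (`var_equal = FALSE` switches to Welch).

## The synthetic generator

Real stacks of stained cilia come without ground truth, so validation
uses rendered cilia of known geometry. A cilium is modelled as a 3D line
segment with constant linear intensity density (uniform staining, no tip
brightening), convolved with a separable anisotropic Gaussian PSF. The
convolution has a closed form — a Gaussian in the perpendicular offset
times an erf difference along the axis — normalised so the mid-segment
on-axis intensity equals the configured `amplitude`. Background is added,
optional Gaussian noise drawn (seeded, hence reproducible), and the volume
is clipped to [0, 255] and quantised to 8-bit.

Defaults (chosen once as realistic confocal-export conditions, with units):

| parameter | default | meaning |
|---|---|---|
| `dxy` | 0.1 µm/px | in-plane pixel size (63× oil objective scale) |
| `dz` | 0.25 µm | Z-step; the standard step size used throughout |
| `psf_sigma_xy` | 0.1 µm | lateral PSF sigma |
| `psf_sigma_z` | 0.3 µm | axial PSF sigma (≈3× lateral, typical confocal) |
| `amplitude` | 180 | peak 8-bit signal above background |
| `background_level` | 10 | constant background |
| `noise_sd` | 8 | additive Gaussian noise (0 for geometry tests) |

Annotations returned by the generator are *analytic*: exact projected
endpoints and the slice span of the unblurred segment — ground truth is
independent of any detection step. Two identities make the generator an
oracle for the measurement methods: the true projected length is
`L·cos(elevation)` and the true axial extent is `L·sin(elevation)`.

`simulate_cohort()` renders the standard validation cohort: 31 flat plus
31 angled cilia (flat elevations U(0°, 8°), angled U(35°, 70°), so the
slice-span classifier reproduces the intended population of every cilium
at `dz` = 0.25 µm), true lengths from a normal with mean 3.2 µm and SD
0.7 µm truncated to [1.8, 5] µm. With `paired_lengths = TRUE` both
populations receive the *identical* length vector, so any flat-vs-angled
difference a method reports is attributable to the method alone.

What the generator does **not** emulate: curved or irregular cilia (the
PyT model assumes a continuous slope; irregular cilia need manual
tracking), depth-dependent PSF broadening, photobleaching through the
stack, Poisson photon statistics (available behind the noise model only
as a Gaussian approximation appropriate for gain-transformed 8-bit
exports), and neighbouring structures that could confuse endpoint
detection. Passing tests therefore demonstrate correctness of the
geometry and statistics pipeline, not robustness to every real-world
imaging artefact.

## Numerical choices

**Slice span ("appears in slice k").** A slice at height `k·dz`
represents the slab `[k·dz − dz/2, k·dz + dz/2)`; the segment appears in
slice `k` iff its z-interval intersects that slab. This nearest-plane
assignment quantises each end of the span to the closest slice, which is
unbiased; assigning by strict plane-intersection would floor the span and
systematically shorten `b`. The axial term uses the interval count,
`b = (z_last − z_first)·dz`: a cilium visible in exactly one slice has
zero axial extent (slice-count × dz would overestimate by one `dz`
systematically).

**PyT quantisation limit.** Both span ends round independently, so
`|b − L·sin θ| ≤ dz` and hence `|c − L| ≤ dz` (the estimate is
1-Lipschitz in `b`). At `dz` = 0.25 µm this is ±12.5% of a 2 µm cilium at
high elevation in the worst phase — an intrinsic resolution limit of the
method, not an implementation artefact. The package's property tests
assert exactly this bound. The same quantisation explains two observed
patterns: on *flat* cilia PyT agrees slightly less with DAAS than MIP
does (the spurious `b` of 0–0.75 µm adds noise), and the Z-step
robustness scan (below) degrades beyond ~0.4 µm steps.

**Z-step robustness scan** (`pyt_step_size_scan()`). One noise-free
cilium (3 µm, 45°) is rendered at a fine 0.04 µm grid, the stack is
resampled (linear interpolation along z) to each step in
{0.05, …, 0.80} µm, and PyT is measured from analytic annotations on each
resampled grid. Because the two span ends quantise independently,
single-acquisition pass/fail is erratic above ~0.3 µm — a step can pass
by coincidence of where the slice planes land. The scan reports the
largest step within 5% of truth; the accompanying tests also verify that
the *spread* across grid phases (re-acquisitions of the same cilium)
grows beyond 0.40 µm steps, which is the practically relevant breakdown.

**Automatic endpoints** (`auto_endpoints()`). Replacing the operator's
clicks needs care because the signal is blurred anisotropically
(`σz ≈ 3σxy`):

1. *Component*: pixels ≥ `intensity_lo` (default 55, the standard display
   window for these 8-bit exports; configurable because other data need
   other values), largest 8-connected component, background estimated as
   the median sub-threshold intensity.
2. *Axis*: per-column intensity centroids (per-row for strongly vertical
   streaks, when the z-extent exceeds twice the s-extent), weighted
   line fit. The transverse centroid of a Gaussian-blurred line lies
   exactly on the axis whatever the PSF anisotropy. Columns/rows whose
   total mass falls below 75% of the maximum are excluded — those are the
   end caps, where the transverse profile is skewed. (A principal axis of
   the blurred blob, or the most-distant pair of threshold or half-max
   pixels, is *biased*: the level set of an anisotropically blurred
   segment is elongated and rotated toward the more blurred direction —
   at 2 µm/45° its diameter overestimates the length by ~10%.)
3. *Tips*: the intensity profile along the fitted axis is sampled by
   bilinear interpolation and each end is placed where it crosses half of
   the background-corrected peak (never below `intensity_lo`), linearly
   interpolated between samples. The on-axis intensity of a blurred
   segment falls to exactly half its plateau at the true tip, so this
   localises the tips independently of the PSF width. The test-suite
   verifies recovery within 5% of truth over the whole noise-free
   validation grid (L ∈ [2, 5] µm, elevation ≤ 70°).

Degenerate inputs: a single bright pixel yields that pixel twice (length
0); of two disjoint blobs only the larger is measured; an image with no
pixel above `intensity_lo` is an error. Ties in component size are broken
by scan order, and endpoint pairs are returned ordered by `(s, z)`, so
the pipeline is fully deterministic for a fixed seed.

**Reslicing.** Columns are spaced at `dxy` (the original in-plane
resolution), rows are the original slices; samples are bilinear within
each slice only — the slicing plane contains the z-axis, so sample
z-coordinates coincide with slice positions and interpolation across z
would be gratuitous. Sampling at grid points is exact, so an axis-aligned
reslice reproduces the raw x–z plane bit for bit.

**Replicates.** The measurement protocol takes three measurements per
cilium and uses their mean; `average_replicates()` also reports the
replicate range as a QC quantity (repeated measurements of the same
cilium should agree within ~0.3 µm). With deterministic automatic
endpoints replicates are identical; `operator_sd` adds per-replicate
endpoint jitter when operator variability is to be emulated.

## Known limitations

* PyT inherits the `±dz` span quantisation; for cilia around 2 µm at
  elevations near 70° the error can exceed 5% at `dz` = 0.25 µm no matter
  how the span is chosen — the only remedies are finer Z-steps or DAAS.
* Straight cilia only. Curved or irregular cilia violate the PyT model
  and the single-axis assumption of the endpoint detector.
* The DAAS reslice direction comes from the annotation's in-plane
  endpoints; a grossly wrong annotation direction produces a plane that
  clips the cilium.
* Agreement statistics assume one length per cilium and method; feed them
  replicate means, not raw replicates.

## Problem sizes used by the test-suite

The validation grid runs 24 noise-free renders (4 lengths × 6
elevations); the cohort analysis renders 62 small per-cilium stacks
(31 + 31); the Z-step scan renders one cilium at a 0.04 µm grid and
resamples it 16 times. Each stack is rendered only over the cilium's
PSF-padded bounding box, so the whole suite completes in well under a
minute on one core.
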