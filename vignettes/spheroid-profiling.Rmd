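---
title: "Radial profiling and metabolic mapping of tumor spheroids: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial profiling and metabolic mapping of tumor spheroids: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroprofile)
```

## The measurement problem

A multicellular tumor spheroid a few hundred micrometres across is not a
homogeneous ball of cells. Diffusion limits on oxygen and nutrients carve
it into concentric microregions: a necrotic core, a quiescent middle
zone, and a proliferative edge. Immunofluorescence markers (macrophage
polarization markers CD80/CD206, proliferation Ki67, apoptosis CC3,
hypoxia HIF-1&alpha;/HIF-2&alpha;) and label-free metabolic readouts
(NADH/FAD autofluorescence) all vary along the radius, and that radial
structure — not the bulk mean — is the biology of interest.

`spheroprofile` turns single-spheroid microscopy images into radial
profiles and regional statistics. The pipeline is:

1. **QC** a field of view: find candidate spheroids, discard any that
   are clipped by the image border, touching a neighbour, or too
   irregular to profile.
2. **Profile** each accepted spheroid: segment it, find the mask
   centroid, cast `K` rays outward, sample `M` intensities per ray,
   average across rays, and min–max normalize.
3. **Partition** the profile into core/quiescent/edge blocks by size
   class and extract one value per microregion.
4. **Compare** regions and size classes with a two-way ANOVA and Tukey
   contrasts, and regress regional values on spheroid diameter.

A separate arm fits per-pixel biexponential models to TCSPC
fluorescence-lifetime histograms of NADH and maps the optical redox
ratio FAD/(FAD + NADH).

## Radial line profiles

Images are converted to grayscale (BT.601 luma for RGB input) and
resampled to a 200 × 200 working grid by exact area averaging — the one
resampling scheme under which a constant image stays constant and the
global mean is conserved, so thin bright rims are averaged rather than
aliased away.

Segmentation is deliberately simple and deterministic: Otsu threshold,
hole filling, largest 8-connected component, one 3 × 3 closing. The
centroid is the unweighted mean of foreground pixel coordinates. For a
non-convex mask the coordinate mean can fall outside the foreground; a
radial profile anchored there is meaningless, so such records are
flagged and rejected rather than silently profiled.

`cast_profiles()` casts `K = 20` rays at angles `2πk/K` (angle 0 along
the +column axis, counterclockwise; an `angle_offset` parameter rotates
the fan). Each ray ends at its own mask-boundary crossing — the first
march sample whose nearest pixel is background, refined by bisection —
so the shared normalized-distance axis runs from 0 at the centroid to 1
at the boundary for every ray regardless of physical length. `M = 80`
samples per ray are read by bilinear interpolation whose support is
restricted to in-mask pixels (weights renormalized): unrestricted
interpolation dilutes the outermost samples with background, biasing
edge-region values for every marker.

The mean profile is the column mean of the `K × M` matrix, and the
normalized profile is

$$x_i^{\mathrm{norm}} = \frac{x_i - \min_j x_j}{\max_j x_j - \min_j x_j},$$

which maps every non-constant profile onto [0, 1]. A constant profile
has no min–max range; it becomes an all-zero vector carrying a
`degenerate` flag (ranges below 10⁻¹² of scale count as constant, a
floating-point guard), and downstream statistics exclude flagged
records deterministically instead of propagating NaNs.

Interpolation accuracy is what limits profile fidelity. On noiseless
radially symmetric phantoms the mean profile recovers the analytic
curve to well under 2 intensity units out of 200 — provided the field
is representable: a cone-shaped field has an apex that bilinear
interpolation cannot express when it falls between pixel centers, so
the recovery tests centre their phantoms on a pixel. Fields whose
radial gradient at the rim exceeds ~5 intensity units per pixel run
into the irreducible half-pixel uncertainty of any discrete boundary.

## Geometry and quality control

Diameter is the equivalent-circle diameter `2·px·sqrt(A/π)`;
circularity is `4πA/P²` clipped to [0, 1]. The perimeter `P` is the
length of the 0.5 level set of the Gaussian-smoothed (σ = 0.8 px) mask
indicator, traced by marching squares: raw digital contours overstate
smooth perimeters by ~5% (pushing a perfect disk's circularity to
~0.90), while estimators tuned to disks understate polygon perimeters.
The smoothed level set gives a digitized disk circularity ≈ 0.98 and a
square ≈ 0.81 (analytic π/4 ≈ 0.785) with one estimator.

The QC flowchart replaces a by-eye triage with four deterministic,
parameterized tests, applied in order so each rejection carries its
first failing reason:

| test | proxy | default |
|---|---|---|
| detection | Otsu + hole fill + 8-connected components | `min_area_px = 200` |
| full view | no pixel within margin of an edge | `border_margin_px = 2` |
| touching | min pixel distance to any neighbour | `gap_px = 3` |
| croppable | padded square crop fits **and** circularity ≥ 0.4 | `pad_fraction = 0.15` |

The circularity floor exists to reject fused blobs. Note its limits:
two spheroids that merely overlap produce a fused region of circularity
~0.5–0.7, which passes the floor; the floor catches necked fusions and
grossly irregular debris. Overlap-merged pairs are instead suppressed
upstream — pairs that remain separate components are caught by the
touching test, and the synthetic QC study places touching pairs with a
2 px gap for exactly that reason.

Accepted spheroids are cropped to a square of side
`max(bounding box sides) × (1 + 2·pad_fraction)`, so downstream
downsampling to the square working grid introduces no aspect
distortion.

## Microregion partitioning and statistics

Spheroids are classified by equivalent diameter: ≤ 200 µm small,
201–400 µm large (the 200 µm boundary is inclusive to small; both
bounds are configurable), larger ones flagged out of range and excluded
from regional statistics. The profile's `M` points are split into three
contiguous blocks, centroid to boundary:

* small: 25% core, 50% quiescent, 25% edge;
* large: 60% core, 30% quiescent, 10% edge.

Core and edge sizes are `round(fraction·M)` and the rounding remainder
goes to the middle block, which preserves the core and edge fractions
exactly at `M = 80` (blocks 20/40/20 and 48/24/8). The default regional
value is the profile at each block's midpoint index — one discrete
point per microregion at its centralized location; a `block_mean` mode
averages whole blocks instead, for markers whose regional signal is
better summarized by an average (the two modes differ for non-monotone
profiles, e.g. quiescent-peaked markers).

`compare_regions()` fits the ordinary fixed-effects two-way model
`value ~ region * size_class` with `stats::aov` and reports
Tukey-adjusted pairwise contrasts of regions within each size class and
of size classes within each region (via emmeans), at α = 0.05. Tukey is
the only multiplicity correction applied — no additional FDR layer.
Zero-variance input is reported as degenerate rather than crashing.
`diameter_correlation()` is ordinary least squares of a regional metric
on diameter, reporting R², the two-sided slope p, and the slope.

A caveat the phantoms make visible: for markers that fade gradually to
background (core-high gradients), Otsu segmentation places the boundary
partway down the ramp, so the measured mask — hence diameter and the
normalized radius — is smaller than the physical spheroid. Edge-bright
and flat markers are measured essentially at truth. This is a property
of intensity-based masking of diffuse objects, shared by any
single-threshold workflow; size-class assignments for strongly
core-weighted markers should be read with it in mind.

## Fluorescence-lifetime fitting and the redox ratio

Each pixel of a TCSPC stack holds a photon-arrival histogram. The decay
model is

$$I(t) = I_0\,(A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}),$$

with τ₁ the short (free NADH) and τ₂ the long (protein-bound NADH)
component; amplitudes are reported normalized to A₁ + A₂ = 1 and the
A₁/A₂ ratio summarizes the free/bound balance. The mean lifetime is
amplitude-weighted, `τm = A₁τ₁ + A₂τ₂` (an intensity-weighted variant
is available behind a flag).

Fitting is bounded Levenberg–Marquardt least squares of the model plus
a constant background (clamped ≥ 0), with bounds τ₁ ∈ [0.05, 1] ns,
τ₂ ∈ [1, 6] ns encoding the free/bound NADH literature range. Weights
are Poisson-motivated `1/max(expected, 1)`: the fit is seeded with
data-based weights, then re-weighted twice by the fitted model.
Weighting by *observed* counts over-trusts bins that fluctuated low and
measurably biases the amplitude ratio at a few thousand photons per
pixel; model re-weighting removes that bias (at 5000 photons the median
A₁/A₂ relative error drops from ~14% to ~7%, and the mean-lifetime bias
from ~0.04 ns to ~0.001 ns on this package's own recovery
simulations). Several starting points are tried and the best Pearson
χ² kept, so a nearly mono-exponential decay — whose lifetime may sit in
the gap between the τ₁ and τ₂ bounds — cannot strand the optimizer.
Bins before the histogram peak are discarded and the axis re-zeroed
there; no instrument-response deconvolution is attempted, so fitted
lifetimes carry the usual small IRF-convolution bias of
tail-fit-without-IRF workflows. Histograms under the photon threshold
(default 100) and non-converged pixels are marked invalid rather than
erroring, and `fit_stack()` optionally sums each pixel's histogram
with its 3 × 3 neighbourhood first, trading spatial resolution for
photons.

Intensity images destined for the redox ratio are normalized by
detector sensitivity and excitation power:
`I_norm = I_raw / (g(gain) · P^e)`, with `g` interpolated log-linearly
between fluorescein-calibration points (no extrapolation — the curve is
steep and unsafe outside its range) and `e = 2` by default because
two-photon signal scales with the square of excitation power (`e = 1`
for one-photon data). The redox ratio is `FAD/(FAD + NADH)` per pixel,
bounded in [0, 1] and invariant to common scaling; pixels whose summed
signal falls below a floor (default 1% of the summed image's 99th
percentile) are background and marked invalid.

## The synthetic-data generators

Every stage is tested against generators that return a truth manifest
alongside the data, and all of them are pure functions of their
parameters and a seed.

* `make_spheroid_image()` draws a disk whose intensity is a chosen
  function of normalized radius (core-high `1−r`, edge-high `r`, flat,
  or custom) plus background and additive Gaussian noise — the
  read-noise-dominated model appropriate for widefield detection.
* `make_qc_field()` + `random_qc_layout()` build multi-spheroid fields
  with per-disk truth labels: interior isolated disks, border-clipped
  disks, and touching pairs separated by a 2 px gap. Layout diameters
  follow a lognormal spread (median 150 µm, log-sd 0.3), echoing the
  size dispersion of a real harvest.
* `make_decay_stack()` Poisson-samples expected biexponential curves
  per pixel (photon counting is Poisson by physics), optionally with
  distinct truth parameters in a central disk versus the surrounding
  annulus.
* `make_cohort()` simulates per-region normalized marker values from
  normal distributions; the default effect table
  (`macrophage_marker_effects()`) encodes reference CD80/CD206
  means and SDs per region and size class, and diameters are uniform
  within class bounds.

What the phantoms do **not** emulate — optical sectioning, PSF blur,
texture, spectral bleed-through, instrument response — bounds what
passing tests show: they validate the geometry, the estimators and the
statistics, not robustness to every optical artifact of real
microscopy. Cohort values are drawn unclamped (reference means sit
within ~1 SD of the [0, 1] boundary), so simulated regional values can
exceed [0, 1] where real normalized profiles cannot.

## Numerical choices, in one place

* Working grid 200 × 200; `K = 20`, `M = 80`; angle 0 along +columns.
* Ray boundary tie-break: first march sample (step 0.25 px) whose
  nearest pixel is background, bisected to sub-step precision.
* Degenerate profiles: all-zeros + flag; excluded downstream.
* Partition rounding remainder → quiescent block.
* Size boundary 200 µm inclusive to small.
* Perimeter: σ = 0.8 px smoothed 0.5-level marching-squares contour.
* Circularity floor 0.4; QC margins: border 2 px, gap 3 px, pad 0.15.
* FLIM: bounds τ₁ ∈ [0.05, 1], τ₂ ∈ [1, 6] ns; threshold 100 photons;
  3 × 3 binning; model-reweighted WLS, multi-start.
* Redox floor: 1% of the summed image's 99th percentile.
* Statistics: α = 0.05, Tukey within families, no extra FDR.

Test problem sizes (the package's choices for its own suite): recovery
studies use 200 × 200 phantoms, 8 × 8 to 24 × 24 decay stacks at
256 bins / 12.5 ns, 200 Poisson pixels per fitting condition, 100
seeded QC fields, 500 null ANOVA replicates, and 100 replicate cohorts
at n = 30 per cell.

## Worked example

```{r example, eval = FALSE}
library(spheroprofile)

# a 150 um edge-bright phantom with known truth
sim <- make_spheroid_image(diameter_um = 150, profile_shape = "edge_high",
                           peak_intensity = 180, background = 8,
                           noise_sd = 3, seed = 1)
rec <- profile_spheroid(sim$image)
rec
#> <spheroid_record> diameter 150.1 um (small), circularity 0.978

part <- build_partition(rec$size_class, 80)
extract_regions(rec$profile_set$normalized_profile, part,
                spheroid_id = "demo", marker = "CD80")
#>   spheroid_id marker size_class      core quiescent      edge     mode excluded
#> 1        demo   CD80      small 0.1145878 0.4946372 0.8798046 midpoint    FALSE
```

## Known limitations

* Single global Otsu threshold: diffuse core-high markers yield masks
  smaller than the physical spheroid (see above).
* Regions are defined on the 1-D radial axis only, as in the reference
  workflow — no 2-D region masks.
* No IRF deconvolution, phasor analysis, or three-component decays.
* No proprietary microscope formats (.sdt, .nd2, .lif), z-stacks, or
  time series; TIFF and CSV only.
* Float TIFF export is quantized to 16 bits (the R TIFF writer does not
  preserve out-of-range float values); lifetime and redox maps are
  exported as CSV by the CLI.
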