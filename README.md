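# spheroprofile

Radial intensity profiling and metabolic imaging analysis of
multicellular tumor spheroids, in R.

As a spheroid grows past a few hundred micrometres, diffusion limits
partition it into concentric microregions — a necrotic core, a
quiescent middle zone, and a proliferative edge — and fluorescence
markers (CD80/CD206 macrophage polarization, Ki67 proliferation, CC3
apoptosis, HIF hypoxia) as well as label-free NADH/FAD autofluorescence
vary along the radius. `spheroprofile` quantifies that radial
organization for people who image spheroids and want per-microregion
numbers instead of bulk means.

## What it computes

**Radial line profiles.** A field of view is QC-triaged (clipped,
touching, or irregular spheroids are rejected with logged reasons),
each accepted spheroid is cropped, resampled to a 200 × 200 working
grid by area averaging, segmented (Otsu + hole fill + largest
component), and profiled: `K = 20` rays are cast from the mask centroid
at angles `2πk/K`, each sampled at `M = 80` points from centroid
(normalized distance 0) to mask boundary (1). The mean profile across
rays is min–max normalized:

```
x_norm = (x − min(x)) / (max(x) − min(x))
```

**Microregion statistics.** Spheroids are classified by equivalent
diameter (≤ 200 µm small, 201–400 µm large) and the profile is split
into contiguous blocks — small: 25/50/25% core/quiescent/edge, large:
60/30/10% — with one representative value per region (block midpoint by
default, block mean optionally). Regions and size classes are compared
with an ordinary two-way ANOVA plus Tukey contrasts, and regional
values are regressed on diameter (OLS R², p, slope).

**FLIM and redox mapping.** Per-pixel TCSPC histograms are fitted with
the biexponential decay

```
I(t) = I0 (A1 e^(−t/τ1) + A2 e^(−t/τ2))
```

(τ1 short / free NADH, τ2 long / protein-bound NADH) by bounded
Levenberg–Marquardt least squares with model-based Poisson weights,
giving maps of amplitude-weighted mean lifetime, A1, and A1/A2.
Intensity channels normalized by detector gain (fluorescein
calibration) and laser power feed pixel-wise optical redox ratio maps,
`FAD/(FAD + NADH)`.

**Synthetic phantoms.** Generators with exact truth manifests
(`make_spheroid_image`, `make_qc_field`, `make_decay_stack`,
`make_cohort`) make the whole pipeline testable without any microscopy
data.

## Worked example

```r
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

The measured diameter (150.1 µm vs 150 µm truth) lands the spheroid in
the small class; the edge-bright marker's normalized intensity rises
from 0.11 at the core midpoint to 0.88 at the edge midpoint, as built
into the phantom. A lifetime fit on a noiseless synthetic decay
recovers its parameters exactly:

```r
h <- expected_decay_curve(0.8, 0.4, 0.2, 2.5, photons = 5000)
fit_pixel_decay(h, 12.5 / 256)
#> <biexp_fit> A1 = 0.800 tau1 = 0.400 ns | A2 = 0.200 tau2 = 2.500 ns
#>   mean lifetime 0.820 ns, A1/A2 = 4.000, reduced chi2 = 4.78e-31
```

End-to-end runs go through `run_pipeline(manifest, output_dir)` (CSV
manifest of images → QC reports, per-spheroid profile CSVs, regional
summary, ANOVA/Tukey and correlation tables, and a run manifest with
the effective configuration). A thin command-line front end with `qc`,
`profile`, `flim`, `redox`, `simulate`, and `run` subcommands lives at
`inst/cli/spheroprofile.R`.

## Vignette

`vignettes/spheroid-profiling.Rmd` documents the model and the
numerical choices: ray termination and interpolation, the perimeter
estimator behind circularity, partition rounding, fitting weights and
bounds, and what the synthetic phantoms do and do not emulate.
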