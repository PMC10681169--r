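---
title: "Quantifying spatial uniformity of lung particle deposition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial uniformity of lung particle deposition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungquad)
```

## The measurement problem

When fluorescent microspheres or recruited immune cells are imaged across a
whole lung lobe, the scientific question is rarely "how much signal is
there" but "how is it arranged": spread evenly through the parenchyma, as
happens when an aerosol is breathed in from an exposure chamber, or
concentrated in clumps around medium and large airways, as happens after an
intranasal liquid bolus. `lungquad` turns a calibrated whole-lobe
fluorescence image into a small set of spatial statistics that answer that
question reproducibly.

The chain is:

1. **Colour classification.** Each pixel is assigned to one of three
   classes — fluorescent particle signal, tissue, or peri-airway
   autofluorescence — by pure per-pixel rules in HSV space
   (`classify_pixels()`). Autofluorescence is an *exclusion* class for the
   particle signal (bright peri-airway tissue must never masquerade as
   beads) but still counts as tissue for coverage purposes.
2. **Quadrat quantification.** A square grid is overlaid
   (`quantify_quadrats()`); each cell records its particle signal and its
   tissue-coverage fraction, and only cells covering at least a threshold
   fraction of tissue enter the analysis. This prevents airway lumens and
   off-lobe background — which cannot contain deposited particles — from
   diluting the statistics.
3. **Dispersion statistics.** Over included cells, the index of dispersion
   $D = \sigma^2 / \mu$ and the coefficient of variation
   $c_v = \sigma / \mu$ are computed (`summarize_dispersion()`). Counts
   from complete spatial randomness are Poisson, for which $D = 1$;
   $D \gg 1$ indicates clustering and $D < 1$ spatial regularity. $D$ and
   $c_v$ react differently to rescaling the signal — $D$ scales linearly
   while $c_v$ is scale-invariant — which is why $D$, weighting extreme
   deposition more heavily, is the primary statistic and $c_v$ the
   corroborating one.
4. **Peri-airway proximity.** Airway lumens are delineated (annotation
   mask, or holes in the tissue mask via `derive_airways()`), an exact
   Euclidean distance transform is computed on the lumen complement, and
   the fraction of particle signal within a fixed radius (default 200 µm)
   of the nearest lumen pixel is reported (`proximity_fraction()`).
5. **Group comparison.** Per-specimen statistics are aggregated per
   exposure group and compared (`compare_groups()`), by Welch's *t* by
   default.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `microns_per_pixel` | — (mandatory) | µm/px | Stitched whole-lobe TIFFs carry no trustworthy resolution metadata; a silently guessed calibration would corrupt every µm-denominated threshold, so the package refuses to default it. |
| `cell_size_um` | 200 | µm | Operating point of the grid sweep (100/200/500 µm tested); large enough for stable counts, small enough to resolve clumps. |
| `coverage_threshold` | 0.90 | fraction | Operating point of the coverage sweep (0.50/0.75/0.90/0.98); excludes airway/background-dominated cells without discarding the lobe margin. |
| `radius_um` | 200 | µm | Peri-airway band width; "near an airway" is measured from the lumen boundary outward, not from the centroid, so airway caliber is not conflated with proximity. |
| `min_lumen_area_um2` | 5000 | µm² | Separates medium/large airways from alveolar-scale holes when lumens are derived rather than annotated. |
| `variance_convention` | sample (n−1) | — | Specimens are finite samples of cells; the convention is switchable and always recorded in outputs. |
| `delta` (pattern band) | 0.2 | — | Half-width of the Poisson-compatible band around D = 1 used by `classify_pattern()`. |

The default group test is Welch's two-sample *t* on per-specimen values:
unequal variances between delivery-route groups are not a nuisance here but
the expected finding (clustered deposition inflates the clustered group's
variance), which rules out the pooled-variance *t*. A permutation test on
the difference of group means is provided as a distribution-free
alternative; it enumerates all label assignments exactly when that is
feasible and otherwise uses seeded Monte-Carlo resampling.

## The synthetic scene generator

No whole-lobe image set ships with the package, so validation rests on a
generator (`generate_scene()`) that emulates the features of these images
that the statistics actually touch:

* a single rounded lobe silhouette (a radially perturbed disk) of tissue;
* non-overlapping elliptical airway lumens (eccentricity up to 2:1,
  matching the appearance of sectioned airways) punched through the tissue;
* a bright autofluorescent band hugging each lumen, since peri-airway
  autofluorescence is the main confuser for red particle signal;
* particles rendered as small disks (default radius 0.5 µm, i.e.
  1-µm-diameter microspheres, which at typical calibrations is a single
  pixel) placed under one of two regimes: **uniform** — complete spatial
  randomness over tissue pixels, the aerosol-chamber phenotype — or
  **clustered** — with probability `cluster_fraction` a particle lands
  uniformly on tissue within `cluster_range_um` of a lumen, otherwise
  anywhere on tissue. This is the simplest two-parameter model that
  reproduces peri-airway clustering with a *knowable* true peri-airway
  fraction, recorded in the scene alongside the truth rasters.

Choices made once and not revisited: the clustering length scale defaults
to 200 µm (the analysis radius; no independent length scale is available
for the clustered phenotype, so the generator ties the two); rendering is
noiseless by default, emulating minimally processed acquisitions —
robustness to additive intensity noise is exercised explicitly in tests at
sd = 4/255; intraluminal deposition (beads trapped inside airway lumens)
is available behind `intraluminal_fraction` but off by default so the
particles-on-tissue invariants hold.

What the generator deliberately does **not** model: airway branching trees,
physically realistic aerosol transport, optical point-spread functions,
stitching artifacts, and illumination gradients. Passing tests on synthetic
scenes therefore demonstrate that the *measurement chain* is correct and
calibrated (masking recovers known pixels, quadrat counts match brute-force
binning, D is 1 under true spatial randomness, known peri-airway fractions
are recovered); they cannot certify colour thresholds against any
particular microscope's palette — on real data the HSV ranges of
`color_model()` are the knobs to adjust, and every mask records the model
that produced it.

## Numerical choices and degenerate inputs

* **Grid arithmetic.** The cell size in pixels is
  `round(cell_size_um / microns_per_pixel)` with a floor of 1 px — a fixed
  rounding rule so outputs are bit-reproducible. Cells are half-open pixel
  intervals anchored at a configurable `origin_px` (image origin by
  default; the tissue bounding box is not used because the coverage
  criterion already absorbs anchoring effects). Partial edge cells are
  retained and judged by their actual pixel count; dropping them would
  bias the lobe margin.
* **Distance transform.** Exact Euclidean, via `EBImage::distmap`,
  verified in the test suite against brute-force nearest-lumen search.
  Square pixels are assumed throughout.
* **Undefined statistics are flagged, never coerced.** Zero included cells
  is an error ("no analyzable tissue"); mean-zero signal leaves D and
  $c_v$ `NA` with `defined = FALSE` (a silent 0 would fabricate perfect
  uniformity from empty tissue); a specimen with no detectable airway
  lumens yields an undefined proximity fraction, not 0.
* **Determinism.** Scene generation and rendering are seeded
  (`rng_seed`; the rendering noise substream is derived as `rng_seed + 1`
  so `render_channels()` reproduces a stored scene bit-identically), run
  configurations are fully serializable, and a pipeline run re-executed
  from its emitted `config.yaml` reproduces every output byte for byte.

## Validation problem sizes

The test suite validates the Poisson calibration on a simulated
8000 × 8000 µm lobe at 2 µm/px (about 1000 included 200-µm cells, mean
count ≈ 4), regime separation on twenty 3200 × 3200 µm scenes per regime
swept over all twelve grid-size × coverage combinations, and peri-airway
recovery at 1000 particles per scene, where binomial sampling error alone
is about ±0.015. These sizes give the dispersion estimator a standard
error (≈ √(2/n)) well inside the ±0.1 acceptance band around D = 1.

## Known limitations

* Colour classification is per-pixel and threshold-based; spectral overlap
  beyond what HSV ranges can separate (e.g. orange autofluorescence inside
  the particle hue range) requires retuning the model or supplying
  externally produced masks via `class_masks()`.
* `derive_airways()` is a topological heuristic (enclosed holes above an
  area floor). Collapsed airways or lumens touching the image border are
  missed; an expert annotation mask, when available, always takes
  precedence.
* Signal is quantified as mask area by default. With non-saturated
  fluorophores and meaningful intensity dynamics, `intensity_sum` mode is
  available, but the two modes are only guaranteed interchangeable (up to
  an affine factor) on saturated signal.
* Anisotropic pixels and 3-D stacks are out of scope; the distance
  transform and grid assume square pixels in a single plane.

## A worked example

```{r example, eval = FALSE}
library(lungquad)

# one clustered (intranasal-like) specimen with known ground truth
cfg <- scene_config(width_px = 1500, height_px = 1500,
                    microns_per_pixel = 2, airway_count = 6,
                    particle_count = 1000, regime = "clustered",
                    cluster_fraction = 0.6, rng_seed = 101)
scene <- generate_scene(cfg)

masks <- classify_pixels(scene$image)
tab   <- quantify_quadrats(masks, scene$image, grid_spec(200, 0.90))
summarize_dispersion(tab)

airways <- derive_airways(masks$tissue, 5000, scene$image)
proximity_fraction(masks$particle, airways, 200, scene$image)
scene$true_periairway_fraction   # ground truth for comparison
```
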