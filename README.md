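# lungquad

Quadrat dispersion and peri-airway proximity analysis of whole-lobe lung
fluorescence images.

## The problem

Two common ways of delivering material to the mouse lung produce very
different spatial patterns: a whole-body **aerosol exposure chamber**
deposits particles evenly through the parenchyma, while **intranasal
instillation** concentrates them in clumps around medium and large
airways. The same contrast appears in the neutrophils recruited after an
inflammatory challenge. `lungquad` is for researchers who image whole
lung lobes by fluorescence microscopy and need a reproducible, auditable
answer to "is this deposition uniform or clustered, and how much of it
sits near the airways?".

## The method

Given a calibrated RGB image (microns-per-pixel is a mandatory input —
it is never guessed):

1. **Colour classification** — per-pixel HSV rules separate fluorescent
   particle signal, tissue, and the peri-airway autofluorescence that is
   excluded from particle signal but kept as tissue coverage.
2. **Quadrat analysis** — a square grid (default 200 µm cells) is
   overlaid; each cell records particle signal and tissue coverage, and
   only cells with ≥ 90% tissue coverage (default) are analyzed, so
   airway lumens and off-lobe background cannot dilute the statistics.
3. **Dispersion statistics** — over included cells the package computes
   the index of dispersion

   D = σ²/μ

   (D = 1 for Poisson counts, i.e. complete spatial randomness; D ≫ 1
   for clustering; D < 1 for spatial regularity) and the coefficient of
   variation c_v = σ/μ as corroboration.
4. **Peri-airway proximity** — airway lumens are taken from an
   annotation mask or derived as enclosed holes in the tissue mask; an
   exact Euclidean distance transform then gives the fraction of signal
   within 200 µm (default) of the nearest lumen pixel.
5. **Group comparison** — per-specimen statistics are aggregated per
   exposure group and compared with Welch's t-test (a seeded permutation
   test is available).

A synthetic lung-scene generator with full ground truth (tissue
silhouette, elliptical airway lumens, autofluorescent bands, uniform or
airway-clustered particle placement) backs the end-to-end validation in
the test suite. See `vignettes/methods.Rmd` for the model, parameter
rationale and limitations.

## Worked example

```r
library(lungquad)

# an intranasal-like specimen with known ground truth
cfg <- scene_config(width_px = 1500, height_px = 1500,
                    microns_per_pixel = 2, airway_count = 6,
                    particle_count = 1000, regime = "clustered",
                    cluster_fraction = 0.6, rng_seed = 101)
scene <- generate_scene(cfg)

masks <- classify_pixels(scene$image)
tab   <- quantify_quadrats(masks, scene$image, grid_spec(200, 0.90))
summarize_dispersion(tab)
#> dispersion_summary: n = 119 cells, mean = 5.924, sample variance = 35
#>   D = 5.908, c_v = 0.9986

classify_pattern(summarize_dispersion(tab))
#> [1] "clustered"

airways <- derive_airways(masks$tissue, 5000, scene$image)
proximity_fraction(masks$particle, airways, 200, scene$image)
#> proximity_result: 70.70% of signal within 200 um of airways (707 / 1000)
scene$true_periairway_fraction
#> [1] 0.707
```

The dispersion summary says the 1000 deposited particles are far from
spatially random (D ≈ 5.9 over 119 analyzable 200-µm cells), and the
proximity result shows 70.7% of the signal lies within 200 µm of an
airway — matching the scene's ground truth exactly. A uniform-regime
scene instead yields D near 1 and a peri-airway fraction equal to the
geometric share of tissue near airways (~26% for this geometry).

For a multi-specimen, two-cohort run that writes per-specimen quadrat
CSVs, a group report and an echoed, re-runnable configuration, see
`run_pipeline()`; a thin command-line front end lives at
`inst/cli/lungquad.R` (subcommands `simulate`, `analyze`, `run`).

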