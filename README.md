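# scact

Quantitative analysis of fluorescence microendoscopy images of
heterogeneous tissue: **s**parse **c**omponent **a**nalysis to separate
nuclei, muscle and adipose structure, followed by a **c**ircle
**t**ransform to detect overlapping nuclei and quantify their size and
density. The intended use is assessment of residual disease in tumor
margins, where nuclear density per 0.25 mm² separates tumor-bearing from
benign tissue, but any single-channel image with point-like, periodic and
curvilinear structure fits the model.

## The method

A preprocessed image `y` is modeled as a sum of tissue components, each
sparse in its own dictionary:

```
y = x_nuclei + x_muscle + x_adipose + w
    x_nuclei  = theta_1        (pixel basis: small, isolated nuclei)
    x_muscle  = F' theta_2     (whole-image DCT: smooth periodic fibers)
    x_adipose = C' theta_3     (curvelet-type frame: curvilinear outlines)
```

The coefficients minimize the l1-regularized least squares objective

```
1/2 ||y - theta_1 - F'theta_2 - C'theta_3||^2
    + tau_1 ||theta_1||_1 + tau_2 ||theta_2||_1 + tau_3 ||theta_3||_1
```

solved by gradient projection for sparse reconstruction (GPSR, compiled
core) with an ISTA reference solver for verification. A gradient-vote
circular Hough transform applied to the nuclear component detects
overlapping nuclei (centers, radii, scores); densities are reported per
0.25 mm² in total and split at 8 µm diameter into small/large
subpopulations. A synthetic phantom generator (tumor = random blurred
disks, muscle = longitudinal fibers, tumor+muscle = weighted composites at
contrast ratios 1.2–1.8) provides ground truth for validation, and the
evaluation module sweeps percent error of recovered density over nuclear
size, density and contrast. Cohort statistics (Wilcoxon rank-sum, ROC/AUC,
Youden index) compare image groups.

See `vignettes/scact-methods.Rmd` for the model, parameter and validation
details.

## Worked example

```r
library(scact)

# a tumor+muscle phantom at contrast ratio 1.5 with known ground truth
spec <- phantom_spec(nucleus_diameter = 10, density = 300, seed = 7)
ph   <- combine_tumor_muscle(simulate_tumor(spec), simulate_muscle(spec),
                             contrast_ratio = 1.5)
nrow(ph$truth)
#> [1] 54

dec <- sca_decompose(ph$pixels)       # pixel/DCT/curvelet separation
dec
#> sca_decomposition: 256 x 256 px, 26 iterations (converged), objective 216.256

det  <- detect_nuclei(dec$components$nuclei, detect_config(),
                      pixel_size = spec$pixel_size)
area <- prod(dim(ph$pixels)) * spec$pixel_size^2 / 1e6   # mm^2
compute_density(det, analyzed_area = area, size_cutoff = 8)
#> nuclei_stats: 54 nuclei in 0.04515 mm2 | density 299.0 /0.25 mm2
#>   (<=8 um: 299.0, >8 um: 0.0)

match_detections(det, ph$truth)$recall
#> [1] 1
```

All 54 simulated nuclei are recovered (recall 1.00), so the estimated
density of 299.0 nuclei/0.25 mm² sits within 0.4% of the configured 300.
The recovered diameters land below the 8 µm cutoff because soft
thresholding erodes disk flanks (a known small-bias, see the methods
vignette); density readouts are unaffected. `render_overlay()` draws the detections red/green at the
8 µm cutoff, and `run_pipeline()` chains the stages and writes component
TIFFs, a detections CSV, a statistics JSON, the overlay PNG and the
resolved configuration. `exec/scact` exposes the same stages as shell
subcommands (`simulate`, `preprocess`, `decompose`, `detect`, `quantify`,
`evaluate`, `run`, `stats`).

For simulation studies:

```r
tab <- sweep_error_surface(diameters = c(8, 12), densities = c(150, 300),
                           ratios = c(1.2, 1.8), replicates = 3, seed = 1)
aggregate(percent_error ~ diameter_px + ratio, tab, mean)
```

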