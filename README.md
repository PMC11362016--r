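# thymoquant

Quantification of age-related thymic remodelling from volumetric imaging,
single-cell expression and injury time courses.

The thymus involutes with age: the medulla fragments, and dense
peri-medullary clusters of age-associated thymic epithelial cells
("HD-TECs", detectable as compact GFP⁺ regions devoid of the ubiquitous
tdTomato reporter) emerge that are absent in young animals. `thymoquant`
implements the quantification machinery needed to measure this process and
validates it end-to-end on synthetic data with exact ground truth.

## What the package computes

**Region volumes from two-channel 3D microscopy.** Density-based
segmentation of lobe, medulla and HD regions: per-slice 2D median filter,
3D Gaussian filter in physical units, min–max normalization with a
fractional threshold, morphological closing, minimum component volume.
The cortex is defined by subtraction, so that

```
V_cortex = V_lobe − V_medulla − V_HD        (exact, on voxel counts)
```

**Whole-lobe cell counts.** Nuclei are detected with a
Laplacian-of-Gaussian blob detector (σ = d/2√3, anisotropy-corrected,
sub-voxel maxima), classified by signed distances to region surfaces —
medullary/HD if d ≤ 0 µm, subcapsular if the distance to the section edge
is ≥ −25 µm, cortical otherwise — and converted to densities
ρ = N/V. Counts for a whole lobe follow the paired-lobe estimator

```
N̂_region = ρ_region(sections, lobe A) × V_region(light-sheet, lobe B)
```

**Single-cell procedures.** The cell-QC rule (flag when more than one of:
low total counts, ≤ 1,000 genes, mitochondrial fraction ≥ 0.2),
cluster-level exclusion, counts-per-10,000 log1p normalization,
one-vs-rest Wilcoxon marker ranking (tie-corrected z, BH FDR ≤ 0.05, no
fold-change filter), top-n z-ranked signatures, reference-subtracted
signature scoring (expression-matched control genes), arg-max subset
mapping, scaled frequency change, and a Cdh1/Vim EMT axis.

**Injury-recovery statistics.** Recovery fraction relative to the
age-matched baseline, trapezoidal AUC over days 0–7 after irradiation,
and the aging index `AUC_aged / AUC_young` with a seeded percentile
bootstrap CI.

**Synthetic data with ground truth.** Seeded generators for image
phantoms (hard-sphere nuclei, Gaussian PSF, Poisson + Gaussian noise, at
light-sheet or confocal voxel spacings), negative-binomial count matrices
(markers, library sizes, mitochondrial fractions, low-quality cells,
doublets, planted contaminant clusters, two age conditions), and
depletion/recovery time courses with age-dependent recovery rates.

## Worked example

Generate an aged-type light-sheet phantom, segment its regions, count
nuclei in a section-style phantom, and combine the two in the paired-lobe
estimator:

```r
library(thymoquant)

ph  <- make_phantom(phantom_spec(seed = 42))      # aged light-sheet lobe
reg <- segment_phantom_regions(ph$stack)
as.data.frame(reg)
#>    region  voxels volume_um3
#> 1    lobe 1190213  4882732.8
#> 2 medulla  223698   917699.2
#> 3      hd  281669  1155519.6
#> 4  cortex  684846  2809513.9

sec <- make_phantom(validation_phantom_spec("confocal_section", seed = 7))
det <- detect_nuclei(sec$stack, channel = "gfp", diameter_um = 5,
                     score_threshold = 0.1)
cl  <- classify_nuclei(det, sec$truth$regions,
                       classification_rules(region_inside_threshold = 1.2))
den <- compute_densities(cl, sec$truth$regions)
subset(den, channel == "gfp")
#>    region channel count volume_um3      density
#> 1  cortex     gfp  1523   10542528 0.0001444625
#> 2 medulla     gfp  3147    2607910 0.0012067134
#> 3      hd     gfp  7658    2455610 0.0031185734

estimate_counts(subset(den, channel == "gfp"), reg)
#>    region channel      density volume_um3 estimated_count
#> 1  cortex     gfp 0.0001444625  2809513.9        405.8694
#> 2 medulla     gfp 0.0012067134   917699.2       1107.4000
#> 3      hd     gfp 0.0031185734  1155519.6       3603.5727
```

The recovered densities sit within a few percent of the generator's true
values (1.5 × 10⁻⁴, 1.2 × 10⁻³ and 3.2 × 10⁻³ nuclei/µm³), and the
estimated counts are densities times the segmented light-sheet volumes.

Injury-recovery statistics on a synthetic time course:

```r
tc <- make_timecourse(timecourse_spec(seed = 1))
aging_index(tc, seed = 1)
#>   subset auc_young  auc_aged     index     ci_lo     ci_hi undefined
#> 1 aaTEC1  22734.89  13740.04 0.6043591 0.5743705 0.6352482     FALSE
#> 2 aaTEC2  18439.24  11395.41 0.6179977 0.5879624 0.6495119     FALSE
#> 3   cTEC  96948.49  66215.93 0.6830012 0.6521494 0.7183703     FALSE
#> 4   mTEC 415695.42 287430.00 0.6914438 0.6584932 0.7291748     FALSE
```

With the default generator settings (aged recovery rate 0.15/day vs
0.5/day in the young) every population recovers less area under its
post-injury curve in the aged group, so the indices fall below 1, each
with its bootstrap confidence interval.

End-to-end runs are orchestrated from a single configuration:

```r
run_pipeline("pipeline.yaml", seed = 1)   # writes CSVs + manifest.json
```

## Package layout

- `R/phantom.R`, `R/expr-sim.R`, `R/timecourse.R` — synthetic-data
  generators with ground truth
- `R/segmentation.R`, `R/regions.R`, `R/image-stack.R` — region
  segmentation and volumes
- `R/nuclei.R` — spot detection, signed distances, classification,
  densities, paired-lobe counts
- `R/qc.R`, `R/markers.R`, `R/signatures.R`, `R/emt.R` — expression-side
  procedures
- `R/dynamics.R` — recovery fraction, AUC, aging index
- `R/pipeline.R` — config-driven orchestration with a run manifest
- `vignettes/thymoquant-methods.Rmd` — models, parameter choices and
  validation design
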