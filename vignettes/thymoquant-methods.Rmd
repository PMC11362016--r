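---
title: "Quantifying thymic involution: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thymic involution: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thymoquant)
```

## Scope

The aged thymus remodels in a characteristic way: the medulla fragments
into islets, and compact peri-medullary clusters of age-associated thymic
epithelial cells (HD-TECs) emerge that are absent in young animals.
`thymoquant` quantifies this remodelling from three kinds of data and
validates every step on synthetic inputs with exact ground truth:

1. **Volumetric imaging** of dual nuclear-reporter lobes (GFP marks the
   epithelial lineage, tdTomato everything else): density-based
   segmentation of lobe, medulla and HD regions, with the cortex defined by
   subtraction so that cortex + medulla + HD equals the lobe exactly.
2. **Nuclear spot counting** in thick sections: Laplacian-of-Gaussian blob
   detection, signed-distance classification into medullary/HD,
   subcapsular and cortical compartments, densities, and the paired-lobe
   estimator (densities from sections of one lobe multiplied by light-sheet
   volumes of the contralateral lobe).
3. **Single-cell expression and injury time courses**: the cell-level QC
   rule, library-size normalization, Wilcoxon marker ranking with FDR
   control, reference-subtracted signature scoring with subset mapping, an
   E-cadherin/vimentin EMT axis, and recovery statistics (recovery
   fraction, trapezoidal AUC, bootstrap aged/young aging index).

## The imaging model and its segmentation

### Phantom generator

`make_phantom()` renders a two-channel voxel volume from an explicit
geometric and optical model:

* **Geometry.** An ellipsoidal lobe contains `n_medulla_blobs` spherical
  medullary blobs (radius jittered ±20%). HD regions are shells grown
  outward from the medullary boundary (default thickness 30 µm), coated
  patchily so that a chosen fraction of the boundary is covered;
  `hd_fraction = 0` reproduces the young-thymus limit. The cortex is the
  remaining lobe volume.
* **Nuclei.** Each region is populated by a hard-sphere Poisson process:
  the number of nuclei is Poisson with mean density × volume, positions are
  uniform, and centres are rejected closer than two nuclear radii (default
  2.5 µm, i.e. 5-µm nuclei) to any accepted centre, across regions and
  channels. The defaults place GFP nuclei at 1.5 × 10⁻⁴ µm⁻³ in cortex,
  1.2 × 10⁻³ in medulla and 3.2 × 10⁻³ in HD clusters — an order of
  magnitude cortex→medulla and a further ~2.7× compaction in HD, matching
  the qualitative ordering seen in reporter imaging; tdTomato nuclei cover
  cortex and medulla at 10⁻³ µm⁻³ and are absent from HD clusters. No
  numeric densities are published, so these are free parameters chosen to
  be biologically plausible (up to ~3 × 10⁶ nuclei/mm³) while staying
  clearly below the jamming density of the hard-sphere process.
* **Optics and noise.** Each nucleus contributes a unit-amplitude Gaussian
  PSF sampled at voxel centres (anisotropic sigma, default 1.8/1.8/4 µm
  for light-sheet-like volumes), followed by Poisson noise
  (`rpois(scale · I)/scale`, default scale 20, i.e. ≈20 photons at a
  nucleus peak) and additive Gaussian read noise (sd 0.05). Spacing
  presets follow the acquisition settings of the modality: 0.915 µm
  laterally and 4.9 µm axially for light-sheet, 0.22/2 µm for confocal.

The generator is deliberately simple where realism does not affect the
quantities under test: there is no depth-dependent attenuation, no
spectral bleed-through, no nuclear shape variation, and blob/shell
geometry is idealized. Consequently, passing the validation suite
demonstrates that the *algorithms* recover a known density field under
realistic sampling, blur and shot noise — not that they are robust to
every artefact of real microscopy.

### Segmentation pipeline

`segment_dense_region()` implements a fixed order of operations: sum the
requested channels, per-slice 2D median filter (radius 2 px), 3D Gaussian
filter specified in micrometres and divided by the per-axis spacing
(honouring anisotropy), min–max normalization with a fractional threshold,
morphological closing, and removal of components below a minimum volume
(default 10⁴ µm³ — about the volume of a smoothed single-nucleus speckle
blob, well below any medullary structure). The original analysis set its
intensity thresholds interactively; they are unrecoverable, so the
threshold here is a fraction of the normalized intensity range (an
automatic Otsu fallback is provided via `threshold_method = "otsu"`).
Two normalization windows are available: strictly per-slice (`"slice"`,
the literal reading; a slice whose min equals max contributes no
foreground) and per-volume (`"volume"`), which is more stable when a
bright structure appears only in some slices — per-slice normalization
rescales medulla-only slices so that medullary intensity saturates the
range, which makes a single fractional threshold mean different things in
different slices. The region pipelines therefore default to `"volume"`.

Because every cell carries exactly one reporter, the two channels carry
complementary information, and `segment_phantom_regions()` exploits it:

* **Lobe**: the *sum* of both channels, wide smoothing (10 µm), low
  threshold, generous closing (15 µm), hole filling, largest component.
  Using tdTomato alone fails in a specific and instructive way: HD
  regions are tdTomato-free, and an HD "bay" at the lobe periphery is not
  an enclosed hole, so hole-filling cannot recover it.
* **GFP-dense tissue** (medulla ∪ HD): GFP at a low threshold (0.22 of
  the volume-normalized range ≈ half the medullary plateau).
* **HD candidate**: GFP at a higher threshold (0.36 ≈ half the HD
  plateau) *minus* the tdTomato-positive mask eroded by 2 µm. The erosion
  compensates optical bleed of the tdTomato signal across the
  medulla–HD interface; without it the inner HD rim is systematically
  lost. On young images nothing GFP-dense is tdTomato-free, so the HD
  mask comes out empty without any special-casing.
* **Medulla**: the dense mask restricted to tdTomato-positive voxels
  (mirroring the biology: the medulla is dense in both reporters, HD
  clusters only in GFP), opened by 5 µm to cut the bleed halo that
  smoothing creates around HD clusters, with enclosed cavities refilled.

The volume normalization in these passes anchors its upper end at the
99.9th intensity percentile rather than the single brightest voxel: the
maximum of a shot-noise-limited volume is a heavy-tailed statistic that
varies by several percent between acquisitions, and anchoring thresholds
to it propagates that variability directly into boundary placement.
* **Composition** (`compose_regions()`): voxels claimed by both medulla
  and HD go to HD (compaction is the stricter criterion), the cortex is
  computed by subtraction, and the volume identity holds exactly on voxel
  counts.

Numerical behaviour worth knowing: the whole chain is invariant to
multiplying the input intensities by a positive constant; min–max
normalization is taken after filtering, so the additive noise floor is
removed by the min subtraction; and raising the binarization threshold can
only shrink the segmented volume.

**Why thresholds sit where they do.** For a plateau of intensity *P*
embedded in a darker background, the blurred profile crosses *P*/2 exactly
at the true boundary, so an unbiased threshold is half the plateau of the
structure being delineated — hence separate passes for medulla and HD
rather than one mask per threshold. A single global threshold placed both
boundaries at the wrong fraction of their plateaus and produced a
systematic one-voxel axial bias (4.9 µm per face at light-sheet spacing),
which is exactly what the two-pass design removes.

**A note on an idealized limit.** One might expect segmentation accuracy
to improve without bound as the PSF shrinks. That holds for a continuous
density field, but not for discrete nuclei at a fixed filter scale: a
smaller PSF makes the rendered field spikier, and the Dice coefficient
*decreases* (measured 0.81 → 0.58 as the PSF shrinks from 4 to 1 µm at a
4-µm filter). What the suite tests instead is the meaningful form: with
total blur matched to the feature scale, noiseless Dice is high, and it
degrades when the blur is insufficient to average out shot noise.

## Nucleus detection and classification

`detect_nuclei()` replaces the original proprietary spot detector with
scale-space blob detection: anisotropy-corrected Gaussian smoothing at
σ = diameter/(2√3) (default diameter 5 µm, matching the generator's 5-µm
nuclei), the scale-normalized negative Laplacian computed with physical
spacings, 26-neighbourhood local maxima above a score threshold, and
per-axis quadratic sub-voxel refinement. The response is linear in
intensity, so doubling the image and the threshold together changes
nothing.

`signed_distance()` uses exact anisotropic Euclidean distance transforms
of the mask and its complement; distances are negative inside a surface,
so the published classification rules read literally: medullary/HD when
the distance to the medullary or HD surface is ≤ 0 µm, subcapsular when
the signed distance to the section edge is ≥ −25 µm, cortical otherwise,
in that precedence. The "section edge" of a thick section is taken as the
lateral lobe boundary only (computed per slice); including the two cut
faces would make every nucleus in a 200-µm section "subcapsular". For the
combined medullary/HD label, per-region attribution goes to the surface
with the most negative distance, ties to HD.

Distances are sampled at the nucleus's containing voxel, so a voxelized
mask resolves positions only to half a voxel. The end-to-end validation
therefore classifies detected (noise-jittered, sub-voxel) centres with a
measurement allowance of half the voxel diagonal on the region-inside
rule; the printed ≤ 0 µm rule remains the default of
`classification_rules()` and is what the rule-exactness checks assert.

`compute_densities()` and `estimate_counts()` are exact arithmetic —
density × volume reproduces the count identically, and the paired-lobe
estimate is a pure product — so their validation is about the inputs:
detection recall/precision ≥ 95% on noiseless sections, ≥ 95% label
accuracy for interior nuclei, and per-region count estimates within 10%
on noisy phantom pairs.

**Problem sizes.** The validation suite uses a 256 × 256 × 64-voxel
light-sheet phantom (≈234 × 234 × 314 µm, ~10⁴ nuclei) for segmentation
and a 380 × 380 × 120-voxel section phantom at 1 × 1 × 2 µm for
detection (~30,000 nuclei; the axial spacing matches confocal
acquisition, the lateral spacing is a 4–5× downsample that keeps the
volume at desk scale). The section phantom is sized by a power argument:
with a fixed 10% tolerance on count recovery, each region must hold
enough nuclei that two independent Poisson realizations differ by well
under 10% (≈1,500 in the sparse cortex gives a combined sampling sd of
~3.5%, leaving room for the 1–2% detection bias measured in dense HD
clusters).

## Expression-side procedures

The count-matrix generator draws negative-binomial counts
(variance µ + φµ², default dispersion φ = 0.5) from a fixed lognormal
gene-weight profile, with subset-exclusive markers boosted by a
natural-log fold change (default 2) in their subset's cells, lognormal
library sizes (median 5,000), per-cell mitochondrial targets from a Beta
distribution (mean 5%), and two age conditions whose subset frequencies
differ, with the aaTEC-like subsets present only in the aged condition.
Low-quality cells shrink their library to 15% and raise the
mitochondrial fraction to 0.35; doublets are literal sums of two cells;
a planted contaminant cluster expresses `Ptprc` in an exact fraction of
its cells. All per-cell metadata are computed from the realized counts,
never sampled separately, so the QC rule faces the same coupling between
indicators that real data shows.

The QC rule is implemented exactly as printed: three negative indicators
— low total counts, ≤ 1,000 detected genes, mitochondrial fraction ≥ 0.2
— and a cell is low-quality when more than one fires. "Low total counts"
carries no published number; the default is the 5th percentile of the
cell's sample, configurable. The ribosomal fraction is computed and
reported but is not an indicator. Cluster-level exclusion (clustering
itself is external; truth labels stand in) drops clusters with a majority
of flagged cells or a majority expressing a contaminant gene; both 50%
defaults are explicit reconstructions of the unquantified published
criterion.

Normalization is counts-per-10,000 with log1p; by construction
Σ exp(v) − 1 returns exactly 10,000 per cell, which the suite checks to
1 × 10⁻⁶ relative.

Marker ranking is one-vs-rest Wilcoxon with the tie-corrected normal
approximation and no continuity correction — the tie-corrected variance
*is* the exact permutation variance, which is what makes the
enumeration oracle in the tests exact — with BH adjustment within each
comparison and no fold-change filter. Signatures keep FDR ≤ 0.05 genes
sorted by descending z (ties broken by gene name for reproducibility),
truncated at n = 20 by default (30 and 10 are used for other mappings).
Signature scoring subtracts an expression-matched random reference: genes
are binned by average expression into 25 rank bins (min-ties, so
identically expressed genes share a bin), 50 controls are sampled per
signature gene (iterating genes in sorted order, making the reference
independent of signature ordering), and the score is the difference of
means. Mapping is arg-max over signature scores with exact ties left
unassigned and the top-minus-runner-up margin reported.

Two displays are reconstructions because the published definitions are
not quantitative: the scaled frequency change (difference of
within-compartment frequencies, aged minus young, divided by the largest
absolute change, so the dominant subset scores ±1) and the EMT axis
(cells ranked by descending *Cdh1*; epithelial/mesenchymal scores as gene
set means; quadrants of the *Cdh1*/*Vim* plane by detection, i.e.
expression > 0). Both are labelled as such in their outputs.

## Injury-recovery statistics

The time-course generator models post-injury abundance as
*m(t) = B(1 − d·f(t)/f(t\*))* with *f(t) = e^{−ρt} − e^{−δt}*: baseline
*B* at day 0 exactly, maximal fractional depletion *d* at the nadir
*t\**, fast depletion (δ = 3/day) and slower recovery (ρ, default
0.5/day young vs 0.15/day aged). Replicates are unit-mean lognormal
perturbations with a chosen coefficient of variation (default 0.1,
10 replicates, days 0/1/4/7 as in the injury experiment).

`recovery_fraction()` expresses each day as a percentage of the
age-matched day-0 mean. `auc_timecourse()` applies the trapezoid to the
replicate means at the observed days (non-uniform spacing handled
natively); the mean of per-replicate AUCs is also reported when
replicates pair across days, since the published choice between the two
is not stated. `aging_index()` is the aged/young AUC ratio with a seeded
percentile bootstrap (replicates resampled within each age × day cell;
2,000 resamples by default). The point estimate uses day means; the
bootstrap captures replicate noise. Coverage is validated by simulation:
the generator's analytic AUC ratio falls inside the 95% CI in ≥ 90% of
100 seeded runs (the suite uses 300 resamples per run to keep the
simulation quick; coverage at 300 and 2,000 resamples is
indistinguishable at this sample size). Whether the published AUCs were
computed on absolute counts or normalized abundances is not stated; both
work here, since the index is invariant to any common rescaling.

## Orchestration and determinism

`run_pipeline()` executes a declared stage list from a single (YAML or
list) configuration, validates stage names before anything runs, derives
every stage's seed from the global seed, and writes a manifest with
package version, seed, per-stage parameters, timings and MD5 hashes of
all outputs. Identical configuration and seed reproduce byte-identical
CSVs, which the suite asserts. As an R package the function surface *is*
the command line: `Rscript -e 'thymoquant::run_pipeline("config.yaml")'`.

## Known limitations

* Segmentation thresholds are fractions of a min–max normalized range;
  on images whose brightest structure differs from the phantom design
  (e.g. young lobes, where the medulla is the brightest structure) the
  appropriate fraction shifts (≈0.45 rather than 0.20) and must be set
  per study, exactly as in the original interactive analysis.
* The axial voxel size of light-sheet data (4.9 µm) bounds achievable
  boundary accuracy; thin structures (HD shells) lose ~0.1 Dice to
  axial voxelization alone.
* The phantom omits attenuation, bleed-through and autofluorescence; the
  expression generator omits batch effects, ambient RNA and
  transcriptional bursting beyond NB dispersion. Numbers obtained on
  real data should be accompanied by their own controls.
* Hypothesis tests between groups (Mann–Whitney, Kruskal–Wallis/Dunn)
  are standard library calls left to the analysis layer and are not
  re-implemented here.
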