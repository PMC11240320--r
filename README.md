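# timequant

Quantification and multi-omic profiling of early (CD57−) and late (CD57+)
differentiation-stage T cells in lymphoma tissue.

## What this package is for

The tumor-immune microenvironment of B-cell lymphomas contains T cells in
very different functional states. Two markers split the CD3+ compartment
into four subsets — CD8 separates cytotoxic (T<sub>C</sub>) from helper
(T<sub>H</sub>) cells, CD57 marks late differentiation — giving
T<sub>H,57−</sub>, T<sub>C,57−</sub>, T<sub>H,57+</sub> and
T<sub>C,57+</sub>. `timequant` implements the full image-to-statistics
chain a cohort study of these subsets needs, for analysts working with
multiplex immunofluorescence images and region-level (GeoMx-style) spatial
omics matrices:

* **Synthetic cohorts with known ground truth** — multi-channel tissue-core
  images (nuclear + CD3/CD8/CD57), AOI-level expression matrices with
  patient random effects, area artifacts, negative-control probes and
  planted effects, and survival tables with a planted hazard step. Every
  downstream stage is testable without any external data.
* **Segmentation** — a classical stand-in (smooth → Otsu → distance
  transform → watershed; rings closed and filled for membrane markers)
  honoring a `label_mask` contract, plus an import path so externally
  produced (e.g. deep-learning) masks can replace it.
* **Phenotyping** — the mask-overlap rule: each nucleus centroid is looked
  up in each marker mask, and cells are classified by
  CD3 gate → CD8 split → CD57 stage.
* **Cell metrics** — frequencies over nucleated cells, percentages of CD3+
  cells, T<sub>H</sub>/T<sub>C</sub> and CD57+/CD57− ratios, and the
  Shannon diversity index over the four T subsets,
  H = −Σ p<sub>i</sub> ln p<sub>i</sub> ∈ [0, ln 4].
* **Detection evaluation** — IoU-based one-to-one matching at a 0.5
  threshold; precision, recall, F1 and detection accuracy
  tp/(tp+fp+fn).
* **Expression preprocessing** — AOI cell-count QC (≥20 cells protein,
  ≥100 RNA), area scaling, stratified pairwise cyclic-loess
  normalization, SNR against negative-control probes, and the transcript
  filter (removed iff >25% of patients have SNR <1.05 in all cell types).
* **Statistics** — Shapiro-gated t/Wilcoxon tests, patient
  random-intercept mixed models with Satterthwaite inference and BH-FDR,
  Spearman correlation, one-way ANOVA + Tukey HSD, chi-square/Fisher
  with an expected-count gate.
* **Survival** — Kaplan–Meier, log-rank, and maximally selected rank
  statistics with a minimum group proportion of 0.1 (naive p flagged as
  selection-biased).
* **Integration** — a design-weighted multiblock sparse PLS-DA
  (DIABLO-style: design 0.1 between data blocks, 1.0 to the outcome) with
  alternating-least-squares extraction, soft-threshold sparsity,
  cross-validated `keepX` tuning, centroid/Mahalanobis prediction and a
  label-permutation test.

## Worked example

```r
library(timequant)

# a 300-cell synthetic tissue core, segmented and phenotyped
scene <- generate_scene(scene_params(n_cells = 300, seed = 1))
cells <- phenotype_scene(scene)
profile <- subset_profile(cells)
round(profile[, c("cd3_frequency", "freq_TH_57neg", "freq_TC_57neg",
                  "th_tc_ratio", "sdi")], 4)
#>   cd3_frequency freq_TH_57neg freq_TC_57neg th_tc_ratio    sdi
#> 1        0.0767        0.0367        0.0267      1.0909 1.1221

# how good was nuclei detection, against the scene's ground truth?
evaluate_detection(segment_nuclei(scene$channels$nuclear),
                   label_mask(scene$truth_nuclei_mask))
#>    tp fp fn precision recall accuracy f1
#> 1 300  0  0         1      1        1  1
```

The profile says: 7.7% of nucleated cells are CD3+ T cells, 3.7% are
early-stage helper cells, the helper/cytotoxic ratio is 1.09, and the
diversity of the four T subsets is 1.12 nats (out of a possible
ln 4 ≈ 1.386). Detection is perfect on this synthetic core — expected,
since the generator draws well-separated cells; see the methods vignette
for what that does and does not demonstrate.

The full synthetic-cohort pipeline (images → phenotyping → metrics →
omics preprocessing → mixed models → survival → integration) runs from a
single configuration and is bit-reproducible under a fixed seed:

```r
res <- run_pipeline(default_run_config(seed = 1, out_dir = "run1"))
head(res$manifest)
```

## Layout

```
R/                   implementation (one file per stage)
tests/testthat/      unit, property and acceptance tests
scripts/acceptance.R end-to-end acceptance computation
vignettes/           methods vignette (models, parameters, limitations)
inst/scripts/        thin command-line wrapper for the pipeline
```
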