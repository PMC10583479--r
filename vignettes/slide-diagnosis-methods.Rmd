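---
title: "Methods: two-stage whole-slide tumor diagnosis and its simulated evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage whole-slide tumor diagnosis and its simulated evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidedx)
```

## The problem and the model

Histologic diagnosis of skin tumors from hematoxylin-and-eosin slides is
the gold standard but carries well-documented inter-rater variability.
`slidedx` implements the computational side of a comparison between an
automated two-stage pipeline and a panel of pathologists on seven common
canine skin tumor types: trichoblastoma, squamous cell carcinoma (SCC),
peripheral nerve sheath tumor (PNST), melanoma, histiocytoma, mast cell
tumor (MCT), and plasmacytoma.

The pipeline diagnoses one whole-slide image (WSI) in two stages:

1. **Tissue segmentation.** The slide is segmented at 4.0 µm/pixel into
   six classes: background, epidermis, dermis, subcutis,
   inflammation/necrosis, and tumor (all tumor types collapsed).
2. **Tumor-patch classification and majority voting.** The tumor mask is
   upscaled ×16 to the 0.25 µm/pixel classification resolution, tiled into
   non-overlapping 1024 px patches, and a patch reaches the classifier
   only if it is 100 % tumor (the *full-tumor rule*). Each retained patch
   is classified into one of the 7 tumor types or an eighth
   *nonneoplastic* class. Nonneoplastic patches are excluded, and the
   tumor type with the most remaining patches is the primary diagnosis;
   the next two are the differentials.

The panel side mirrors the human protocol: each of 6 raters gives a
primary diagnosis and 2 differentials with confidences on a 0.01 grid in
[0.01, 0.98] that sum to exactly 1.00, primary first. The consensus
primary is the modal primary vote; a draw is broken by the higher mean
confidence among each candidate's voters. The *decimal consensus* of a
slide is the number of raters (0–6) agreeing with the consensus primary,
and the accumulated value per tumor type is the mean over its slides
(slides with 4/6 and 5/6 agreement accumulate to 4.5).

## What is simulated, and why

No public WSIs or trained networks accompany the original evaluation, so
the package replaces them with parameterized stochastic stand-ins while
keeping every downstream rule exact:

* **Slides** become integer label rasters (`generate_slide_raster()`):
  a background border, an epidermis band, dermis and subcutis layers,
  optional inflammation/necrosis pockets, and a connected tumor blob grown
  from random ellipses to a target pixel fraction. This emulates the
  *geometry* that the tiling, purity, and masking rules consume. It does
  not emulate pixel texture, staining, or tumor heterogeneity, so passing
  tests say nothing about how a real CNN would perform — only that the
  aggregation and evaluation machinery behaves as specified.
* **The segmentation network** becomes an oracle that corrupts each pixel
  of the true six-class view independently with a per-class error rate.
* **The classification network** becomes an oracle that draws each
  patch's emitted class from a column-stochastic confusion matrix; the
  bundled default is the benchmark patch-confusion table with columns
  renormalized to sum exactly to 1 (the printed 2-decimal columns sum to
  0.97–1.01).
* **Raters** become `rater_model`s with a per-type probability of a
  correct primary, similarity-weighted wrong/differential draws, and a
  Dirichlet confidence triple discretized to the reporting grid.

## Defaults and the conditions they encode

| Parameter | Default | Why |
|---|---|---|
| slides per tumor type | 50 | the benchmark training cohort design (350 slides) |
| split ratios | 0.70 / 0.10 / 0.20 | reproduces 245/35/70 slides and 35 training slides per type |
| raster size | 768 × 768 px at 4 µm | a ~3 × 3 mm biopsy section; desk-scale |
| tumor fraction | U(0.2, 0.5) | typical tumor-bearing biopsy occupancy |
| inflammation fraction | 0.05 | minor pockets, enough to exercise the class |
| patches per slide per epoch | 10 | one uniform sampling epoch yields 2,450 training / 350 validation patches |
| purity threshold | 0.90 | classifier training patches must be ≥90 % the sampled class |
| classification patch | 1024 px at 0.25 µm | ×16 above the 4 µm segmentation grid (64×64 blocks) |
| rater primary accuracy | 0.97 | consistent with a 5.8/6 mean decimal consensus |
| confidence concentration | 0.07 | calibrated so mean primary confidence ≈ 0.9, the reported level |

Split rounding is `floor(ratio * n)` per type with the remainder assigned
to training — the only deterministic rule that reproduces 245/35/70
exactly.

## Numerical and design choices

* **Adaptive sampling update.** The source protocol states only the
  direction (up-sample weak classes, under-sample strong ones). We use
  `weight ∝ (1 − score) + ε` with ε = 0.05: the simplest rule that is
  strictly monotone in the score and keeps every class above a floor. The
  validation score contract is any per-class value in [0, 1] (per-class F1
  is the intended instantiation).
* **Tiling.** Grid origin (0,0), stride = patch size, partial edge tiles
  discarded. The full-tumor check is evaluated on 64 × 64 blocks of the
  4 µm mask, which is provably identical to upscaling ×16 and checking
  1024 px tiles (and property-tested on random masks); materializing the
  upscaled mask for a 2048² raster would cost ~1 GiB per slide.
* **Ties.** Algorithm-side ties in patch counts are broken by the
  canonical tumor-type order and flagged (`tie_flag`); panel-side draws
  are broken by mean confidence as the human protocol specifies, with a
  second-level fallback to canonical order (`draw_resolved`).
* **Patch fractions** are reported relative to retained (post-exclusion)
  patches.
* **"No tumor diagnosis"** (no full-tumor tile, or all patches
  nonneoplastic) is a first-class status, not an error, so cohorts can
  count such slides.
* **Confidence grid.** Confidences are held as integer hundredths, so the
  sum-to-1.00 constraint is exact. The generator discretizes Dirichlet
  draws by largest-remainder rounding, then clips into [1, 98] hundredths
  with the residue pushed onto the largest entry.
* **Confusion-table conventions.** The benchmark patch table is
  column-normalized with rows = predicted; its printed "Precision" row is
  the column-normalized diagonal and its "Recall" row the diagonal over
  its row sum — swapped relative to convention. `precision_recall_f1()`
  exposes both the `"paper"` convention (for reproducing the table) and
  the `"conventional"` one; reproduction tests use ±0.01 per entry
  because the printed derived rows are internally inconsistent at the
  second decimal.
* **Column-sum tolerance.** Printed 2-decimal fraction tables have column
  sums between 0.97 and 1.01 (rounding plus cells < 0.01 printed as
  0.00), so `confusion_matrix()` validates column fractions to within
  0.05.
* **PCA.** `stats::prcomp` on column-centered (not standardized)
  features — confidences and patch fractions already share the [0, 1]
  scale; standardization is available by flag. Component signs are fixed
  by making the largest-magnitude loading positive. Tests verify
  agreement with an independent eigendecomposition of the covariance
  matrix to 1e-8.
* **Seeds.** One master seed; per-slide, per-rater, and per-stage streams
  derive from it by a stable string hash, so results do not depend on
  iteration order. Stochastic oracles keep private RNG streams and never
  disturb the caller's RNG state.
* **Bone and cartilage** appear in real annotation schemes but not in the
  six-class segmentation task; they carry optional fine codes and are
  folded into subcutis by the six-class view. The default generator omits
  them.

## Open choices resolved here

* **Votes are primaries only.** The 0–6 decimal-consensus range implies
  each rater contributes one vote; differentials do not count toward the
  majority, and a rater listing the consensus label as a differential does
  not raise the decimal consensus. Differential consensus ranks the
  remaining labels by primary-vote count, then mean confidence.
* **Slide-level per-class F1** is computed conventionally from count
  matrices. The benchmark's separately printed per-type algorithm F1
  column is not derivable from its count table and is not reproduced.
* **Fraction denominators** for the top-3 feature matrix use retained
  patches, consistent with reporting percentages "of the tumor patches".

## Problem sizes used in the checks

The bundled tests run at deliberately small scale: 350-slide cohorts use
160² rasters (the split and patch-count arithmetic is size-independent);
generative-recovery checks use 10,000 draws per class; the end-to-end
majority-voting check uses a 140-slide cohort of 2048² rasters with tumor
fractions in [0.5, 0.6], which yields several hundred retained patches
per slide. Joint per-cell recovery checks over all 49 confusion cells use
a critical value of 4 binomial SD to control the family-wise false-alarm
rate; individually named cells are checked at 3 SD.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(
  cohort = cohort_config(n_slides_per_type = 3, raster_size_px = c(512, 512),
                         tumor_fraction_range = c(0.35, 0.5),
                         split_ratios = c(0, 0, 1), seed = 9),
  seed = 9)
res <- run_study(cfg, split = "test")
res$slide_accuracy          # majority-vote slide accuracy on the cohort
res$consensus_accuracy      # simulated panel consensus accuracy
res$decimal_consensus_by_type
res$patch_mean_diagonal     # mean per-type fraction of correct patches
```

## Known limitations

* Rasters carry one tumor type per slide and no texture; mixed or
  collision tumors, stain variation, and scanner artifacts are out of
  scope.
* The classifier oracle draws patches i.i.d.; spatial correlation of CNN
  errors (e.g. contiguous misclassified regions) is not modeled, which
  makes majority voting slightly *more* reliable here than on real
  slides at equal confusion rates.
* The segmenter oracle corrupts pixels independently, so its errors do
  not form plausible connected regions either.
* Reported-table reproduction is arithmetic on printed values, not a
  re-run of the original networks.
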