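# renalmorph

Quantitative morphometry for H&E-stained kidney-transplant biopsies on
whole-slide images (WSI).

The Banff classification grades allograft lesions 0–3, and its two most
prognostic lesions — interstitial fibrosis (**ci**) and interstitial
inflammatory infiltration (**i**) — are scored by visually estimating
*relative areas* of cortex. That estimate is the main source of
interobserver disagreement and makes borderline changes hard to separate
from rejection. renalmorph computes those areas explicitly, for
pathologists and computational-pathology groups who already have (or want
to validate) a structure segmentation model.

## What it computes

Given an RGB tissue image with pixel-size calibration and an instance
segmentation of the three structure classes (glomeruli, tubules,
arteries) from any segmenter honouring a simple contract, the pipeline:

1. detects tissue by grayscale thresholding (background is near-white),
2. scans the slide with 50 µm windows (99 px at x20, 0.5056 µm/px) at
   50 % overlap, discarding small unstable window-border instances,
3. merges same-class fragments with a strong intersection back into whole
   structures,
4. derives **stroma** = tissue ∖ structures, and carves out the **proper
   stromal space** — the normal 15–20 µm stromal rim around each
   structure, excluded from fibrosis accounting:

   `fibrosis % = |stroma ∖ rim| / |tissue| × 100`
5. detects cells in the stroma by thresholding + watershed and classifies
   each fitted ellipse: **lymphocyte** iff semi-axis ratio < 2, mean gray
   brightness < 95 (0–255) and lymphocyte-sized; otherwise nucleus,
6. flags 50 × 50 µm grid tiles containing ≥ 2 lymphocytes and ≥ 20 cells
   as **infiltration**:

   `infiltration % = |flagged tiles ∩ (stroma ∖ rim)| / |tissue| × 100`
7. evaluates segmentations (per-class Dice `2TP/(2TP+FN+FP)`,
   column-normalized confusion matrix, COCO-style mAP@[0.5:0.95]) and
   discriminates Banff score groups 0–1 vs 2–3 by ROC with
   Youden-optimal cutoffs.

A built-in synthetic renal-cortex generator (oval glomeruli with Bowman
capsule, Voronoi-packed polygonal tubules, arteries with lumen, tunable
fibrosis/infiltration fractions, rendered nuclei and lymphocytes) provides
exhaustive ground truth, a perfect "oracle" segmenter and controlled
segmentation corruption, so the whole measurement chain is testable
without clinical data.

## Worked example

```r
library(renalmorph)

slide <- generate_slide(synth_params(image_size_px = 640, seed = 42))
print(slide)
#> <synth_slide> 640 x 640 px, 32 instances, 123 cells
#>   tissue 81.9% of raster; fibrosis 25.4%, infiltration 7.7% of tissue

result <- run_full_pipeline(slide$rgb, make_oracle_segmenter(slide),
                            slide$params$calibration, pipeline_config())
print(as.data.frame(result$report), digits = 4)
#>   roi_id tissue_area_um2 fibrosis_rel_area_pct infiltration_rel_area_pct
#> 1    roi           85776                  25.4                     7.735
#>   n_lymphocytes n_nuclei n_infiltration_tiles
#> 1            18      103                    3
```

The generator asked for 25 % fibrosis and 8 % infiltration; the realized
ground truth is 25.4 % / 7.7 %, and the pipeline — running the full
window-scan → merge → stroma → cells → tiles chain on the rendered image —
measures 25.4 % and 7.73 %: the measurement chain recovers truth to a
tenth of a point when segmentation is perfect. Replace the oracle with
`corrupt_segmentation()` (or your own model) to study how measurement
degrades with segmentation quality.

ROC analysis on a cohort of scored slides:

```r
cohort <- simulate_score_cohort(n_per_group = 200, d_prime = 2, seed = 42)
roc <- roc_analysis(cohort, feature = "infiltration", score = "ci")
print(roc)
#> <roc_result> infiltration area vs ci score (0-1 vs 2-3)
#>   n = 200 positive / 200 negative
#>   AUC = 0.9374
#>   Youden-optimal cutoff = 11.582%: sensitivity 93.0%, specificity 80.0%, J = 0.730
```

`tidy(roc)` returns the per-cutoff curve, `glance(roc)` the one-row
summary, `autoplot(roc)` the ROC plot; `autoplot()` on a label map draws
the class overlay (glomeruli orange, tubules blue, arteries green, stroma
grey, proper space light blue, infiltration brown).

A thin command-line wrapper lives at `inst/cli/renal-morph.R`
(`synth`, `analyze`, `evaluate`, `roc` subcommands) for shell use; see the
header of that file.

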