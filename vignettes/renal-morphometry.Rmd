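---
title: "Quantifying fibrosis and interstitial infiltration in renal transplant biopsies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrosis and interstitial infiltration in renal transplant biopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalmorph)
```

## The measurement problem

The Banff classification grades renal-allograft biopsies lesion by lesion
on a 0–3 scale. Two of its most prognostic lesions — interstitial fibrosis
(ci) and interstitial inflammatory infiltration (i) — require the
pathologist to estimate *relative areas* of the cortex by eye, which is the
main source of interobserver variability and makes borderline cases hard
to separate from true rejection. renalmorph replaces the eyeball estimate
with explicit morphometry on whole-slide images (WSI): given a tissue
image and an instance segmentation of its parenchymal structures, it
derives the stromal compartment, finds nuclei and lymphocytes inside it,
maps infiltrated regions, and reports fibrosis and infiltration as
percentages of tissue that can be compared against expert scores.

The segmentation itself is pluggable. Any model (or a human annotator, via
GeoJSON) that returns per-structure binary masks for the three structure
classes — glomeruli, tubules, arteries — can drive the pipeline; the
package ships a ground-truth oracle for its own synthetic slides so that
every downstream stage can be validated without clinical data.

## Pipeline model and assumptions

1. **Tissue detection.** A pixel is tissue iff its Rec. 601 luminance (0–255)
   falls below `tissue_threshold` (default 230; `"otsu"` available). The
   assumption is standard H&E on glass: background is near-white.
2. **Sliding-window segmentation.** Segmenters see small square windows
   (`window_um = 50`, i.e. 99 px at the x20 pixel size of 0.5056 µm — the
   conversion rounds half away from zero). Windows tile the tissue
   bounding box with 50 % overlap. Instances touching a window border with
   area below `border_discard_area_um2` (100 µm²) are discarded as
   unstable; the overlapping neighbour window sees them in its interior.
3. **Merging.** Fragments of one structure seen by several windows are
   reunified by repeatedly unioning same-class instances whose overlap
   reaches `merge_iou_min = 0.5`, to a fixpoint. Overlap is measured
   against the *smaller* mask (`merge_criterion = "overlap"`). This choice
   is forced by geometry: with a 50 %-overlap tiling, two clips of a
   structure wider than a window share at most the window overlap, so
   their IoU tops out near 1/3 and an IoU-0.5 rule could never reassemble
   a glomerulus (which spans 2–3 windows at x20). Intersection over the
   smaller fragment exceeds 1/2 for exactly those clip pairs while still
   leaving genuinely distinct neighbouring structures (which share little
   or nothing) unmerged. Classical IoU merging remains available as
   `merge_criterion = "iou"`.
4. **Stroma and the proper stromal space.** Tissue not claimed by a
   structure class is stroma. Healthy cortex keeps a thin stromal rim
   around every structure; following convention this rim
   (`proper_stroma_width_um`, default 15 µm, valid 15–20) is excluded from
   fibrosis accounting. It is computed as a Euclidean-distance dilation of
   the structure union (in µm, so x20 and x40 scans behave identically)
   intersected with the stroma. What remains is the fibrosis-eligible
   compartment: in an edematous biopsy it stays small, in a fibrotic one
   connective tissue replaces parenchyma and it grows.
5. **Cells.** Dark objects inside stroma (plus the rim, by default) are
   thresholded — Otsu restricted to stromal pixels, capped at
   `cell_threshold_max = 180` so a nearly cell-free stroma cannot push the
   threshold into its own texture — and split by watershed on the distance
   transform. Each object gets a moment-equivalent ellipse and its mean
   gray value. A cell is a **lymphocyte** iff semi-axis ratio < 2, mean
   brightness < 95 and area within the lymphocyte gate (equivalent
   diameter 4–10 µm); otherwise it is a **nucleus** if within the nucleus
   gate (4–15 µm). The gates are configuration, since published practice
   fixes only the ratio and brightness cutoffs.
6. **Infiltration.** A fixed (non-sliding) grid of 50 × 50 µm tiles,
   anchored at the ROI origin, is flagged where a tile holds ≥ 2
   lymphocytes *and* ≥ 20 detected cells. Lymphocyte nuclei are nuclei, so
   all detected cells count towards the 20 by default;
   `count_lymphocytes_as_nuclei = FALSE` gives the strict reading
   (non-lymphocyte nuclei only). The infiltration area is the union of
   flagged tiles intersected with the fibrosis-eligible stroma, so
   fibrosis always contains infiltration — matching the clinical reading
   that infiltration happens *in* the interstitium.
7. **Morphometry.** Fibrosis % = eligible stroma / tissue; infiltration %
   = infiltrated subset / tissue; plus cell and tile counts, exported as
   CSV per ROI.

Score-group discrimination is deliberately simple: slides scored 0–1
versus 2–3 form two groups, the measured area is the classifier, the ROC
curve is swept over every distinct value (positive iff value ≥ cutoff),
AUC is trapezoidal (equal to the Mann–Whitney concordant-pair fraction),
and the reported operating point maximizes Youden's J = sensitivity +
specificity − 1. Both the maximal J and the cutoff achieving it are
reported under distinct names, since "Youden's J" is sometimes used
loosely for the cutoff itself. Group comparisons beyond ROC (beta
regression, ANOVA, post-hoc tests) are out of scope: the per-slide CSV is
the interface to any statistics package.

## The synthetic cortex generator

`generate_slide()` produces an H&E-like renal cortex crop with exhaustive
ground truth — label map, instance list, cell table, and true fibrosis /
infiltration fractions computed with the same geometric definitions the
pipeline uses. Defaults describe a 777 × 777 µm field at x20
(1536 px, 0.5056 µm/px):

* **Glomeruli** — ovals of 100–150 µm diameter with a Bowman-capsule rim
  rendered as part of the instance, so "true borders include tuft and
  capsule" holds morphologically.
* **Tubules** — a jittered-grid Voronoi packing (spacing from
  `tubule_size_um_range`, 30–50 µm) shrunk by a ~5 µm seam, giving the
  densely packed polygonal look of cortex.
* **Arteries** — near-circular, ≥ 100 µm, with a pale lumen (rendered
  below the tissue threshold so the lumen still reads as tissue).
* **Class balance** — structure areas target the conventional
  tubuli:glomeruli:arteries ≈ 40:3:2 ratio. Diameters are sampled, then
  rescaled within their anatomical ranges so each class lands on its area
  quota. This holds at the default field size; a small field (below about
  1300 px at x20) cannot honour the ratio because a single glomerulus or
  artery already exceeds its quota, and the generator then places one
  anyway — a deliberate bias towards realism over ratio.
* **Fibrosis** — patches carved out of the tubule packing by thresholding
  a smooth random field; the threshold is calibrated by bisection at
  generation time so the realized fibrosis-eligible fraction lands within
  ±1 point of `fibrosis_fraction_target` (error if the target is
  geometrically infeasible). Orphaned tubule fragments under 150 µm²
  dissolve into stroma.
* **Infiltration** — clusters of 50 µm grid tiles (chosen
  nearest-to-a-focal-point, so infiltrates are contiguous) each populated
  with 6 lymphocytes and 18 nuclei on a jittered sub-grid; a tile that
  cannot host its full complement is not counted as infiltrated, so the
  ground truth never promises densities the rule could not detect.
  Normal stroma gets 3 nuclei per tile-equivalent area — far below the
  20-cell rule, so the rule is attainable only in infiltrates.
* **Cells** — lymphocytes are near-circular (ratio ≤ 1.6) with mean gray
  50–90; nuclei are gray 100–160, round-ish in crowded infiltrates and up
  to ratio 2.8 in sparse stroma. Both populations sit clearly on their
  side of the ratio-2 / gray-95 classification boundary, which is what
  makes "rendered lymphocytes satisfy the detection rules by
  construction" a meaningful invariant rather than a tautology: the
  *detector* must still find, split and measure them.

The same seed yields byte-identical slides. `oracle_segmenter()` returns
ground truth clipped to a window (a perfect segmenter), and
`corrupt_segmentation()` degrades any instance list with seeded dropout
and boundary jitter so that Dice, confusion and mAP behave like they do on
imperfect models.

**What the generator does not emulate:** stain variability and color
deconvolution targets, scanner artifacts, tissue folds, tubulitis (cells
inside tubular epithelium), capsule and medulla, nuclei inside structure
classes, and the long-tailed morphology of real nuclei. Passing the
recovery tests therefore shows that the *measurement chain* is faithful
when segmentation is faithful; it says nothing about how a particular
segmentation model behaves on real H&E.

## Numerical choices

* µm→px conversion rounds half away from zero (50/0.5056 = 98.89 → 99).
* Coordinates are 0-based; boxes half-open, masks stored cropped to tight
  bounding boxes.
* Window stride is `floor(window_px / 2)`, so the overlap is
  `ceil(window_px / 2)` and a clip pair of one structure always shares
  more than half of the smaller clip — the merge criterion's worst case
  is covered.
* Dice of two empty masks is reported as 1 and flagged `degenerate`.
* Average precision uses all-point interpolation; greedy matching in
  descending score, ties broken by larger IoU then input order; classes
  with neither truths nor predictions are excluded from the mAP mean and
  reported as undefined.
* The ROC sweep includes a +Inf cutoff so the curve always spans (0,0) to
  (1,1); prediction uses value ≥ cutoff.
* Watershed tolerance is 1 gray-distance unit; lower oversplits elongated
  nuclei, higher merges touching lymphocytes in dense infiltrates.

## Validation at desk scale

The test-suite exercises every stage on synthetic fields of 512–768 px
(260–390 µm) across multiple seeds, plus one 1536 px field for the class
ratio; `scripts/acceptance.R` re-runs the oracle pipeline on five 640 px
slides and a 400-slide binormal cohort. At these sizes the oracle-driven
pipeline recovers structure masks pixel-exactly (per-class Dice 1.0 after
merging), and measured fibrosis / infiltration track generator truth to
within a tenth of a percentage point — the ±3-point tolerance used in the
tests is dominated by cell-detection stochasticity at low densities, not
by the geometry.

## Known limitations

* The infiltration grid is anchored, not sliding; an infiltrate straddling
  a tile boundary at sub-rule density on both sides is missed. This
  mirrors the published rule rather than improving on it.
* Merging by overlap-over-smaller can, in principle, absorb a small
  spurious instance that a segmenter emits mostly inside a larger true
  one; with well-behaved segmenters this is the desired behaviour.
* Cell classification uses size, shape and brightness only — no texture,
  no immune subtyping; tubulitis and arteritis are out of scope.
* `detect_tissue` assumes bright-background brightfield scans.
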