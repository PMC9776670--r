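# glomopipe

Glomerulus detection, five-class segmentation and glomerulosclerosis
quantification for renal-biopsy whole-slide images (WSIs), with a
downstream eGFR-slope prognosis regression.

## What it does

The fraction of a glomerular tuft replaced by sclerotic scar tissue is a
prognostic marker in IgA nephropathy (IgAN) and other chronic kidney
diseases, but scoring it by eye across a gigapixel slide is slow and
subjective. glomopipe implements a two-step computational pipeline:

1. **Detection** — the WSI is scanned row-by-row with 2000 µm square
   windows overlapping by 10% (a 200 µm strip), at a frame downsampled by
   an integer factor (default 8, i.e. 40× → 5×). A pluggable detector runs
   per window; boxes are remapped to WSI microns and duplicates of the same
   glomerulus at window borders are merged: boxes overlapping by ≥ 35%
   (intersection over the smaller box's area) are fused into their
   bounding-box union, transitively, to a fixpoint.
2. **Segmentation** — each merged box is cropped with a 20 µm margin and a
   pluggable segmenter labels every pixel as one of five classes
   (background, Bowman's space, glomerular tuft, crescentic region,
   sclerotic region). Labels are repositioned into a full-WSI map; pixels
   never detected stay background.

Quantification converts label maps into class areas (µm²) and the
sclerotic proportion per glomerulus,

    p = area(sclerotic) / [ area(tuft) + area(sclerotic) ],

so a globally sclerosed glomerulus (no tuft left) scores 1. The slide-level
summary (mean of per-glomerulus proportions) enters a multivariate OLS of
the patient's eGFR slope — the per-patient regression slope of eGFR over
the two years after biopsy — on six prognostic variables (age, sex,
hypertension, eGFR at biopsy, UPCR, sclerotic proportion), with z-scored
predictors (standardized partial regression coefficients), per-coefficient
t-test p-values, VIF diagnostics and R².

An evaluation harness provides greedy-IoU detection F1, per-class and mean
IoU with fold aggregation (micro-averaged, mean ± SE), and Welch's t-test
for comparing metric samples.

Trained neural backends (region-proposal detectors, transformer segmenters)
are out of scope: glomopipe defines their I/O contracts and ships
deterministic reference backends — truth oracles, a seeded jitter detector,
a classical blob detector and a nearest-palette-colour segmenter — plus a
**phantom WSI generator** (elliptical glomeruli with wedge lesions of
analytically known area fractions) and a **synthetic IgAN cohort generator**
whose eGFR slopes depend on the sclerotic proportion by construction, so
every stage is testable end to end without clinical data.

## Worked example

```r
library(glomopipe)

ph <- generate_phantom(phantom_spec(
  wsi_extent = c(4000, 3000), n_glomeruli = 6, seed = 7,
  sclerotic_fraction_dist = function(n) rbeta(n, 1, 4),
  crescent_fraction_dist = function(n) rep(0.15, n)))

res <- run_pipeline(ph$wsi, detector_blob(), segmenter_palette())
evaluate_detection(res$detections, ph$truth_boxes)
#> <detection_eval> TP=6 FP=0 FN=0  precision=1.000 recall=1.000 F1=1.000

q <- quantify_glomeruli(res$glom_masks, res$detections$boxes$glom_id)
round(q[, c("glom_id", "area_tuft", "area_sclerotic", "sclerotic_prop")], 3)
#>   glom_id area_tuft area_sclerotic sclerotic_prop
#> 1       1      6328           6900          0.522
#> 2       2      8292           3376          0.289
#> 3       3     10040           1504          0.130
#> 4       4     11368           1324          0.104
#> 5       5     13240            100          0.007
#> 6       6     20364            108          0.005

wsi_sclerotic_proportion(q)        # 0.1764 — matches the generator truth
mean_iou(iou_per_class(res$wsi_mask, ph$truth_mask))  # 1 (noise-free phantom)
```

The model-free blob detector finds all six glomeruli (F1 = 1), the palette
segmenter is exact on a noise-free phantom (mean IoU = 1), and the
recovered per-glomerulus sclerotic proportions (52.2%, 28.9%, ...) match
the area fractions the generator drew.

Prognosis on a synthetic cohort (46 patients, only the sclerosis effect
truly nonzero at −3 mL/min/1.73 m²/yr per SD):

```r
coh <- generate_cohort(cohort_spec(seed = 7))
fit_prognosis_model(filter_eligible(coh))
#> Multivariate eGFR-slope regression (n = 46, R^2 = 0.56, 2-yr window)
#>   Age                              beta   0.232 (0.541)  p = 0.671   VIF 1.1
#>   Sex (male = 1)                   beta   0.245 (0.562)  p = 0.665   VIF 1.2
#>   Hypertension (presence = 1)      beta   0.301 (0.583)  p = 0.609   VIF 1.3
#>   eGFR at renal biopsy             beta  -0.263 (0.548)  p = 0.634   VIF 1.1
#>   UPCR at renal biopsy             beta   0.051 (0.551)  p = 0.927   VIF 1.1
#>   Proportion of sclerotic regions  beta  -3.674 (0.549)  p = 5.63e-08 VIF 1.1 *
```

Only the sclerotic proportion is significant, recovering the generating
effect within sampling error; all VIFs stay near 1 under independent
covariates.

A thin command-line wrapper lives at `inst/cli/glomopipe.R`
(`detect`, `pipeline`, `prognosis` subcommands over the same functions).

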