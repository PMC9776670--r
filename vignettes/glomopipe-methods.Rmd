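---
title: "Methods: detection, segmentation and prognosis in glomopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, segmentation and prognosis in glomopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomopipe)
```

## The problem

Histopathological assessment of renal biopsies hinges on the glomeruli: the
fraction of each glomerular tuft replaced by sclerotic scar tissue carries
prognostic information for chronic kidney disease, in particular IgA
nephropathy (IgAN). Scoring that fraction by eye across a gigapixel
whole-slide image (WSI) is slow and subjective. glomopipe implements an
automated two-step pipeline: (1) detect every glomerulus on the slide with a
sliding window at reduced magnification, and (2) segment the pixels inside
each detected box into five classes — background, Bowman's space, glomerular
tuft, crescentic region and sclerotic region — then stitch the labels back
into WSI coordinates. Downstream layers turn the composite label map into
per-glomerulus and per-slide sclerotic proportions, and relate that
proportion to the patient's kidney-function trajectory (the eGFR slope) in a
multivariate regression.

The deep-network backends that would do the detection and segmentation in a
clinical deployment (region-proposal detectors, transformer segmenters) are
deliberately out of scope: they are GPU-scale artifacts trained on restricted
data. glomopipe defines their I/O contracts, ships deterministic reference
backends that honour those contracts, and focuses on everything around them —
the geometry, the merging, the stitching, the quantification and the
statistics — which is where the reproducible science lives.

## Coordinate frames and geometry

All positions and lengths are expressed in microns in the WSI frame (origin
top-left, x rightward, y downward); rasters attach a `pixel_frame` carrying
microns-per-pixel. Conversions round half-up for lengths, and floor origins /
ceil far edges for boxes, so a pixel box never under-covers its micron box.
Pixel boxes are 0-based and half-open.

The sliding-window grid uses 2000 µm square windows with 10% overlap
(a 200 µm strip), scanned row-by-row, left-to-right. The final window per
axis is clamped to the slide edge rather than padded, which guarantees exact
coverage without inventing out-of-slide pixels. Detection runs at a frame
downsampled by an integer factor (default 8, i.e. 40× optical to 5×
working magnification).

**Duplicate merging.** A glomerulus near a window border is detected once per
window; the fragments must be fused. Boxes overlapping by 35% or more are
merged into their bounding-box union, transitively, and the procedure is
iterated to a fixpoint (a fresh union may overlap further boxes). The overlap
ratio is intersection over the *smaller* box's area, not IoU: the typical
duplicate pair is a thin clipped fragment against a nearly complete box, and
an IoU-based rule would systematically under-trigger on exactly those pairs.
The 200 µm strip guarantees that any glomerulus up to ~200 µm wide appears
complete in at least one window, so the fragment nests inside the complete
box and the min-area ratio is 1. Both the ratio definition and the threshold
are configurable, and merging can optionally be restricted to the
inter-window overlap strips (`grid_overlap_strips()`); the default merges
globally, which is a superset of strip-restricted behaviour and simpler to
reason about. A merged box takes the maximum confidence of its constituents —
a duplicate should not dilute the best evidence.

**Detection evaluation** uses greedy one-to-one matching in descending box
IoU with a 0.5 acceptance threshold (standard detection practice; the
threshold is a parameter), and F1 with the 0/0 → 0 convention.

## Segmentation and stitching

Each merged box is cropped with a 20 µm margin on all sides (one tenth of
the ~200 µm textbook glomerulus diameter), clipped at slide edges, and passed
to the segmenter, which must return a label matrix of the crop's shape.
Predicted labels — including those of margin pixels — are repositioned into a
full-WSI label map initialised to background, so everything the detector
missed is background by construction. Margin write-back can be disabled
(`write_margin = FALSE`) to restrict labels to the unmargined box; both
behaviours are supported because the choice is not observable from
published composites.

Where two crops overlap, a non-background label always beats background, and
among competing non-background labels the crop whose box centre is nearer
wins, with ties going to the lower glomerulus id. This rule is deterministic
and order-free; a `last_write` alternative is provided. Real glomeruli rarely
overlap after merging, so the rule matters mainly for robustness.

An optional per-channel mean/SD colour transfer to a reference tile
(`normalize_color()`) is available as a minimal stain-variation correction;
it is deliberately simple and swappable.

## The phantom generator

Because clinical WSIs are restricted, the test bed is synthetic. A phantom
slide is a white background carrying non-overlapping glomeruli, each drawn
as two concentric similar ellipses: the outer ellipse bounds the interior of
Bowman's capsule, the inner (72% linear scale) is the tuft, and the ring
between them is Bowman's space. Lesions are angular wedges: a sector of the
tuft becomes sclerotic, a sector of the ring becomes a crescent. The wedge is
defined in the ellipses' *parametric* angle, for which the enclosed area
fraction equals the angle fraction exactly for concentric similar ellipses —
so a target area fraction maps to a wedge in closed form and pixelation is
the only error source (empirically below 0.5% at 1–2 µm/px for 200 µm
glomeruli; the tests allow ±2%).

Each class is painted a distinct RGB centroid, pairwise separated by at least
100 intensity units, plus optional Gaussian noise. This makes the shipped
nearest-palette-colour segmenter *exact* at noise 0, giving the pipeline an
analytic end-to-end ground truth: with the oracle detector and the palette
segmenter, the stitched composite must reproduce the truth mask bit for bit,
and the test suite asserts exactly that.

Defaults are chosen as study conditions, stated once: 200 µm mean diameter
(log-normal 6% jitter, axis ratio 0.8–1), 2 µm/px working calibration
(scanner-native 0.23 µm/px is supported but produces rasters ~75× larger for
no testing benefit), zero lesion fractions and zero noise unless specified,
and a 50 µm minimum gap between bounding boxes so that the 20 µm
margin-padded crops of distinct glomeruli can never overlap — which makes
stitched class areas exactly conserved. Placement is rejection sampling with
a retry cap; infeasible requests fail loudly. All randomness flows through
one seeded generator per call; the seed fully determines the output.

What the phantom does *not* emulate: PAS staining appearance, tubules,
vessels, interstitium, scanner artefacts, overlapping glomeruli, or
non-elliptical lesion geometry. Passing tests therefore demonstrate the
correctness of the pipeline machinery — geometry, merging, stitching,
quantification, statistics — not the performance of any trained model on
real tissue.

## Quantification and evaluation

Class areas are pixel counts times the squared calibration. The sclerotic
proportion of a glomerulus is sclerotic area over the *whole tuft* (tuft +
sclerotic): a globally sclerosed glomerulus with no remaining tuft scores 1,
and a glomerulus with neither tuft nor sclerosis is undefined and excluded
from slide-level summaries. The slide-level summary defaults to the
unweighted mean over glomeruli (the "mean proportion" used as the prognostic
variable); an area-pooled mode is provided for sensitivity analysis.

Per-class IoU is intersection over union of the per-class pixel sets; a
class absent from both masks is excluded from the mean rather than scored 1,
which would inflate results on lesion-free crops (configurable by filtering
the returned vector). Fold aggregation pools pixel counts within a fold
(micro-average) before the ratio, then reports mean and standard error
(sample SD/√k) across folds; fold assignments are caller-supplied. Sample
comparisons use Welch's unequal-variance t-test via `stats::t.test`.

## eGFR-slope prognosis regression

Each patient's kidney-function trajectory is summarised as the OLS slope of
eGFR over time, restricted to visits within 2 years of biopsy (closed
interval — a visit exactly at 2 years is included; the window is a
parameter). Eligibility mirrors standard IgAN study criteria: age ≥ 18 at
biopsy, no end-stage renal failure at biopsy (eGFR ≥ 15, plus an explicit
flag when present), and at least 1 year of follow-up.

The multivariate model regresses the slope on six predictors: age, sex
(male = 1), hypertension (present = 1), eGFR at biopsy, UPCR at biopsy, and
the slide-level sclerotic proportion. Predictors — binaries included — are
z-scored, so each coefficient is a *standardized partial regression
coefficient*: the slope change in mL/min/1.73 m²/yr per within-cohort SD of
the predictor. The outcome is left in raw slope units by default, which is
what makes coefficients of magnitude 2–3 with SEs near 1 interpretable;
`standardize_outcome = TRUE` gives the fully standardized (unitless)
variant, under which an orthogonal predictor's beta reduces to its Pearson
correlation with the outcome (a property the tests exploit). Raw-scale
coefficients are reported alongside. Per-coefficient p-values are two-sided
t-tests from the OLS fit; no multiple-testing correction is applied, since
the report mirrors tables that present raw p-values. Multicollinearity is
diagnosed with VIF = 1/(1 − R²ⱼ), implemented from the definition and
cross-checked in the tests against an independent implementation; exact
linear dependence among predictors is an error naming the dependent columns.

The synthetic cohort generator draws covariates from distributions spanning
realistic adult IgAN ranges (age ~ N(46, 15) truncated to 18–85, eGFR at
biopsy ~ N(65, 25) truncated to 16–120, UPCR log-normal around 1.2 g/g,
sclerotic proportion Beta(1, 20), sex and hypertension Bernoulli near 55%
and 60%), builds the true slope as a linear combination of the z-scored
covariates (default effects: only sclerosis acts, at −3 per SD) plus
N(0, 3) patient-level noise, and observes eGFR at 8 evenly spaced visits
over 2 years with N(0, 2) measurement noise. True slopes are retained so
recovery tests can compare against construction. At zero noise, OLS recovers
the effects to machine precision; at the default noise and n = 500, the
sclerosis effect is recovered within sampling error and is essentially
always significant, while VIFs stay near 1 under independent covariates.

## Numerical choices and problem sizes

Rounding: half-up for micron→pixel lengths (base `round()` is
round-half-even); floor/ceil for box origins/far edges. Merging iterates
transitive closure to a fixpoint and sorts output canonically, so results
are independent of input order. Stitching ties break to the lower
glomerulus id. Degenerate inputs error with named conditions
(`calibration error`, `invalid parameter`, `contract violation`,
`generation error`, `undefined result`, `multicollinearity error`) rather
than returning silent NAs, except where the contract defines an
undefined-flag (`NA` IoU for absent classes, `NA` proportion for empty
glomeruli).

The test suite and the acceptance script run phantoms up to 8000 × 6000 µm
at 2 µm/px (12 megapixels), 500 random box sets for merge properties, 1000
random 64 × 64 mask pairs for IoU equivalence, 20 jitter seeds for the
degradation ordering, and 50 cohorts of n = 500 for parameter recovery —
sizes chosen so the full analytic contract is exercised on a single CPU in
a couple of minutes.

## Known limitations

- The phantom's colour-separable classes make segmentation trivially exact
  for the palette backend; it validates the pipeline, not segmentation
  difficulty. Realistic performance requires trained backends plugged into
  the same contracts.
- The merge rule's behaviour for glomeruli wider than the overlap strip
  (> 200 µm) depends on fragment geometry; the shipped tests cover the
  340 µm straddling case explicitly.
- The prognosis model is plain OLS: no mixed effects across visits, no
  treatment adjustment, no survival modelling.
- `wsi_raster` holds the base-resolution raster in memory; pyramidal slide
  formats should be tiled upstream before entering the pipeline.
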