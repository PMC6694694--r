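---
title: "Automated DR assessment from fundus photographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated DR assessment from fundus photographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fundusdr)
```

## The problem

Diabetic retinopathy (DR) is staged from colour fundus photographs by the
lesions they show: microaneurysms define mild non-proliferative DR (NPDR),
hemorrhages and hard exudates mark moderate disease, extensive hemorrhages
signal severe NPDR, and neovascular change defines proliferative DR (PDR).
In community screening with non-mydriatic cameras a large fraction of
photographs is unreadable, so any automated grader needs a quality gate in
front of its staging rules, and clinical interpretation benefits from
*quantified* lesion burden, not just a stage label.

`fundusdr` implements a classical (non-deep-learning) assessment pipeline:
morphology- and colour-rule-based lesion detection with a small margin
classifier, a decision-rule stage cascade, pixel-level lesion
quantification, and the screening statistics used to evaluate such a
grader against clinician reference standards. Because no screening imagery
is distributed with the package, validation rests on a seeded synthetic
scene generator with exact per-pixel ground truth.

## Pipeline

For one photograph the stages are:

1. **ROI extraction** (`establish_roi`). Adaptive luminance thresholding
   (pixel brighter than its local mean minus an offset; window 1/8 of the
   frame side) combined with a near-black floor; the largest connected
   bright component is hole-filled and compared with an ideal disc
   template at its centroid (Jaccard >= 0.55), falling back to the
   template when the component is ragged. Frames without a dark border
   return the full frame minus a one-pixel margin.
2. **Denoising** (`denoise`). A per-channel 3x3 median (radius
   configurable). Radius 1 is the default: it removes impulse noise while
   preserving vessels two pixels wide and the smallest microaneurysms.
   Larger radii measurably erase thin vessels, which is why the default is
   deliberately small.
3. **Normalisation** (`normalize_image`). Images are matched to a standard
   reference in the HSL decomposition: lightness is linearly rescaled to
   the reference mean/SD over the ROI, saturation is matched
   multiplicatively on its mean, hue is untouched, and the result is
   clipped to [0, 255]. HSL was chosen over HSV/Lab because it keeps the
   lightness/saturation axes independent enough for a two-moment match
   while remaining hue-preserving; the reference is a generated clean
   scene shipped as `standard_profile()`, and users may substitute their
   own profile.
4. **Vessel segmentation** (`segment_vessels`). A multi-orientation line
   operator on the green channel (the channel with the strongest vessel
   contrast): at 12 orientations and two line lengths (9 and 17 px at 512
   px width) the response is the excess of the oriented line mean over the
   local neighbourhood mean of the inverted channel. Three guards matter
   in practice: responses are suppressed where the pixel is not darker
   than its surround (the operator otherwise rims bright/dark boundaries),
   a band along the field boundary is excluded (the black background
   otherwise dominates the local mean), and responses near the core of any
   thick dark-red region are excised - vessels are thin, so anything with
   a distance-transform core above ~4.5 px is lesion, not vessel. Small
   or compact residual components are removed. An optional per-pixel
   colour classifier (`train_vessel_classifier`) can refine candidates;
   it is off by default because the line operator alone meets the Dice
   targets on the synthetic suite.
5. **Optic-disc localisation** (`locate_optic_disc`). Bright blobs above
   the 97th ROI luminance percentile are scored by a weighted sum of four
   normalised terms: brightness percentile (0.30), circularity (0.20),
   vessel convergence - relative vessel density in an annulus around the
   candidate (0.25) - and a size prior centred on the expected disc radius
   of 0.13 ROI radii (0.25). The size prior is what keeps small, perfectly
   round exudates from outscoring a disc whose thresholded blob is ragged.
   Low-confidence results are returned flagged, never raised, and feed the
   quality gate.
6. **Lesion detection** (`detect_red_lesions`, `detect_bright_lesions`,
   `detect_prp_scars`). Red lesions: small candidates from a dark top-hat
   (closing minus image) of the green channel at a small scale
   (disc radius / 15), large candidates from a colour rule (HSL lightness
   < 0.32, reddish hue); the vessel tree is cut out of the candidate map
   first (the colour rule matches vessels too, and dark lesions would
   otherwise merge with the network into one giant component); candidates
   inside the disc or overlapping the vessel map by >= 20% are suppressed,
   and the survivors are accepted or rejected by a linear SVM on region
   features (area, eccentricity, circularity, saturation, lightness,
   green-channel contrast, boundary gradient), then split at the
   microaneurysm/hemorrhage area boundary of 30 px at 512 px width
   (scaled by (width/512)^2). Bright lesions: a bright top-hat of the
   lightness channel with a structuring element *larger than the largest
   expected lesion* (disc radius / 1.4 - a smaller element preserves the
   lesions under opening and the top-hat vanishes), an absolute lightness
   floor, disc exclusion with margin, then a fixed two-feature rule:
   sharp-edged candidates (mean boundary gradient >= 25 gray levels/px)
   are exudates, fuzzy pale ones cotton-wool spots. Photocoagulation
   scars: round, similar-sized pale spots (saturation <= 0.65, which
   separates them from yellow exudates) in the peripheral annulus beyond
   0.45 ROI radii; a scene is PRP-positive at >= 10 spots with size
   coefficient of variation <= 0.6.
7. **Quality gate** (`assess_quality`). Five scores: high-frequency energy
   (mean absolute Laplacian of luminance over the eroded ROI; below 4.0 =>
   fuzzy), dark fraction (luminance < 30; above 0.15 => dark_area),
   saturated fraction (any channel >= 250; above 0.25 => overexposed),
   eyelash score (area of elongated dark components touching the field
   boundary, relative to the ROI; above 0.002 => eyelash), and decentring
   (ROI centroid offset from the frame centre; above 0.13 ROI radii =>
   decentered). The decentring score is deliberately frame-relative: a
   position-deviated photograph shifts the whole field, leaving disc
   position *within* the ROI unchanged, so a disc-relative measure cannot
   see it. Thresholds were calibrated once on the seeded degradation suite
   (`scripts/calibrate_quality.R`) and frozen in the default
   configuration.
8. **Staging** (`grade_dr`). A first-match rule cascade: UNGRADABLE when
   the gate fails (absorbing); PRP on a positive scar pattern; DR3 when
   hemorrhage counts reach 20 in all four quadrants *or* total red-lesion
   area reaches 8000 px (at 512 px width) - an adaptation of the clinical
   4-2-1 severe-NPDR rule to what photographs show, with the area fallback
   standing in for venous beading and IRMA, which are not reliably visible
   on non-mydriatic photographs; DR2 on any hemorrhage or bright lesion;
   DR1 on microaneurysms only; DR0 otherwise. An experimental PDR rule
   (large confluent red area) exists but is off by default, because
   proliferative change is not reliably assessable without angiography.
   The cascade is monotone by construction: adding lesions can only move
   the stage upward.
9. **Quantification** (`quantify_lesions`). Six indices per image: total
   area, lesion count and maximum single-lesion area for the hemorrhage
   family (microaneurysm + hemorrhage; a config switch can exclude
   microaneurysms) and the exudate family (exudate + cotton-wool). Areas
   are raw pixel counts - no mm^2 calibration is attempted. Sample SDs use
   the n-1 denominator so group summaries compose exactly with the
   summary-statistics ANOVA.

## Evaluation statistics

`evaluation`-module functions mirror how screening studies report:
sensitivity (diseased correctly diagnosed), specificity (non-diseased
correctly diagnosed), missed-diagnosis rate = 1 - sensitivity,
misdiagnosis rate = 1 - specificity, PPV/NPV, unweighted Cohen's kappa
with the qualitative bands (<0.2 poor, 0.21-0.40 fair, 0.41-0.60 moderate,
0.61-0.80 good, >0.81 excellent), and ROC by threshold sweep with
trapezoid AUC (equal to the pairwise concordance statistic).

One-way ANOVA is computed **from group summary statistics**: with group
sizes $n_i$, means $\bar x_i$ and SDs $s_i$,
$SS_b = \sum_i n_i(\bar x_i - \bar x)^2$ about the weighted grand mean and
$SS_w = \sum_i (n_i - 1) s_i^2$, giving
$F = \frac{SS_b/(k-1)}{SS_w/(N-k)}$ - identical to a raw-data ANOVA on any
dataset with those summaries (property-tested against `lm`). Pairwise
comparisons use Fisher's LSD with the pooled error:
$SE_{ij} = \sqrt{MS_w (1/n_i + 1/n_j)}$, unadjusted two-sided t p-values
on $N - k$ df, and $CI_{95} = \Delta \pm t_{0.975, N-k} SE$. The published
pairwise table this package reproduces has exactly this SE and df
structure, which identifies LSD even though the post-hoc method is not
named there; Bonferroni is available as an option. p-values below 0.001
are displayed "< 0.001" to match table formatting.

The shipped `published_group_summaries()` and
`published_screening_table()` CSVs carry the per-group lesion summaries
and the clinician-vs-system outcome counts of a community screening study
of 19,904 photographs; the acceptance script recomputes the F statistics,
the LSD comparison, the 42.0% disqualification rate and the 17.3% DR
prevalence among qualified images from them.

## The synthetic scene generator

`render_scene()` emulates 45-degree non-mydriatic photographs at a
512 x 512 desk-scale canvas (camera-native resolution is several times
larger; every pixel threshold is resolution-relative so behaviour
transfers): a circular field (radius 0.46 of the frame) on a near-black
background, radial vignetting, a bright disc (radius 0.14 ROI radii,
displaced 0.55 ROI radii nasally by laterality), a darker macula on the
temporal side, and a recursively branching vessel tree rooted at the disc
(five trunks, width 6 px decaying by 0.72 per branch level, wiggling
random walk). Lesions are planted with exact pixel-area bookkeeping:
microaneurysms (5-20 px), hemorrhages (ellipses, by default 50-500 px),
exudates (sharp yellow), cotton-wool spots (pale, soft-alpha edges,
fuzzy), photocoagulation scars (pale round spots in the periphery). Red
lesions are placed off-vessel (small ones strictly; large ones may cross
a vessel marginally, kept under the 20% overlap invariant), all lesions
clear of the disc and inside the field. A per-class contrast parameter
in (0, 1] scales colour departure from the local retina and is the
difficulty dial for property tests. All randomness derives from one scene
seed (cohort seeds fan out through a documented integer splitting scheme),
so any scene is reproducible in isolation.

Quality degradations (`degrade`) implement the five disqualification
causes: Gaussian blur (sigma = 12 x severity px), a dark patch covering
about severity/2 of the field, eyelash-like dark intrusions from the top,
global overexposure (gain 1 + 3 x severity plus offset), and decentring
(field shifted by half the severity times the width).

The default cohort (`dr_cohort_spec`) has three severity groups of
39/29/23 scenes. Lesion-load templates are calibrated so planted
total-area means increase strictly with severity while lesion *counts*
peak in the middle group - in advanced disease lesions enlarge and fuse,
so counts drop while areas grow. Group 1 mixes microaneurysm-only scenes
with mild hemorrhage/exudate loads, group 2 has many moderate lesions
(18-30 hemorrhages of 150-380 px), group 3 fewer but large ones (8-14 of
900-2000 px). Stage labels for accuracy measurements are the stages the
*planted* lesions imply under the active rule table (`truth_stage`), so
cohort accuracy isolates detection performance from rule ambiguity.

**What passing these tests does and does not show.** The generator
reproduces the geometry and photometry that drive this pipeline's design
- thin dark vessels, a bright disc, small dark and bright lesions on a
textured field, the five degradation modes - but not media opacity,
illumination gradients from pupil vignetting, laser scar pigment rings,
camera compression artefacts, or the continuum of real lesion morphology.
Passing the suite shows the algorithms are correctly implemented and
internally consistent at realistic contrast; it does not certify clinical
performance on real photographs.

## Numerical choices and edge cases

* Pixel coordinates are 0-based (row, col) in the documentation sense but
  follow R's 1-based indexing internally; areas are raw pixel counts.
* Overlays paint saturated green (0,255,0) over red-family lesions and
  saturated blue (0,0,255) over bright-family lesions so marked areas can
  be recounted bit-exactly from the rendered PNG; overlapping pixels are
  painted once, green over blue by default (configurable).
* The stage enum keeps PDR distinct from DR3; a configurable collapse map
  (`grading$collapse_pdr_to_dr3`) pools them for comparison against
  graders that do not separate the two.
* Degenerate inputs are first-class: all-black frames raise a no-field
  error; zero lightness SD falls back to a mean shift with a warning;
  zero within-group variance yields an explicit infinite-F signal distinct
  from contract errors; undefined metrics (no positive reference cases,
  degenerate kappa margins, prevalence over an empty qualified set) raise
  errors naming the metric.
* The red-lesion classifier is a linear SVM stored as plain weights
  (scaling, coefficient vector, intercept), trained deterministically at
  first use from a fixed-seed generator-labelled candidate corpus and
  cached; `write_model()`/`read_model()` persist it as JSON. Identical
  data and seed reproduce identical predictions.
* Ties in disc scoring break toward the brighter candidate; ties in the
  overlay toward green; quadrant boundary pixels belong to the quadrant
  on the non-strict side of each axis.

## Problem sizes

The validation suite uses 20 scenes (14 with lesions, 6 clean) and the
default cohort 91 scenes, all at 512 x 512 - sizes chosen so the full
validation (generation, pipeline, statistics) completes in minutes on a
single core while keeping at least ~25 lesions per group for stable group
summaries. The classifier trains on candidates from 6 scenes; held-out
accuracy is checked on freshly generated ones.

## Known limitations

* No venous beading, IRMA or neovascularisation detection; severe disease
  is inferred from hemorrhage burden alone, and PDR staging is
  experimental and off by default.
* Grading is per-image; multi-field-per-eye fusion and per-patient
  aggregation are out of scope.
* No mm^2 calibration, DICOM support or macular-edema grading.
* Detected lesion areas on heavily fused lesion clusters underestimate
  planted areas by roughly 10-20%; counts on fused clusters reflect
  connected components, not planted lesions.
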