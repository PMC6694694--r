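# fundusdr

Automated assessment of diabetic retinopathy (DR) from colour fundus
photographs, with pixel-level lesion quantification and the screening
statistics needed to evaluate such a grader against clinicians.

## What it does, and for whom

Community DR screening with non-mydriatic cameras produces large volumes
of photographs that must be quality-gated, graded for DR stage, and —
ideally — quantified for lesion burden. `fundusdr` implements a classical
rule-based pipeline for this task, aimed at researchers studying automated
screening and at method developers who need a fully reproducible,
ground-truthed test bed:

* **Pre-processing** — field-of-view (ROI) extraction, median denoising,
  and HSL lightness/saturation normalisation against a standard reference
  image.
* **Anatomy** — retinal vessel segmentation by a multi-orientation line
  operator on the green channel, and optic-disc localisation by
  brightness, shape, size and vessel-convergence scoring.
* **Lesions** — red lesions (microaneurysms, hemorrhages) by dark top-hat
  morphology plus colour discrimination, filtered by a linear-SVM margin
  classifier; bright lesions (hard exudates, cotton-wool spots) by bright
  top-hat and an edge-sharpness rule; photocoagulation (PRP) scar
  patterns.
* **Grading** — an image-quality gate (fuzziness, dark area, eyelash
  interference, overexposure, decentring) and a first-match decision-rule
  cascade: UNGRADABLE → PRP → DR3 (hemorrhage count ≥ 20 in all four
  quadrants, adapted from the clinical 4-2-1 severe-NPDR rule, or total
  red-lesion area ≥ 8000 px at 512 px width) → DR2 (any hemorrhage or
  bright lesion) → DR1 (microaneurysms only) → DR0.
* **Quantification** — six indices per image: total area, count, and
  maximum single-lesion area for the hemorrhage and exudate families
  (areas in raw pixels).
* **Evaluation** — confusion matrices, sensitivity/specificity,
  missed-diagnosis and misdiagnosis rates, PPV/NPV, unweighted Cohen's
  kappa with qualitative bands, ROC/AUC, one-way ANOVA **from group
  summary statistics** (`SS_w = Σ(nᵢ−1)sᵢ²`, `SS_b = Σnᵢ(x̄ᵢ−x̄)²`,
  `F = MS_b/MS_w`) and Fisher-LSD pairwise comparisons with the pooled
  error term (`SE = √(MS_w(1/nᵢ+1/nⱼ))`, CI₉₅ = Δ ± t₀.₉₇₅,df·SE).
* **Synthetic scenes** — a seeded generator of fundus-like photographs
  (circular field, branching vessel tree, bright disc, macula, planted
  lesions with exact pixel areas, five quality degradations) that serves
  as the package's entire validation bed.

No study imagery ships with the package; two small CSVs of *published*
summary tables (per-group lesion summaries and a clinician-vs-system
outcome table from a 19,904-image screening program) feed the statistics
modules.

## Worked example

```r
library(fundusdr)
cfg <- dr_config()

# a moderate-NPDR-like synthetic scene with known ground truth
sc <- render_scene(scene_spec(
  seed = 2003,
  lesions = list(microaneurysm = list(count = 2),
                 hemorrhage = list(count = 4, area = c(80, 300)),
                 exudate = list(count = 3))))

res <- grade_image(sc$image, cfg)
res$stage
#> [1] "DR2"
res$grading$rule_path
#> [1] "qualified" "moderate"
unlist(res$record$quant[-1])
#> hemorrhage_total_area_px         hemorrhage_count   hemorrhage_max_area_px
#>                      651                        6                      208
#>    exudate_total_area_px            exudate_count      exudate_max_area_px
#>                      382                        3                      175
quantify_truth(sc$truth)$hemorrhage_total_area_px   # planted truth
#> [1] 660
```

The stage is DR2 because hemorrhages are present but neither the
per-quadrant count (20) nor the severe area threshold is reached; the six
quantification indices are pixel counts over the detected lesion regions
(651 detected vs 660 planted hemorrhage-family pixels here; the count of 6
pools the 4 hemorrhages with the 2 microaneurysms).

The screening statistics reproduce published summary tables directly:

```r
pub <- published_group_summaries()
g <- pub[pub$index == "hemorrhage_total_area_px", ]
a <- anova_oneway_summary(g)
round(a$F, 3); format_p(a$p)
#> [1] 16.034
#> [1] "< 0.001"
lsd_pairwise(a, g)[1, c("mean_difference", "standard_error", "p")]
#>   mean_difference standard_error            p
#> 1       -14297.54       3042.766 9.594361e-06
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/fundusdr grade scenes/ --out results --overlays
Rscript inst/cli/fundusdr eval pairs.csv --out results
Rscript inst/cli/fundusdr synth --n 10 --seed 7 --out scenes
Rscript inst/cli/fundusdr anova summaries.csv
```

## Configuration

All thresholds live in one nested list (`dr_config()`), overridable from
a YAML file with unknown keys rejected. Key groups: `roi`, `preprocess`,
`vessels`, `disc`, `quadrants`, `red_lesions`, `bright_lesions`, `prp`,
`quality`, `grading`, `overlay`, `quantify`, `eval`, `synthetic`. See the
methods vignette (`vignettes/fundusdr-methods.Rmd`) for what each
parameter means, the defaults, and why.
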