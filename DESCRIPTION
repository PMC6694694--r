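Package: fundusdr
Title: Automated Fundus Image Assessment and Lesion Quantification for
    Diabetic Retinopathy Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-implementation of a rule-based automated diabetic-retinopathy
    (DR) assessment pipeline for non-mydriatic colour fundus photographs:
    field-of-view extraction, reference-image normalisation, vessel and
    optic-disc segmentation, red-lesion (microaneurysm/hemorrhage) and
    bright-lesion (exudate/cotton-wool) detection by mathematical morphology
    and a margin classifier, photocoagulation-scar recognition, image-quality
    gating, decision-rule DR staging, and pixel-level lesion quantification.
    Includes a seeded synthetic fundus-scene generator with exact ground
    truth for validation, and the screening-evaluation statistics used in DR
    screening studies (confusion matrices, sensitivity/specificity, Cohen's
    kappa, ROC/AUC, one-way ANOVA from group summaries, and Fisher-LSD
    pairwise comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
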