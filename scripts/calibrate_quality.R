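#!/usr/bin/env Rscript
# Calibration of the image-quality gate thresholds on the seeded
# degradation suite. For each degradation mode the relevant score is
# measured on clean scenes and on degraded copies at moderate severity;
# the suggested threshold is the midpoint of the separating gap (for
# fuzziness, the geometric midpoint of the clean and blurred high-frequency
# energies). The resulting values are frozen in the package's default
# configuration; re-run this script after changing the generator or the
# score definitions.
#
# Usage: Rscript scripts/calibrate_quality.R [--seed N]

suppressMessages(library(fundusdr))

args <- commandArgs(trailingOnly = TRUE)
seed <- 555L
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

n <- 6L
cfg <- dr_config()
scores <- list()
for (i in seq_len(n)) {
  sc <- render_scene(scene_spec(seed = seed + i))
  roi <- establish_roi(sc$image, cfg)
  clean <- assess_quality(sc$image, roi, cfg = cfg)
  row <- list(clean = clean)
  for (mode in c("blur", "dark_patch", "eyelash", "overexpose", "decenter")) {
    img <- degrade(sc$image, mode, severity = 0.6, seed = seed + 100L + i)
    roi_d <- tryCatch(establish_roi(img, cfg), error = function(e) roi)
    row[[mode]] <- assess_quality(img, roi_d, cfg = cfg)
  }
  scores[[i]] <- row
}

pull <- function(cond, field) sapply(scores, function(r) r[[cond]][[field]])

cat("score ranges (clean vs degraded at severity 0.6):\n")
report <- function(field, clean_v, deg_v, suggestion) {
  cat(sprintf("  %-18s clean [%.4g, %.4g]   degraded [%.4g, %.4g]   -> %s\n",
              field, min(clean_v), max(clean_v), min(deg_v), max(deg_v),
              suggestion))
}
fz_c <- pull("clean", "fuzzy_score"); fz_d <- pull("blur", "fuzzy_score")
report("fuzzy_score", fz_c, fz_d,
       sprintf("fuzzy_min = %.2f", sqrt(min(fz_c) * max(fz_d))))
dk_c <- pull("clean", "dark_fraction"); dk_d <- pull("dark_patch", "dark_fraction")
report("dark_fraction", dk_c, dk_d,
       sprintf("dark_frac_max = %.3f", (max(dk_c) + min(dk_d)) / 2))
el_c <- pull("clean", "eyelash_score"); el_d <- pull("eyelash", "eyelash_score")
report("eyelash_score", el_c, el_d,
       sprintf("eyelash_max = %.4f", (max(el_c) + min(el_d)) / 2))
ov_c <- pull("clean", "saturated_fraction"); ov_d <- pull("overexpose", "saturated_fraction")
report("saturated_fraction", ov_c, ov_d,
       sprintf("saturated_frac_max = %.3f", (max(ov_c) + min(ov_d)) / 2))
dc_c <- pull("clean", "decenter_px"); dc_d <- pull("decenter", "decenter_px")
roi_r <- sqrt(establish_roi(render_scene(scene_spec(seed = seed + 1L))$image,
                            cfg)$area_px / pi)
report("decenter_px", dc_c, dc_d,
       sprintf("decenter_frac_max = %.3f (fraction of ROI radius %.0f px)",
               (max(dc_c) + min(dc_d)) / 2 / roi_r, roi_r))
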