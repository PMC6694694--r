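# Validation metrics on synthetic scenes with exact ground truth: the
# quantitative evidence that the detectors and the stage rules work under
# the study-like conditions the generator emulates.

#' Detection metrics over a scene suite
#'
#' Runs the pipeline on every scene of a [validation_suite()] (or any list
#' of rendered scenes) and measures, against ground truth:
#' per-lesion recall of planted hemorrhages at or above `min_hem_px`
#' (a lesion counts as found when at least half its pixels are detected as
#' red-lesion pixels), red-lesion false positives per lesion-free scene,
#' the relative error of the detected exudate-family total area, optic-disc
#' localisation success (centre error below half the true radius), and the
#' per-scene vessel Dice overlap.
#'
#' @param scenes List of rendered scenes (each with `image`, `truth`,
#'   optional `clean` flag).
#' @param cfg Configuration.
#' @param model Red-lesion classifier (default model when `NULL`).
#' @param min_hem_px Hemorrhage size floor for the recall computation.
#' @return List of metrics (see details) plus the per-scene table.
#' @export
suite_detection_metrics <- function(scenes, cfg = dr_config(), model = NULL,
                                    min_hem_px = 50) {
  if (is.null(model)) model <- default_red_lesion_model(cfg = cfg)
  hem_found <- 0L; hem_total <- 0L
  fp_clean <- integer(); dice <- numeric(); disc_ok <- logical()
  exu_truth <- 0; exu_det <- 0
  rows <- list()
  for (sc in scenes) {
    pre <- preprocess_scene(sc$image, cfg)
    red <- detect_red_lesions(pre$normalized, pre$vessels, pre$disc, pre$roi,
                              model, cfg)
    brt <- detect_bright_lesions(pre$normalized, pre$disc, pre$roi, cfg)
    tv <- sc$truth$masks$vessel
    dice <- c(dice, 2 * sum(pre$vessels$mask & tv) /
                max(1, sum(pre$vessels$mask) + sum(tv)))
    derr <- sqrt(sum((pre$disc$center - sc$truth$disc_center)^2))
    disc_ok <- c(disc_ok, derr < 0.5 * sc$truth$disc_radius)
    detred <- red$rasters$microaneurysm | red$rasters$hemorrhage
    truthred <- sc$truth$label_raster == CLASS_CODES["hemorrhage"] |
      sc$truth$label_raster == CLASS_CODES["microaneurysm"]
    # per-lesion hemorrhage recall
    hm <- sc$truth$label_raster == CLASS_CODES["hemorrhage"]
    lab <- EBImage::bwlabel(hm)
    n_hem <- 0L; n_hit <- 0L
    if (max(lab) > 0) {
      idx_by <- split(which(lab > 0), lab[lab > 0])
      for (idx in idx_by) {
        if (length(idx) < min_hem_px) next
        n_hem <- n_hem + 1L
        if (mean(detred[idx]) >= 0.5) n_hit <- n_hit + 1L
      }
    }
    hem_total <- hem_total + n_hem; hem_found <- hem_found + n_hit
    # false positives: detected red regions mostly off any planted red lesion
    n_fp <- sum(vapply(red$regions, function(r)
      mean(truthred[r$pixels]) < 0.1, logical(1)))
    if (isTRUE(sc$clean)) fp_clean <- c(fp_clean, n_fp)
    # exudate-family areas
    tq <- quantify_truth(sc$truth)
    dq <- quantify_lesions(brt, cfg = cfg)
    exu_truth <- exu_truth + tq$exudate_total_area_px
    exu_det <- exu_det + dq$exudate_total_area_px
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = sc$image$image_id, clean = isTRUE(sc$clean),
      n_hem = n_hem, n_hit = n_hit, n_red_fp = n_fp,
      vessel_dice = dice[length(dice)], disc_err_px = derr)
  }
  list(hemorrhage_recall = if (hem_total) hem_found / hem_total else NA_real_,
       fp_per_clean_scene = if (length(fp_clean)) mean(fp_clean) else NA_real_,
       max_fp_clean_scene = if (length(fp_clean)) max(fp_clean) else NA_real_,
       exudate_area_rel_error = if (exu_truth > 0)
         abs(exu_det - exu_truth) / exu_truth else NA_real_,
       disc_success_rate = mean(disc_ok),
       vessel_dice_mean = mean(dice), vessel_dice_min = min(dice),
       per_scene = do.call(rbind, rows))
}

#' Run the pipeline over a cohort and compare to planted truth
#'
#' Grades every scene of a [simulate_cohort()] result, labels each scene
#' with the stage its planted lesions imply under the active rule table
#' ([truth_stage()]), and summarises: stage accuracy, sensitivity of
#' disease detection (planted DR1+ called DR1+), quantification reports,
#' and group summaries of the detected lesion burden.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param cfg Configuration.
#' @param model Red-lesion classifier (default model when `NULL`).
#' @return List: `stage_accuracy`, `sensitivity_dr`, `stages` /
#'   `truth_stages` vectors, `reports`, `summary` (detected group
#'   summaries), `anova` (one-way ANOVA of detected total hemorrhage area
#'   across groups).
#' @export
cohort_pipeline_metrics <- function(cohort, cfg = dr_config(), model = NULL) {
  if (is.null(model)) model <- default_red_lesion_model(cfg = cfg)
  stages <- character(); truths <- character(); reports <- list()
  for (sc in cohort$scenes) {
    res <- grade_image(sc$image, cfg, model)
    quad <- partition_quadrants(res$roi, res$disc, cfg)
    stages <- c(stages, res$stage)
    truths <- c(truths, truth_stage(sc$truth, quad, cfg))
    reports[[length(reports) + 1L]] <- res$record$quant %||%
      quant_report(sc$image$image_id, 0, 0, 0, 0, 0, 0)
  }
  names(stages) <- names(truths) <- names(cohort$assignment)
  dr_pos <- function(s) !s %in% c("DR0", "UNGRADABLE")
  summ <- summarize_groups(reports, cohort$assignment)
  tot <- summ[summ$index == "hemorrhage_total_area_px", ]
  anova <- anova_oneway_summary(tot)
  list(stage_accuracy = mean(stages == truths),
       sensitivity_dr = if (any(dr_pos(truths)))
         mean(dr_pos(stages)[dr_pos(truths)]) else NA_real_,
       stages = stages, truth_stages = truths, reports = reports,
       summary = summ, anova = anova)
}

#' Three repeated quantifications of one scene
#'
#' Runs the full pipeline three times on the same image and reports whether
#' the three quantification reports are identical — the repeatability check
#' (perfect agreement corresponds to kappa 1).
#'
#' @param image A `fundus_image`.
#' @param cfg Configuration.
#' @param model Red-lesion classifier.
#' @return List: `identical` (logical), `kappa` (1 when identical),
#'   `reports`.
#' @export
repeatability_check <- function(image, cfg = dr_config(), model = NULL) {
  if (is.null(model)) model <- default_red_lesion_model(cfg = cfg)
  reps <- lapply(1:3, function(i) grade_image(image, cfg, model)$record$quant)
  same <- identical(reps[[1]], reps[[2]]) && identical(reps[[2]], reps[[3]])
  list(identical = same, kappa = if (same) 1 else NA_real_, reports = reps)
}
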