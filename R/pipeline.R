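# End-to-end per-image pipeline and the batch entry points behind the CLI.

# Shared preprocessing + anatomy steps (used by the detectors' training
# corpus as well as by grade_image).
preprocess_scene <- function(image, cfg = dr_config(), profile = NULL) {
  roi <- establish_roi(image, cfg)
  den <- denoise(image, cfg$preprocess$denoise_radius)
  profile <- profile %||% standard_profile(cfg)
  norm <- normalize_image(den, roi, profile)
  vessels <- segment_vessels(norm, roi, cfg = cfg)
  disc <- locate_optic_disc(norm, vessels, roi, cfg)
  list(roi = roi, normalized = norm, vessels = vessels, disc = disc,
       profile = profile)
}

#' Grade one fundus photograph end to end
#'
#' Runs the full pipeline: ROI extraction, denoising, normalisation against
#' the standard profile, vessel segmentation, optic-disc localisation,
#' quality gating, lesion detection (red, bright, photocoagulation scars),
#' quadrant partition, decision-rule staging and quantification. A
#' disqualified image is staged `UNGRADABLE` and lesion detection is
#' skipped.
#'
#' @param image A `fundus_image`.
#' @param cfg Configuration.
#' @param model Optional red-lesion candidate classifier.
#' @param profile Optional normalisation profile (defaults to the shipped
#'   standard profile).
#' @return A `dr_assessment` list: `record` ([grading_record()]), `stage`,
#'   `quality`, `lesions`, `grading`, plus the intermediate `roi`,
#'   `vessels`, `disc`.
#' @export
grade_image <- function(image, cfg = dr_config(), model = NULL,
                        profile = NULL) {
  stopifnot(inherits(image, "fundus_image"))
  pre <- preprocess_scene(image, cfg, profile)
  quality <- assess_quality(image, pre$roi, pre$disc, cfg)
  d <- dim(image$pixels)[1:2]
  if (!quality$qualified) {
    lesions <- lesion_set(list(), d)
    grading <- structure(list(stage = "UNGRADABLE", rule_path = "ungradable",
                              evidence = list()), class = "grading_result")
    rec <- grading_record(image$image_id, "UNGRADABLE", quality, NULL)
    return(structure(list(record = rec, stage = "UNGRADABLE",
                          quality = quality, lesions = lesions,
                          grading = grading, roi = pre$roi,
                          vessels = pre$vessels, disc = pre$disc),
                     class = "dr_assessment"))
  }
  red <- detect_red_lesions(pre$normalized, pre$vessels, pre$disc, pre$roi,
                            model, cfg)
  brt <- detect_bright_lesions(pre$normalized, pre$disc, pre$roi, cfg)
  prp <- detect_prp_scars(pre$normalized, pre$roi, pre$disc, cfg)
  if (isTRUE(attr(prp, "prp_positive"))) {
    # scars are bright and round, so the bright-lesion detector re-reports
    # them; on a scar-positive scene the scar interpretation wins
    scar <- prp$rasters$prp_scar
    keep <- vapply(brt$regions, function(r) mean(scar[r$pixels]) < 0.5,
                   logical(1))
    brt <- lesion_set(brt$regions[keep], brt$dim)
  }
  lesions <- merge_lesion_sets(red, brt, prp)
  attr(lesions, "prp_positive") <- attr(prp, "prp_positive")
  quad <- partition_quadrants(pre$roi, pre$disc, cfg)
  grading <- grade_dr(lesions, quad, quality, cfg = cfg)
  quant <- quantify_lesions(lesions, image$image_id, cfg)
  rec <- grading_record(image$image_id, grading$stage, quality, quant)
  structure(list(record = rec, stage = grading$stage, quality = quality,
                 lesions = lesions, grading = grading, quadrants = quad,
                 roi = pre$roi, vessels = pre$vessels, disc = pre$disc),
            class = "dr_assessment")
}

#' Batch grading entry point
#'
#' Grades every readable image and writes the per-image report (and
#' optional lesion overlays). Per-image failures are logged and recorded as
#' error rows; they never abort the batch.
#'
#' @param inputs Character vector of image paths and/or directories.
#' @param cfg Configuration.
#' @param out_dir Output directory for the report and overlays.
#' @param overlays Write a `<id>_overlay.png` per qualified image.
#' @param format Report format, `"csv"` or `"json"`.
#' @param quiet Suppress progress lines.
#' @return Invisibly, the list of [grading_record()]s. Raises an input
#'   error when no readable image is found.
#' @export
run_grade <- function(inputs, cfg = dr_config(), out_dir = ".",
                      overlays = FALSE, format = "csv", quiet = FALSE) {
  paths <- character()
  for (p in inputs) {
    if (dir.exists(p)) {
      paths <- c(paths, list.files(p, "\\.(png|jpe?g|tiff?)$",
                                   full.names = TRUE, ignore.case = TRUE))
    } else paths <- c(paths, p)
  }
  if (length(paths) == 0) io_error("no input images found")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- default_red_lesion_model(cfg = cfg)
  records <- list(); n_ok <- 0L
  for (p in paths) {
    t0 <- Sys.time()
    rec <- tryCatch({
      img <- read_image(p)
      res <- grade_image(img, cfg, model)
      if (overlays && res$stage != "UNGRADABLE")
        write_overlay(img, res$lesions,
                      file.path(out_dir, paste0(img$image_id, "_overlay.png")), cfg)
      n_ok <- n_ok + 1L
      res$record
    }, error = function(e) {
      r <- grading_record(sub("\\.[^.]*$", "", basename(p)), "UNGRADABLE",
                          list(flags = "error", qualified = FALSE), NULL)
      r$status <- paste0("error: ", conditionMessage(e))
      r
    })
    if (is.null(rec$status)) rec$status <- "ok"
    records[[length(records) + 1L]] <- rec
    if (!quiet)
      message(sprintf("[grade] %s -> %s (%.2fs)", basename(p), rec$stage,
                      as.numeric(Sys.time() - t0, units = "secs")))
  }
  if (n_ok == 0) io_error("no readable input images")
  write_report(records, file.path(out_dir, paste0("report.", format)), format)
  invisible(records)
}

#' Screening evaluation entry point
#'
#' Reads a CSV of `image_id, reference_label, test_label[, score]` rows and
#' writes the confusion matrix, agreement (kappa + band), one-vs-rest
#' screening metrics per label, an optional ROC (when scores are present)
#' and, when a disqualified label is configured, the cohort summary
#' (disqualification rate and DR prevalence among qualified images).
#'
#' @param pairs_csv Path to the label-pair CSV.
#' @param cfg Configuration (uses `cfg$eval`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `cm`, `kappa`, `metrics`, `roc`, `cohort`.
#' @export
run_eval <- function(pairs_csv, cfg = dr_config(), out_dir = ".") {
  if (!file.exists(pairs_csv)) io_error(paste0("no such file: ", pairs_csv))
  df <- tryCatch(read.csv(pairs_csv, stringsAsFactors = FALSE),
                 error = function(e) io_error(paste0("malformed CSV: ",
                                                     conditionMessage(e))))
  need <- c("reference_label", "test_label")
  if (!all(need %in% names(df)))
    io_error(paste0("CSV must have columns: ", paste(need, collapse = ", ")))
  bad <- which(is.na(df$reference_label) | is.na(df$test_label))
  if (length(bad))
    io_error(paste0("malformed CSV: missing label at line ", bad[1] + 1L))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cm <- confusion_matrix(df$reference_label, df$test_label)
  kap <- cohen_kappa(cm)
  labs <- rownames(cm)
  metrics <- lapply(setNames(labs, labs), function(lb)
    tryCatch(unclass(screening_metrics(cm, lb)), error = function(e) NULL))
  roc <- NULL
  if ("score" %in% names(df) && nzchar(cfg$eval$positive_labels[1] %||% "")) {
    pos <- df$reference_label %in% cfg$eval$positive_labels
    roc <- tryCatch(roc_auc(df$score, pos), error = function(e) NULL)
  }
  cohort <- NULL
  if (nzchar(cfg$eval$disqualified_label %||% "") &&
      cfg$eval$disqualified_label %in% labs) {
    cohort <- cohort_summary(cm,
                             dr_labels = intersect(cfg$eval$dr_labels, labs),
                             disqualified_label = cfg$eval$disqualified_label)
  }
  write.csv(as.data.frame.matrix(unclass(cm)),
            file.path(out_dir, "confusion_matrix.csv"))
  jsonlite::write_json(
    list(kappa = kap, metrics = metrics,
         roc = if (!is.null(roc)) list(auc = roc$auc) else NULL,
         cohort = cohort),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(list(cm = cm, kappa = kap, metrics = metrics, roc = roc,
                 cohort = cohort))
}
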