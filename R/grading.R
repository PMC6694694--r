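# Image-quality gate (disqualification) and decision-rule DR staging.

#' Assess photograph quality
#'
#' Computes the five disqualification scores and flags used in screening:
#' `fuzzy` (high-frequency energy of the field below a floor), `dark_area`
#' (fraction of the field darker than a luminance level), `overexposed`
#' (fraction of the field saturated in any channel), `eyelash` (elongated
#' dark intrusions crossing the field boundary), and `decentered` (field
#' centroid displaced from the frame centre). An image is qualified exactly
#' when no flag fires. Thresholds live in `cfg$quality` and were calibrated
#' once on the seeded degradation suite (see `scripts/calibrate_quality.R`).
#'
#' @param image A `fundus_image` (the original, not the normalised image).
#' @param roi [roi_mask()].
#' @param disc Optional [locate_optic_disc()] result; adds disc confidence
#'   to the fuzziness evidence when present.
#' @param cfg Configuration (uses `cfg$quality`).
#' @return A `quality_report`: scores, `flags` (character subset of
#'   `fuzzy, dark_area, eyelash, overexposed, decentered`), `qualified`.
#' @export
assess_quality <- function(image, roi, disc = NULL, cfg = dr_config()) {
  stopifnot(inherits(image, "fundus_image"), inherits(roi, "roi_mask"))
  qc <- cfg$quality
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  L <- luminance(px)
  m <- roi$mask
  inner <- EBImage::erode(m, EBImage::makeBrush(9, "disc")) > 0

  lap <- EBImage::filter2(L, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
  fuzzy_score <- mean(abs(lap[inner]))

  dark_fraction <- mean(L[m] < qc$dark_level)
  saturated <- (px[, , 1] >= qc$saturated_level) |
    (px[, , 2] >= qc$saturated_level) | (px[, , 3] >= qc$saturated_level)
  saturated_fraction <- mean(saturated[m])

  # eyelash: elongated dark components inside the field touching its boundary
  ring <- m & !inner
  dark <- (L < 40) & m
  dark <- prune_small(dark, 40)
  eyelash_score <- 0
  lab <- EBImage::bwlabel(dark)
  if (max(lab) > 0) {
    idx_by <- split(which(lab > 0), lab[lab > 0])
    for (idx in idx_by) {
      if (!any(ring[idx])) next
      rr <- ((idx - 1L) %% h) + 1L; cc <- ((idx - 1L) %/% h) + 1L
      span <- max(max(rr) - min(rr), max(cc) - min(cc)) + 1
      elong <- span^2 / length(idx)      # large for thin, long intrusions
      if (elong > 3) eyelash_score <- eyelash_score + length(idx)
    }
  }
  eyelash_score <- eyelash_score / roi$area_px

  idx <- which(m)
  roi_ctr <- c(mean(((idx - 1L) %% h) + 1L), mean(((idx - 1L) %/% h) + 1L))
  roi_r <- sqrt(roi$area_px / pi)
  decenter_px <- sqrt(sum((roi_ctr - c((h + 1) / 2, (w + 1) / 2))^2))

  flags <- character()
  if (fuzzy_score < qc$fuzzy_min) flags <- c(flags, "fuzzy")
  if (dark_fraction > qc$dark_frac_max) flags <- c(flags, "dark_area")
  if (eyelash_score > qc$eyelash_max) flags <- c(flags, "eyelash")
  if (saturated_fraction > qc$saturated_frac_max) flags <- c(flags, "overexposed")
  if (decenter_px > qc$decenter_frac_max * roi_r) flags <- c(flags, "decentered")

  structure(list(fuzzy_score = fuzzy_score, dark_fraction = dark_fraction,
                 saturated_fraction = saturated_fraction,
                 eyelash_score = eyelash_score, decenter_px = decenter_px,
                 disc_confidence = if (is.null(disc)) NA_real_ else disc$confidence,
                 flags = flags, qualified = length(flags) == 0),
            class = "quality_report")
}

#' Decision-rule DR staging
#'
#' First-match rule cascade over the lesion evidence (all thresholds in
#' `cfg$grading`):
#' 1. `ungradable` - the quality gate failed (absorbing: no lesion evidence
#'    can override it);
#' 2. `prp_pattern` - the photocoagulation-scar pattern is positive;
#' 3. `severe` - hemorrhage count reaches the per-quadrant threshold in all
#'    four quadrants, or total red-lesion area reaches the severe fallback
#'    (the 4-2-1-style rule adapted to photograph-visible evidence);
#' 4. `pdr_confluent` (optional, off by default) - confluent red area near
#'    the disc in experimental PDR mode;
#' 5. `moderate` - any hemorrhage or any bright lesion;
#' 6. `mild` - microaneurysms only;
#' 7. `no_dr` - otherwise.
#'
#' @param lesions Merged [lesion_set()] for the image.
#' @param quadrants [partition_quadrants()] output on the same frame.
#' @param quality [assess_quality()] output.
#' @param prp_positive Logical; the scar-pattern verdict (defaults to the
#'   `prp_positive` attribute of `lesions`, else `FALSE`).
#' @param cfg Configuration (uses `cfg$grading`).
#' @return A `grading_result`: `stage`, `rule_path`, `evidence`.
#' @export
grade_dr <- function(lesions, quadrants, quality, prp_positive = NULL,
                     cfg = dr_config()) {
  stopifnot(inherits(lesions, "lesion_set"), inherits(quadrants, "quadrant_map"))
  if (!identical(dim(quadrants$labels), as.integer(lesions$dim)))
    contract_error("quadrant map and lesion set differ in frame size")
  if (is.null(prp_positive))
    prp_positive <- isTRUE(attr(lesions, "prp_positive"))
  gc <- cfg$grading
  w <- lesions$dim[2]

  cls <- vapply(lesions$regions, function(r) r$class, character(1))
  areas <- vapply(lesions$regions, function(r) r$area_px, numeric(1))
  hem <- cls == "hemorrhage"; ma <- cls == "microaneurysm"
  bright <- cls %in% c("exudate", "cottonwool")
  red_area <- sum(areas[hem | ma])
  quad_counts <- integer(4)
  for (r in lesions$regions[hem]) {
    q <- quadrants$labels[round(r$centroid[1]), round(r$centroid[2])]
    if (q >= 1) quad_counts[q] <- quad_counts[q] + 1L
  }
  evidence <- list(
    n_microaneurysm = sum(ma), n_hemorrhage = sum(hem),
    n_bright = sum(bright), n_prp_scar = sum(cls == "prp_scar"),
    red_lesion_area_px = red_area,
    bright_lesion_area_px = sum(areas[bright]),
    hemorrhages_per_quadrant = quad_counts,
    prp_positive = prp_positive)

  path <- character()
  decide <- function(stage, rule) {
    if (stage == "PDR" && isTRUE(gc$collapse_pdr_to_dr3)) stage <- "DR3"
    structure(list(stage = stage, rule_path = c(path, rule),
                   evidence = evidence), class = "grading_result")
  }
  if (!quality$qualified) return(decide("UNGRADABLE", "ungradable"))
  path <- c(path, "qualified")
  if (prp_positive) return(decide("PRP", "prp_pattern"))
  h_q <- gc$hemorrhages_per_quadrant
  a_severe <- scale_area(gc$a_severe_px, w)
  if (all(quad_counts >= h_q) || red_area >= a_severe)
    return(decide("DR3", "severe"))
  if (isTRUE(gc$pdr_mode) && red_area >= scale_area(gc$a_pdr_px, w))
    return(decide("PDR", "pdr_confluent"))
  if (any(hem) || any(bright)) return(decide("DR2", "moderate"))
  if (any(ma)) return(decide("DR1", "mild"))
  decide("DR0", "no_dr")
}

#' Stage implied by planted ground truth
#'
#' Applies the same decision rules to a scene's ground-truth regions: the
#' label a perfect detector would receive under the active rule table. Used
#' to stage-label synthetic cohorts.
#'
#' @param truth A [ground_truth()].
#' @param quadrants A [partition_quadrants()] result for the scene.
#' @param cfg Configuration.
#' @return Stage string.
#' @export
truth_stage <- function(truth, quadrants, cfg = dr_config()) {
  d <- dim(truth$label_raster)
  regions <- truth_regions_as_lesions(truth)
  ls <- lesion_set(regions, d)
  qual <- list(qualified = TRUE, flags = character())
  grade_dr(ls, quadrants, qual, prp_positive = NULL, cfg = cfg)$stage
}

# Ground-truth regions as lesion_region objects with exact pixel supports.
truth_regions_as_lesions <- function(truth) {
  d <- dim(truth$label_raster)
  h <- d[1]
  out <- list()
  if (nrow(truth$regions) == 0) return(out)
  # regions of one class are disjoint; split that class's pixels by
  # connected components and match to the region table by centroid
  for (cl in unique(truth$regions$class)) {
    mask <- truth$label_raster == CLASS_CODES[cl]
    lab <- EBImage::bwlabel(mask)
    idx_by <- split(which(lab > 0), lab[lab > 0])
    for (k in seq_along(idx_by)) {
      out[[length(out) + 1L]] <- lesion_region(length(out) + 1L, cl,
                                               idx_by[[k]], d)
    }
  }
  out
}
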