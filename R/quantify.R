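#' Per-image lesion quantification report
#'
#' The six pixel-level indices reported per photograph: total area, lesion
#' count and maximum single-lesion area for the hemorrhage family and for
#' the exudate family. Areas are raw pixel counts (no mm^2 calibration).
#'
#' @param image_id Identifier.
#' @param hemorrhage_total_area_px,hemorrhage_count,hemorrhage_max_area_px
#'   Hemorrhage-family indices.
#' @param exudate_total_area_px,exudate_count,exudate_max_area_px
#'   Exudate-family indices.
#' @return A `quant_report`.
#' @export
quant_report <- function(image_id,
                         hemorrhage_total_area_px, hemorrhage_count,
                         hemorrhage_max_area_px,
                         exudate_total_area_px, exudate_count,
                         exudate_max_area_px) {
  v <- c(hemorrhage_total_area_px, hemorrhage_count, hemorrhage_max_area_px,
         exudate_total_area_px, exudate_count, exudate_max_area_px)
  if (any(v < 0)) contract_error("quantification indices must be non-negative")
  chk <- function(total, count, mx, fam) {
    if (mx > total) contract_error(paste0(fam, ": max area exceeds total area"))
    if ((count == 0) != (total == 0) || (count == 0) != (mx == 0))
      contract_error(paste0(fam, ": count, total and max must vanish together"))
  }
  chk(hemorrhage_total_area_px, hemorrhage_count, hemorrhage_max_area_px, "hemorrhage")
  chk(exudate_total_area_px, exudate_count, exudate_max_area_px, "exudate")
  structure(list(image_id = as.character(image_id),
                 hemorrhage_total_area_px = as.integer(hemorrhage_total_area_px),
                 hemorrhage_count = as.integer(hemorrhage_count),
                 hemorrhage_max_area_px = as.integer(hemorrhage_max_area_px),
                 exudate_total_area_px = as.integer(exudate_total_area_px),
                 exudate_count = as.integer(exudate_count),
                 exudate_max_area_px = as.integer(exudate_max_area_px)),
            class = "quant_report")
}

quant_index_names <- c("hemorrhage_total_area_px", "hemorrhage_count",
                       "hemorrhage_max_area_px", "exudate_total_area_px",
                       "exudate_count", "exudate_max_area_px")

#' Quantify a lesion set
#'
#' Computes the six per-image indices from a detected (or ground-truth)
#' [lesion_set()]. The hemorrhage family pools microaneurysm and hemorrhage
#' regions (microaneurysms can be excluded via
#' `cfg$quantify$include_microaneurysms`); the exudate family pools exudate
#' and cotton-wool regions. Counting is per connected detected region.
#'
#' @param lesions A `lesion_set`.
#' @param image_id Identifier carried into the report.
#' @param cfg Configuration list.
#' @return A [quant_report()].
#' @export
quantify_lesions <- function(lesions, image_id = "", cfg = dr_config()) {
  stopifnot(inherits(lesions, "lesion_set"))
  hem_classes <- if (isTRUE(cfg$quantify$include_microaneurysms))
    c("microaneurysm", "hemorrhage") else "hemorrhage"
  exu_classes <- c("exudate", "cottonwool")
  fam <- function(classes) {
    areas <- vapply(lesions$regions, function(r)
      if (r$class %in% classes) r$area_px else NA_integer_, integer(1))
    areas <- areas[!is.na(areas)]
    list(total = sum(areas), count = length(areas),
         max = if (length(areas)) max(areas) else 0L)
  }
  h <- fam(hem_classes); e <- fam(exu_classes)
  quant_report(image_id, h$total, h$count, h$max, e$total, e$count, e$max)
}

#' Group summary of quantification indices
#'
#' Per-group sample size, mean and sample standard deviation (n-1
#' denominator) of each of the six indices, in the layout used to compare
#' lesion burden across DR severity groups.
#'
#' @param reports List of [quant_report()] objects.
#' @param assignment Named character vector or list mapping `image_id` to a
#'   group label, or a character vector parallel to `reports`.
#' @return A data frame with one row per (group, index): columns `group`,
#'   `index`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(reports, assignment) {
  if (length(reports) == 0) contract_error("no reports to summarise")
  ids <- vapply(reports, function(r) r$image_id, character(1))
  groups <- if (!is.null(names(assignment))) {
    missing <- setdiff(ids, names(assignment))
    if (length(missing))
      contract_error(paste0("unassigned image(s): ", paste(missing, collapse = ", ")))
    as.character(unlist(assignment)[ids])
  } else {
    if (length(assignment) != length(reports))
      contract_error("assignment length must match reports")
    as.character(assignment)
  }
  mat <- t(vapply(reports, function(r) unlist(r[quant_index_names]),
                  numeric(length(quant_index_names))))
  colnames(mat) <- quant_index_names
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    rows <- mat[groups == g, , drop = FALSE]
    if (nrow(rows) < 2)
      contract_error(paste0("group '", g, "' has n < 2"))
    do.call(rbind, lapply(quant_index_names, function(idx) {
      data.frame(group = g, index = idx, n = nrow(rows),
                 mean = mean(rows[, idx]), sd = sd(rows[, idx]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
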