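# Published summary tables from a community non-mydriatic DR screening
# program, shipped as plain CSVs. They are the reference inputs for the
# statistics modules: the per-group lesion-quantification summaries feed
# the summary-statistics ANOVA and LSD comparisons, and the
# clinician-vs-system outcome table feeds the cohort arithmetic.

#' Published lesion-quantification group summaries
#'
#' Per-group (n, mean, SD) of the six lesion-quantification indices across
#' three DR severity groups (group 1 mild+moderate NPDR, group 2 severe
#' NPDR, group 3 PDR), as published by a DR screening study. Areas are in
#' pixels, counts in lesions per image.
#'
#' @return Data frame: `index`, `group`, `n`, `mean`, `sd`.
#' @export
published_group_summaries <- function() {
  read.csv(system.file("extdata", "dr_lesion_group_summaries.csv",
                       package = "fundusdr"), stringsAsFactors = FALSE)
}

#' Published clinician-vs-system screening outcome table
#'
#' Image counts by clinician reference category (rows) and automated-system
#' output category (columns) from a community DR screening program of
#' 19,904 fundus photographs.
#'
#' @return Integer matrix with reference categories as row names.
#' @export
published_screening_table <- function() {
  df <- read.csv(system.file("extdata", "dr_screening_outcomes.csv",
                             package = "fundusdr"),
                 stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$reference
  storage.mode(m) <- "integer"
  m
}
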