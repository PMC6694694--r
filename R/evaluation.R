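# Screening-evaluation statistics: confusion matrices, binary screening
# metrics, Cohen's kappa with qualitative bands, ROC/AUC, one-way ANOVA from
# group summary statistics, and Fisher-LSD pairwise comparisons with the
# pooled ANOVA error term.

#' Build a confusion matrix from (reference, test) label pairs
#'
#' Rows are the reference (clinician) labels, columns the test (automated
#' system) labels, in the supplied order.
#'
#' @param reference,test Parallel label vectors.
#' @param labels Ordered label vocabulary covering both vectors.
#' @return A `confusion_matrix`: integer matrix with `labels` as dimnames.
#' @export
confusion_matrix <- function(reference, test, labels = NULL) {
  if (length(reference) != length(test))
    contract_error("reference and test must have equal length")
  if (length(reference) == 0) contract_error("no label pairs")
  if (is.null(labels)) labels <- sort(unique(c(reference, test)))
  bad <- setdiff(unique(c(reference, test)), labels)
  if (length(bad))
    contract_error(paste0("label(s) outside the vocabulary: ",
                          paste(bad, collapse = ", ")))
  m <- table(factor(reference, levels = labels), factor(test, levels = labels))
  m <- matrix(as.integer(m), length(labels), length(labels),
              dimnames = list(reference = labels, test = labels))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Coerce a count table to a confusion matrix
#'
#' @param counts Square numeric matrix (rows = reference, cols = test) with
#'   dimnames.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || is.null(rownames(counts)))
    contract_error("counts must be a square labelled matrix")
  if (any(counts < 0) || sum(counts) == 0)
    contract_error("counts must be non-negative with positive total")
  m <- matrix(as.integer(round(counts)), nrow(counts), ncol(counts),
              dimnames = list(reference = rownames(counts), test = colnames(counts)))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Binary screening metrics from a confusion matrix
#'
#' Collapses the matrix to disease-positive vs disease-negative by the given
#' positive reference/test label set, then computes: sensitivity (proportion
#' of diseased correctly diagnosed), specificity (proportion of non-diseased
#' correctly diagnosed), missed-diagnosis rate (1 - sensitivity),
#' misdiagnosis rate (1 - specificity), accuracy, and the positive and
#' negative predictive values.
#'
#' @param cm A [confusion_matrix()].
#' @param positive_labels Labels counted as disease-positive (applied to both
#'   axes).
#' @return A `screening_metrics` list.
#' @export
screening_metrics <- function(cm, positive_labels) {
  stopifnot(inherits(cm, "confusion_matrix"))
  labs <- rownames(cm)
  pos <- labs %in% positive_labels
  if (!any(pos)) contract_error("no positive labels present in the matrix")
  tp <- sum(cm[pos, pos, drop = FALSE]); fn <- sum(cm[pos, !pos, drop = FALSE])
  fp <- sum(cm[!pos, pos, drop = FALSE]); tn <- sum(cm[!pos, !pos, drop = FALSE])
  if (tp + fn == 0) fdr_error("sensitivity undefined: no positive reference cases",
                              "fdr_undefined_metric")
  if (fp + tn == 0) fdr_error("specificity undefined: no negative reference cases",
                              "fdr_undefined_metric")
  sens <- tp / (tp + fn); spec <- tn / (fp + tn)
  structure(list(
    sensitivity = sens, specificity = spec,
    missed_rate = 1 - sens, misdiagnosis_rate = 1 - spec,
    accuracy = (tp + tn) / (tp + fn + fp + tn),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    tp = tp, fn = fn, fp = fp, tn = tn
  ), class = "screening_metrics")
}

#' Cohen's kappa with qualitative agreement band
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` where chance agreement `p_e`
#' comes from the row/column margins, banded as: < 0.2 poor, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 good, > 0.81 excellent.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `kappa` and `band`.
#' @export
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- sum(cm)
  if (n == 0) contract_error("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 8)
    fdr_error("kappa undefined: degenerate margins give chance agreement 1",
              "fdr_undefined_metric")
  k <- (po - pe) / (1 - pe)
  band <- if (k <= 0.2) "poor" else if (k <= 0.40) "fair" else
    if (k <= 0.60) "moderate" else if (k <= 0.80) "good" else "excellent"
  list(kappa = k, band = band)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique scores (predicting positive when
#' `score >= t`), producing (1 - specificity, sensitivity) points from
#' (0, 0) to (1, 1); the AUC is the trapezoid area, which equals the
#' pairwise concordance statistic.
#'
#' @param scores Numeric scores, larger meaning more disease-like.
#' @param labels Binary labels (logical, or 0/1) parallel to `scores`.
#' @return A `roc_curve` list: `points` (data frame `fpr`, `tpr`), `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || length(scores) == 0)
    contract_error("scores and labels must be non-empty and parallel")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) contract_error("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels) / np, numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & !labels) / nn, numeric(1)))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the one-way ANOVA table from per-group (n, mean, sd)
#' triples: between-group sum of squares about the weighted grand mean,
#' within-group sum of squares `sum((n_i - 1) sd_i^2)`, the F ratio and its
#' upper-tail p-value. Identical to a raw-data ANOVA on any dataset with
#' those exact summaries.
#'
#' @param groups Data frame with columns `n`, `mean`, `sd` (one row per
#'   group), or a list of `c(n, mean, sd)` triples.
#' @return An `anova_result` list: `k`, `df_between`, `df_within`,
#'   `ms_between`, `ms_within`, `F`, `p`.
#' @export
anova_oneway_summary <- function(groups) {
  g <- normalize_groups(groups)
  k <- nrow(g)
  if (k < 2) contract_error("need at least two groups")
  if (any(g$n < 2)) contract_error("each group needs n >= 2")
  if (any(g$sd < 0)) contract_error("sd must be non-negative")
  N <- sum(g$n)
  grand <- sum(g$n * g$mean) / N
  ssb <- sum(g$n * (g$mean - grand)^2)
  ssw <- sum((g$n - 1) * g$sd^2)
  dfb <- as.integer(k - 1); dfw <- as.integer(N - k)
  msb <- ssb / dfb; msw <- ssw / dfw
  if (msw == 0) {
    return(structure(list(k = k, df_between = dfb, df_within = dfw,
                          ms_between = msb, ms_within = 0,
                          F = if (msb > 0) Inf else 0,
                          p = if (msb > 0) 0 else 1, infinite_f = msb > 0),
                     class = "anova_result"))
  }
  f <- msb / msw
  structure(list(k = k, df_between = dfb, df_within = dfw,
                 ms_between = msb, ms_within = msw, F = f,
                 p = pf(f, dfb, dfw, lower.tail = FALSE), infinite_f = FALSE),
            class = "anova_result")
}

normalize_groups <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("n", "mean", "sd") %in% names(groups)))
      contract_error("groups need columns n, mean, sd")
    return(groups[, c("n", "mean", "sd")])
  }
  do.call(rbind, lapply(groups, function(x)
    data.frame(n = x[[1]], mean = x[[2]], sd = x[[3]])))
}

#' Fisher-LSD pairwise comparisons from an ANOVA
#'
#' Unadjusted pairwise t comparisons using the pooled within-group error:
#' for groups i, j the mean difference is `mean_i - mean_j`, its standard
#' error `sqrt(MS_within (1/n_i + 1/n_j))`, the p-value two-sided from the t
#' distribution on the within df, and the 95% CI
#' `difference +/- t[0.975, df] SE`. All ordered pairs are returned, so
#' swapping a pair negates the difference and mirrors the interval.
#'
#' @param anova An [anova_oneway_summary()] result on the same groups.
#' @param groups The same group summaries (data frame `n`, `mean`, `sd`,
#'   optional `group` labels).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param method `"lsd"` (default) or `"bonferroni"` (p and CI adjusted by
#'   the number of unordered pairs).
#' @return Data frame: `group_i`, `group_j`, `mean_difference`,
#'   `standard_error`, `p`, `ci_lower`, `ci_upper`.
#' @export
lsd_pairwise <- function(anova, groups, conf_level = 0.95,
                         method = c("lsd", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(inherits(anova, "anova_result"))
  g <- normalize_groups(groups)
  labels <- if (is.data.frame(groups) && "group" %in% names(groups))
    as.character(groups$group) else paste0("group", seq_len(nrow(g)))
  if (nrow(g) != anova$k || sum(g$n) - anova$k != anova$df_within)
    contract_error("group summaries do not match the ANOVA")
  m <- choose(anova$k, 2)
  adj <- if (method == "bonferroni") m else 1
  alpha <- (1 - conf_level) / adj
  tc <- qt(1 - alpha / 2, anova$df_within)
  out <- list()
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
    if (i == j) next
    d <- g$mean[i] - g$mean[j]
    se <- sqrt(anova$ms_within * (1 / g$n[i] + 1 / g$n[j]))
    p <- if (se == 0) as.numeric(d == 0) else
      min(1, adj * 2 * pt(abs(d) / se, anova$df_within, lower.tail = FALSE))
    out[[length(out) + 1L]] <- data.frame(
      group_i = labels[i], group_j = labels[j],
      mean_difference = d, standard_error = se, p = p,
      ci_lower = d - tc * se, ci_upper = d + tc * se,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Cohort arithmetic from a reference-by-test count table
#'
#' From a screening count table whose rows are the clinician reference
#' categories, computes the total image count, the number and percentage
#' disqualified for reading, and the DR prevalence among qualified images
#' (reference rows in `dr_labels` over the qualified total). Percentages are
#' also returned rounded to one decimal for display.
#'
#' @param counts Reference-by-test count matrix (or `confusion_matrix`) with
#'   row names.
#' @param dr_labels Reference labels counted as DR disease.
#' @param disqualified_label Reference label of disqualified images.
#' @return List: `n_total`, `n_qualified`, `n_disqualified`,
#'   `disqualified_pct`, `prevalence_qualified`, `prevalence_pct`.
#' @export
cohort_summary <- function(counts, dr_labels,
                           disqualified_label = "Disqualification") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) contract_error("counts must have row names")
  missing <- setdiff(c(dr_labels, disqualified_label), rownames(counts))
  if (length(missing))
    contract_error(paste0("label(s) absent from the table: ",
                          paste(missing, collapse = ", ")))
  row_totals <- rowSums(counts)
  n_total <- sum(row_totals)
  n_disq <- sum(row_totals[disqualified_label])
  n_qual <- n_total - n_disq
  if (n_qual == 0)
    fdr_error("prevalence undefined: no qualified images", "fdr_undefined_metric")
  n_dr <- sum(row_totals[dr_labels])
  list(n_total = n_total, n_qualified = n_qual, n_disqualified = n_disq,
       disqualified_pct = round(100 * n_disq / n_total, 1),
       prevalence_qualified = n_dr / n_qual,
       prevalence_pct = round(100 * n_dr / n_qual, 1))
}

#' Format a p-value the way screening tables print it
#'
#' @param p Numeric p-value.
#' @param digits Decimal places.
#' @return `"< 0.001"` below 0.001, otherwise the rounded value as character.
#' @export
format_p <- function(p, digits = 3) {
  ifelse(p < 0.001, "< 0.001", formatC(round(p, digits), format = "f", digits = digits))
}
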