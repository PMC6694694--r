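test_that("confusion matrices count pairs exactly", {
  cm <- confusion_matrix(rep("a", 10), rep("a", 10), c("a", "b"))
  expect_identical(sum(diag(cm)), 10L)
  expect_identical(sum(cm) - sum(diag(cm)), 0L)

  set.seed(11)
  labs <- c("x", "y", "z")
  ref <- sample(labs, 300, TRUE); tst <- sample(labs, 300, TRUE)
  cm2 <- confusion_matrix(ref, tst, labs)
  expect_identical(sum(cm2), 300L)
  # brute-force nested counting oracle
  for (i in labs) for (j in labs)
    expect_identical(cm2[i, j], sum(ref == i & tst == j))

  expect_error(confusion_matrix("q", "x", labs), class = "fdr_contract_error")
})

test_that("screening metrics implement the stated definitions", {
  cm <- as_confusion_matrix(matrix(c(50, 10, 5, 35), 2, 2,
                                   dimnames = list(c("dr", "no"), c("dr", "no"))))
  m <- screening_metrics(cm, "dr")
  expect_equal(m$sensitivity, 50 / 55)
  expect_equal(m$specificity, 35 / 45)
  expect_equal(m$missed_rate, 1 - m$sensitivity)
  expect_equal(m$misdiagnosis_rate, 1 - m$specificity)
  expect_equal(m$accuracy, 85 / 100)
  expect_equal(m$ppv, 50 / 60)
  expect_equal(m$npv, 35 / 40)

  perfect <- confusion_matrix(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  mp <- screening_metrics(perfect, "a")
  expect_equal(mp$sensitivity, 1)
  expect_equal(mp$specificity, 1)

  oneclass <- confusion_matrix(rep("a", 4), rep("a", 4), c("a", "b"))
  expect_error(screening_metrics(oneclass, "a"), class = "fdr_undefined_metric")
})

test_that("the published screening table reproduces its printed margins", {
  tab <- published_screening_table()
  expect_identical(sum(tab), 19904L)
  # No-DR row: 5377 of 9266 called DR0 (58.0%)
  expect_identical(tab["No DR", "DR0"], 5377L)
  expect_equal(round(100 * tab["No DR", "DR0"] / sum(tab["No DR", ]), 1), 58.0)
})

test_that("Cohen's kappa matches brute force and bands correctly", {
  id <- confusion_matrix(rep(c("a", "b", "c"), 4), rep(c("a", "b", "c"), 4))
  k <- cohen_kappa(id)
  expect_equal(k$kappa, 1)
  expect_identical(k$band, "excellent")

  # counts equal to the outer product of the margins -> kappa 0
  cnt <- outer(c(40, 60), c(50, 50)) / 100
  cm0 <- as_confusion_matrix(matrix(cnt, 2, 2,
                                    dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(cohen_kappa(cm0)$kappa, 0, tolerance = 1e-12)

  # brute force on random tables; kappa stays in [-1, 1]
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:5, 1)
    counts <- matrix(rpois(n * n, 8), n, n,
                     dimnames = list(letters[1:n], letters[1:n]))
    counts[1, 1] <- counts[1, 1] + 1
    cm <- as_confusion_matrix(counts)
    N <- sum(cm)
    po <- sum(diag(cm)) / N
    pe <- 0
    for (j in 1:n) pe <- pe + sum(cm[j, ]) * sum(cm[, j]) / N^2
    k <- cohen_kappa(cm)$kappa
    expect_equal(k, (po - pe) / (1 - pe))
    expect_gte(k, -1); expect_lte(k, 1)
    if (sum(cm) - sum(diag(cm)) > 0) expect_lt(k, 1)
  }

  # band cut points as published: 0.58 is "moderate"
  cm58 <- as_confusion_matrix(matrix(c(55, 20, 20, 55), 2, 2,
                                     dimnames = list(c("a", "b"), c("a", "b"))))
  kk <- cohen_kappa(cm58)
  expect_gt(kk$kappa, 0.41); expect_lt(kk$kappa, 0.60)
  expect_identical(kk$band, "moderate")
})

test_that("trapezoid AUC equals the pairwise concordance oracle", {
  set.seed(5)
  scores <- c(rnorm(30, 2) + 100, rnorm(30))   # perfectly separated
  labels <- rep(c(TRUE, FALSE), each = 30)
  expect_equal(roc_auc(scores, labels)$auc, 1, tolerance = 1e-12)
  # tie handling: pos {1, 2} vs neg {1, 3} -> concordance 0.375
  expect_equal(roc_auc(c(1, 1, 2, 3), c(TRUE, FALSE, TRUE, FALSE))$auc, 0.375)

  conc <- function(s, l) {
    pos <- s[l]; neg <- s[!l]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  for (i in 1:5) {
    n <- sample(20:200, 1)
    s <- round(rnorm(n), sample(0:2, 1))   # ties included
    l <- runif(n) < 0.4
    if (!any(l) || all(l)) next
    expect_equal(roc_auc(s, l)$auc, conc(s, l), tolerance = 1e-9)
  }

  # label-independent scores hover at 0.5
  set.seed(99)
  s <- rnorm(2000); l <- runif(2000) < 0.5
  expect_gt(roc_auc(s, l)$auc, 0.45)
  expect_lt(roc_auc(s, l)$auc, 0.55)

  # curve runs monotonically from (0,0) to (1,1)
  rc <- roc_auc(rnorm(50), runif(50) < 0.5)
  expect_true(all(diff(rc$points$fpr) >= 0))
  expect_true(all(diff(rc$points$tpr) >= 0))
  expect_equal(unlist(rc$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rc$points[nrow(rc$points), ]), c(fpr = 1, tpr = 1))

  expect_error(roc_auc(1:4, rep(TRUE, 4)), class = "fdr_contract_error")
})

test_that("summary-statistics ANOVA reproduces the published F statistics", {
  pub <- published_group_summaries()
  printed_f <- c(hemorrhage_total_area_px = 16.034, hemorrhage_count = 37.100,
                 hemorrhage_max_area_px = 17.146, exudate_total_area_px = 10.553,
                 exudate_count = 5.552, exudate_max_area_px = 15.256)
  for (idx in names(printed_f)) {
    a <- anova_oneway_summary(pub[pub$index == idx, ])
    expect_lt(abs(a$F - printed_f[[idx]]), 0.05)
    expect_identical(a$df_between, 2L)
    expect_identical(a$df_within, 88L)
  }
})

test_that("summary ANOVA equals raw-data ANOVA and respects invariants", {
  set.seed(31)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    ns <- sample(3:12, k, TRUE)
    raw <- lapply(ns, function(n) rnorm(n, sample(0:5, 1), runif(1, 0.5, 3)))
    g <- data.frame(n = ns, mean = vapply(raw, mean, 0),
                    sd = vapply(raw, sd, 0))
    a <- anova_oneway_summary(g)
    df <- data.frame(y = unlist(raw),
                     grp = factor(rep(seq_len(k), ns)))
    ref <- anova(stats::lm(y ~ grp, df))
    expect_equal(a$F, ref$`F value`[1], tolerance = 1e-8)
    expect_equal(a$p, ref$`Pr(>F)`[1], tolerance = 1e-8)
    # affine invariance of F
    g2 <- transform(g, mean = 3.7 * mean - 11, sd = 3.7 * sd)
    expect_equal(anova_oneway_summary(g2)$F, a$F, tolerance = 1e-8)
  }
  eq <- data.frame(n = c(5, 5), mean = c(2, 2), sd = c(1, 2))
  expect_equal(anova_oneway_summary(eq)$F, 0)
  degen <- data.frame(n = c(5, 5), mean = c(1, 2), sd = c(0, 0))
  expect_true(is.infinite(anova_oneway_summary(degen)$F))
})

test_that("LSD comparisons reproduce the published pairwise table", {
  pub <- published_group_summaries()
  g <- pub[pub$index == "hemorrhage_total_area_px", ]
  a <- anova_oneway_summary(g)
  cmp <- lsd_pairwise(a, g)
  row <- cmp[cmp$group_i == "group1" & cmp$group_j == "group2", ]
  expect_lt(abs(row$mean_difference - (-14297.535)) / 14297.535, 0.001)
  expect_lt(abs(row$standard_error - 3042.766) / 3042.766, 0.001)
  expect_lt(abs(row$ci_lower - (-20344.39)) / 20344.39, 0.001)
  expect_lt(abs(row$ci_upper - (-8250.68)) / 8250.68, 0.001)
  expect_lt(row$p, 0.001)

  # antisymmetry: swapped pair negates the difference and mirrors the CI
  rev <- cmp[cmp$group_i == "group2" & cmp$group_j == "group1", ]
  expect_equal(rev$mean_difference, -row$mean_difference)
  expect_equal(rev$ci_lower, -row$ci_upper)
  expect_equal(rev$ci_upper, -row$ci_lower)
  expect_equal(rev$p, row$p)
  expect_true(all(cmp$ci_lower <= cmp$mean_difference &
                    cmp$mean_difference <= cmp$ci_upper))
})

test_that("cohort arithmetic reproduces the published rates", {
  tab <- published_screening_table()
  dr_labels <- c("Mild NPDR", "Moderate NPDR", "Severe NPDR", "PDR", "PRP")
  cs <- cohort_summary(tab, dr_labels, "Disqualification")
  expect_identical(cs$n_total, 19904)
  expect_identical(cs$n_qualified, 11535)
  expect_equal(cs$disqualified_pct, 42.0)
  expect_equal(cs$prevalence_pct, 17.3)

  only_dq <- matrix(5, 1, 1, dimnames = list("Disqualification", "DR0"))
  expect_error(cohort_summary(only_dq, character(), "Disqualification"),
               class = "fdr_undefined_metric")

  # brute-force prevalence oracle on random tables
  set.seed(77)
  for (i in 1:20) {
    labs <- c("a", "b", "dq")
    ref <- sample(labs, 200, TRUE)
    tst <- sample(labs, 200, TRUE)
    cm <- confusion_matrix(ref, tst, labs)
    if (sum(ref != "dq") == 0) next
    cs2 <- cohort_summary(cm, "a", "dq")
    expect_equal(cs2$prevalence_qualified,
                 sum(ref == "a") / sum(ref != "dq"))
  }
})

test_that("p-values format the way screening tables print them", {
  expect_identical(format_p(0.0004), "< 0.001")
  expect_identical(format_p(0.717), "0.717")
})
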