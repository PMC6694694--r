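test_that("quantification follows its definitions", {
  d <- c(512L, 512L)
  idx1 <- which(fundusdr:::disc_raster(512, 512, c(100, 100), 20))[1:100]
  idx2 <- which(fundusdr:::disc_raster(512, 512, c(300, 300), 20))[1:250]
  ls <- lesion_set(list(lesion_region(1, "hemorrhage", idx1, d),
                        lesion_region(2, "hemorrhage", idx2, d)), d)
  q <- quantify_lesions(ls)
  expect_identical(q$hemorrhage_total_area_px, 350L)
  expect_identical(q$hemorrhage_count, 2L)
  expect_identical(q$hemorrhage_max_area_px, 250L)
  expect_identical(q$exudate_total_area_px, 0L)

  q0 <- quantify_lesions(lesion_set(list(), d))
  expect_true(all(unlist(q0[fundusdr:::quant_index_names]) == 0))

  # totals equal independent pixel counts of the per-class rasters
  pool <- grid_lesion_pool()
  ls2 <- lesion_set(pool, d)
  q2 <- quantify_lesions(ls2)
  expect_identical(q2$hemorrhage_total_area_px,
                   sum(ls2$rasters$hemorrhage) + sum(ls2$rasters$microaneurysm))
  expect_identical(q2$exudate_total_area_px,
                   sum(ls2$rasters$exudate) + sum(ls2$rasters$cottonwool))

  # microaneurysm exclusion switch
  cfg_noma <- dr_config(overrides = list(quantify =
                                           list(include_microaneurysms = FALSE)))
  q3 <- quantify_lesions(ls2, cfg = cfg_noma)
  expect_identical(q3$hemorrhage_total_area_px, sum(ls2$rasters$hemorrhage))

  expect_error(quant_report("x", 10, 2, 20, 0, 0, 0),
               class = "fdr_contract_error")  # max > total
  expect_error(quant_report("x", 10, 0, 0, 0, 0, 0),
               class = "fdr_contract_error")  # count/total inconsistent
})

test_that("quantification is invariant under translation and rotation", {
  d <- c(512L, 512L)
  pool <- grid_lesion_pool(n_ma = 3, n_hem = 5, n_ex = 2)
  ls <- lesion_set(pool, d)
  q <- quantify_lesions(ls)
  shift <- function(idx) {
    rr <- ((idx - 1L) %% 512L) + 1L + 7L; cc <- ((idx - 1L) %/% 512L) + 1L + 5L
    (cc - 1L) * 512L + rr
  }
  rot <- function(idx) {  # 90-degree rotation of the frame
    rr <- ((idx - 1L) %% 512L) + 1L; cc <- ((idx - 1L) %/% 512L) + 1L
    (rr - 1L) * 512L + (512L - cc + 1L)
  }
  for (f in list(shift, rot)) {
    moved <- lapply(ls$regions, function(r)
      lesion_region(r$region_id, r$class, f(r$pixels), d))
    expect_identical(unclass(quantify_lesions(lesion_set(moved, d)))[-1],
                     unclass(q)[-1])
  }
})

test_that("group summaries match a streaming oracle and ignore order", {
  set.seed(7)
  reports <- lapply(1:12, function(i)
    quant_report(paste0("img", i), sample(0:500, 1) + 1, sample(1:5, 1), 1,
                 0, 0, 0))
  # fix max <= total, count coherence
  reports <- lapply(reports, function(r) {
    quant_report(r$image_id, r$hemorrhage_total_area_px, r$hemorrhage_count,
                 min(r$hemorrhage_total_area_px, 1 + r$hemorrhage_total_area_px %/% 2),
                 0, 0, 0)
  })
  groups <- rep(c("g1", "g2", "g3"), each = 4)
  names(groups) <- vapply(reports, function(r) r$image_id, character(1))
  s <- summarize_groups(reports, groups)

  # Welford streaming oracle for one cell
  vals <- vapply(reports[1:4], function(r) r$hemorrhage_total_area_px,
                 numeric(1))
  mean_w <- 0; m2 <- 0
  for (k in seq_along(vals)) {
    delta <- vals[k] - mean_w
    mean_w <- mean_w + delta / k
    m2 <- m2 + delta * (vals[k] - mean_w)
  }
  row <- s[s$group == "g1" & s$index == "hemorrhage_total_area_px", ]
  expect_equal(row$mean, mean_w)
  expect_equal(row$sd, sqrt(m2 / (length(vals) - 1)))

  perm <- sample(length(reports))
  s2 <- summarize_groups(reports[perm], groups)
  expect_equal(s, s2)

  # identical reports -> SD 0
  same <- lapply(1:3, function(i) quant_report(paste0("s", i), 10, 1, 10, 0, 0, 0))
  s3 <- summarize_groups(same, setNames(rep("g", 3), paste0("s", 1:3)))
  expect_true(all(s3$sd == 0))

  expect_error(summarize_groups(reports[1:3], setNames(c("a", "a", "b"),
                                                       names(groups)[1:3])),
               class = "fdr_contract_error")  # group with n < 2
})

test_that("per-quadrant hemorrhage counts conserve the total", {
  quad <- full_quadrants()
  pool <- grid_lesion_pool(n_ma = 0, n_hem = 25, n_ex = 0)
  ls <- lesion_set(pool, c(512L, 512L))
  res <- grade_dr(ls, quad, qualified_quality(), cfg = fix_cfg())
  expect_identical(sum(res$evidence$hemorrhages_per_quadrant),
                   res$evidence$n_hemorrhage)
})
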