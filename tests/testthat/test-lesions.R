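test_that("a single small microaneurysm is found at its planted centroid", {
  sc <- fix_scene(55, list(microaneurysm = list(count = 1, area = c(9, 9))))
  pre <- fix_pre(55, list(microaneurysm = list(count = 1, area = c(9, 9))))
  red <- detect_red_lesions(pre$normalized, pre$vessels, pre$disc, pre$roi,
                            fix_model(), fix_cfg())
  expect_length(red$regions, 1L)
  expect_identical(red$regions[[1]]$class, "microaneurysm")
  tr <- sc$truth$regions[1, ]
  err <- sqrt(sum((red$regions[[1]]$centroid -
                     c(tr$centroid_row, tr$centroid_col))^2))
  expect_lt(err, 2)
})

test_that("lesion-free scenes produce no red lesions", {
  for (s in c(2001, 2011)) {
    pre <- fix_pre(s)
    red <- detect_red_lesions(pre$normalized, pre$vessels, pre$disc, pre$roi,
                              fix_model(), fix_cfg())
    expect_length(red$regions, 0L)
  }
})

test_that("a hemorrhage painted onto a vessel is suppressed", {
  sc <- fix_scene(2001)
  px <- sc$image$pixels
  # centre a dark-red blob on a true vessel pixel well away from the disc
  vidx <- which(sc$truth$masks$vessel &
                  fundusdr:::disc_raster(512, 512, c(256, 160), 60))
  stopifnot(length(vidx) > 0)
  ctr <- c(((vidx[1] - 1) %% 512) + 1, ((vidx[1] - 1) %/% 512) + 1)
  blob <- fundusdr:::disc_raster(512, 512, ctr, 6)
  for (ch in 1:3) { p <- px[, , ch]; p[blob] <- c(98, 32, 24)[ch]; px[, , ch] <- p }
  img <- fundus_image(px, "on_vessel")
  roi <- establish_roi(img, fix_cfg())
  nrm <- normalize_image(denoise(img, 1), roi, standard_profile(fix_cfg()))
  vm <- segment_vessels(nrm, roi, cfg = fix_cfg())
  disc <- locate_optic_disc(nrm, vm, roi, fix_cfg())
  red <- detect_red_lesions(nrm, vm, disc, roi, fix_model(), fix_cfg())
  # no accepted region may sit mostly on the planted blob
  on_blob <- vapply(red$regions, function(r) mean(blob[r$pixels]) > 0.5,
                    logical(1))
  expect_false(any(on_blob))
})

test_that("no lesion pixel lies inside the disc or outside the ROI", {
  pre <- fix_pre(2003, list(microaneurysm = list(count = 2),
                            hemorrhage = list(count = 4, area = c(80, 300)),
                            exudate = list(count = 3)))
  red <- detect_red_lesions(pre$normalized, pre$vessels, pre$disc, pre$roi,
                            fix_model(), fix_cfg())
  brt <- detect_bright_lesions(pre$normalized, pre$disc, pre$roi, fix_cfg())
  disc_m <- fundusdr:::disc_raster(512, 512, pre$disc$center, pre$disc$radius_px)
  for (r in c(red$regions, brt$regions)) {
    expect_true(all(pre$roi$mask[r$pixels]))
    expect_false(any(disc_m[r$pixels]))
    # red regions respect the vessel-overlap bound
    if (r$class %in% c("microaneurysm", "hemorrhage"))
      expect_lt(mean(pre$vessels$mask[r$pixels]), 0.20)
  }
})

test_that("bright lesions are recovered with accurate area and classes", {
  lesions <- list(exudate = list(count = 4, area = c(60, 250)),
                  cottonwool = list(count = 1))
  sc <- fix_scene(302, lesions)
  pre <- fix_pre(302, lesions)
  brt <- detect_bright_lesions(pre$normalized, pre$disc, pre$roi, fix_cfg())
  tq <- quantify_truth(sc$truth)
  dq <- quantify_lesions(brt, cfg = fix_cfg())
  expect_lt(abs(dq$exudate_total_area_px - tq$exudate_total_area_px) /
              tq$exudate_total_area_px, 0.20)
  cls <- vapply(brt$regions, function(r) r$class, character(1))
  expect_identical(sum(cls == "exudate"), 4L)   # sharp yellow blobs
  expect_identical(sum(cls == "cottonwool"), 1L) # fuzzy pale blob
  # the disc is never reported as an exudate
  disc_m <- fundusdr:::disc_raster(512, 512, sc$truth$disc_center,
                                   sc$truth$disc_radius)
  for (r in brt$regions) expect_lt(mean(disc_m[r$pixels]), 0.01)
})

test_that("photocoagulation scar patterns are recognised", {
  lesions <- list(prp_scar = list(count = 48, area = c(50, 120)))
  pre <- fix_pre(410, lesions)
  prp <- detect_prp_scars(pre$normalized, pre$roi, pre$disc, fix_cfg())
  expect_gte(length(prp$regions), 0.8 * 48)
  expect_true(attr(prp, "prp_positive"))

  pre3 <- fix_pre(411, list(prp_scar = list(count = 3)))
  prp3 <- detect_prp_scars(pre3$normalized, pre3$roi, pre3$disc, fix_cfg())
  expect_false(attr(prp3, "prp_positive"))

  pre0 <- fix_pre(2001)
  prp0 <- detect_prp_scars(pre0$normalized, pre0$roi, pre0$disc, fix_cfg())
  expect_length(prp0$regions, 0L)
})

test_that("the margin classifier trains deterministically and separates", {
  toy <- data.frame(x = c(rnorm(20, -3), rnorm(20, 3)),
                    y = c(rnorm(20, -3), rnorm(20, 3)),
                    label = rep(c("a", "b"), each = 20))
  m1 <- train_candidate_classifier(toy, seed = 11)
  expect_identical(predict_classifier(m1, toy), toy$label)  # separable: 100%

  m2 <- train_candidate_classifier(toy, seed = 11)
  probe <- data.frame(x = rnorm(50), y = rnorm(50))
  expect_identical(predict_classifier(m1, probe), predict_classifier(m2, probe))

  expect_error(train_candidate_classifier(data.frame(x = 1:5, label = "a"),
                                          seed = 1), class = "fdr_contract_error")

  # JSON persistence round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m1, path)
  m3 <- read_model(path)
  expect_identical(predict_classifier(m3, probe), predict_classifier(m1, probe))
})

test_that("the default model generalises to held-out synthetic candidates", {
  corpus <- fundusdr:::red_candidate_corpus(31337L, n_scenes = 2L,
                                            cfg = fix_cfg())
  pred <- predict_classifier(fix_model(),
                             corpus[, fundusdr:::red_feature_cols])
  expect_gte(mean(pred == corpus$label), 0.85)
})

test_that("detection is deterministic and monotone in lesion contrast", {
  pre <- fix_pre(302, list(exudate = list(count = 4, area = c(60, 250)),
                           cottonwool = list(count = 1)))
  r1 <- detect_bright_lesions(pre$normalized, pre$disc, pre$roi, fix_cfg())
  r2 <- detect_bright_lesions(pre$normalized, pre$disc, pre$roi, fix_cfg())
  expect_identical(quantify_lesions(r1), quantify_lesions(r2))

  # one hemorrhage at increasing contrast: once visible, never lost
  detected <- vapply(c(0.6, 0.8, 1.0), function(ct) {
    sc <- render_scene(scene_spec(
      seed = 808, lesions = list(hemorrhage = list(count = 1, area = c(200, 200),
                                                   contrast = c(ct, ct)))))
    pre <- fundusdr:::preprocess_scene(sc$image, fix_cfg())
    red <- detect_red_lesions(pre$normalized, pre$vessels, pre$disc, pre$roi,
                              fix_model(), fix_cfg())
    length(red$regions) > 0
  }, logical(1))
  expect_true(all(diff(detected) >= 0))
  expect_true(detected[3])
})
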