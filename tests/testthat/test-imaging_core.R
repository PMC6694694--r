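test_that("image containers enforce their contracts", {
  expect_error(fundus_image(array(0, c(64, 64, 3))), class = "fdr_size_error")
  expect_error(fundus_image(array(300, c(128, 128, 3))),
               class = "fdr_contract_error")
  img <- flat_image()
  expect_identical(dim(img), c(160L, 160L, 3L))
  rm <- roi_mask(matrix(c(TRUE, FALSE), 160, 160))
  expect_equal(rm$area_px, sum(rm$mask))
})

test_that("PNG write/read round trips are lossless and size is validated", {
  sc <- fix_scene(5)
  path <- withr::local_tempfile(fileext = ".png")
  write_image(sc$image, path)
  back <- read_image(path)
  expect_identical(back$pixels, sc$image$pixels)
  expect_equal(dim(back$pixels)[1:2], c(512L, 512L))

  small <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(array(0.5, c(64, 64, 3)),
                                     colormode = "Color"), small)
  expect_error(read_image(small), class = "fdr_size_error")
  expect_error(read_image("does/not/exist.png"), class = "fdr_io_error")
})

test_that("grayscale input is replicated to three channels with a warning", {
  path <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(matrix(0.5, 140, 150)), path)
  expect_warning(img <- read_image(path), "grayscale")
  expect_identical(dim(img$pixels)[3], 3L)
  expect_identical(img$pixels[, , 1], img$pixels[, , 2])
})

test_that("overlay paints lesion families green/blue and conserves areas", {
  sc <- fix_scene(5)
  d <- dim(sc$image$pixels)[1:2]
  empty <- lesion_set(list(), d)
  expect_identical(render_overlay(sc$image, empty)$pixels, sc$image$pixels)

  # one hemorrhage of 350 px -> exactly 350 pure-green pixels in the file
  idx <- which(fundusdr:::disc_raster(d[1], d[2], c(200, 200), 30))[1:350]
  ls1 <- lesion_set(list(lesion_region(1, "hemorrhage", idx, d)), d)
  path <- withr::local_tempfile(fileext = ".png")
  write_overlay(sc$image, ls1, path)
  ov <- read_image(path)
  green <- ov$pixels[, , 1] == 0 & ov$pixels[, , 2] == 255 & ov$pixels[, , 3] == 0
  expect_identical(sum(green), 350L)

  # mixed families: rendered-file pixel counts equal the QuantReport totals
  idx2 <- which(fundusdr:::disc_raster(d[1], d[2], c(300, 140), 9))
  idx3 <- which(fundusdr:::disc_raster(d[1], d[2], c(120, 320), 11))
  ls <- lesion_set(list(lesion_region(1, "hemorrhage", idx, d),
                        lesion_region(2, "microaneurysm", idx2, d),
                        lesion_region(3, "exudate", idx3, d)), d)
  write_overlay(sc$image, ls, path)
  ov <- read_image(path)
  q <- quantify_lesions(ls)
  green <- ov$pixels[, , 1] == 0 & ov$pixels[, , 2] == 255 & ov$pixels[, , 3] == 0
  blue <- ov$pixels[, , 1] == 0 & ov$pixels[, , 2] == 0 & ov$pixels[, , 3] == 255
  expect_identical(sum(green), as.integer(q$hemorrhage_total_area_px))
  expect_identical(sum(blue), as.integer(q$exudate_total_area_px))

  # overlap tie: overlapping pixels painted once, green over blue
  ls_ov <- lesion_set(list(lesion_region(1, "hemorrhage", idx, d),
                           lesion_region(2, "exudate", idx[1:100], d)), d)
  ov2 <- render_overlay(sc$image, ls_ov)
  green2 <- ov2$pixels[, , 1] == 0 & ov2$pixels[, , 2] == 255 & ov2$pixels[, , 3] == 0
  blue2 <- ov2$pixels[, , 2] == 0 & ov2$pixels[, , 3] == 255 & ov2$pixels[, , 1] == 0
  expect_identical(sum(green2), 350L)
  expect_identical(sum(blue2), 0L)

  bad <- lesion_set(list(), c(256L, 256L))
  expect_error(render_overlay(sc$image, bad), class = "fdr_contract_error")
})

test_that("reports serialise records with literal stage names and round-trip", {
  recs <- list(
    grading_record("a", "DR2", list(flags = character(), qualified = TRUE),
                   quant_report("a", 350, 2, 250, 90, 1, 90)),
    grading_record("b", "DR0", list(flags = character(), qualified = TRUE),
                   quant_report("b", 0, 0, 0, 0, 0, 0)),
    grading_record("c", "UNGRADABLE",
                   list(flags = c("fuzzy", "dark_area"), qualified = FALSE), NULL))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(recs, csv, "csv")
  lines <- readLines(csv)
  expect_length(lines, 4L)            # header + 3 rows
  parsed <- read.csv(csv, stringsAsFactors = FALSE)
  expect_identical(names(parsed)[1:4], c("image_id", "stage", "qualified", "flags"))
  expect_identical(parsed$stage, c("DR2", "DR0", "UNGRADABLE"))

  json <- withr::local_tempfile(fileext = ".json")
  write_report(recs, json, "json")
  back <- read_report(json, "json")
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$stage, recs[[i]]$stage)
    expect_identical(back[[i]]$image_id, recs[[i]]$image_id)
    expect_identical(back[[i]]$quant, recs[[i]]$quant)
    expect_identical(back[[i]]$quality$flags, recs[[i]]$quality$flags)
  }
  expect_error(write_report(list(), csv, "csv"), class = "fdr_contract_error")
})

test_that("a grading record is UNGRADABLE exactly when disqualified", {
  q_bad <- list(flags = "fuzzy", qualified = FALSE)
  expect_error(grading_record("x", "DR1", q_bad), class = "fdr_contract_error")
  expect_error(grading_record("x", "UNGRADABLE", qualified_quality()),
               class = "fdr_contract_error")
  expect_silent(grading_record("x", "UNGRADABLE", q_bad))
})
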