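# Shared fixtures, built in code and cached for the test session.

.fix <- new.env()

fix_cfg <- function() {
  if (is.null(.fix$cfg)) .fix$cfg <- dr_config()
  .fix$cfg
}

fix_model <- function() {
  if (is.null(.fix$model)) .fix$model <- default_red_lesion_model(cfg = fix_cfg())
  .fix$model
}

# Memoised rendered scenes keyed by seed + lesion spec.
fix_scene <- function(seed, lesions = list(), size = c(512L, 512L)) {
  key <- paste0("scene_", seed, "_", digest_lesions(lesions), "_", size[1])
  if (is.null(.fix[[key]]))
    .fix[[key]] <- render_scene(scene_spec(size = size, lesions = lesions,
                                           seed = seed))
  .fix[[key]]
}

digest_lesions <- function(lesions) {
  if (length(lesions) == 0) return("clean")
  paste(vapply(names(lesions), function(n)
    paste0(n, paste(unlist(lesions[[n]]), collapse = "-")), character(1)),
    collapse = "_")
}

# Memoised preprocessing of a fixture scene.
fix_pre <- function(seed, lesions = list()) {
  key <- paste0("pre_", seed, "_", digest_lesions(lesions))
  if (is.null(.fix[[key]])) {
    sc <- fix_scene(seed, lesions)
    .fix[[key]] <- fundusdr:::preprocess_scene(sc$image, fix_cfg())
  }
  .fix[[key]]
}

# A flat mid-gray frame (no black border).
flat_image <- function(value = 128, h = 160, w = 160) {
  fundus_image(array(value, c(h, w, 3)), "flat")
}

# Synthetic lesion regions laid out on a grid, for rule/property tests that
# need lesion sets without running detection.
grid_lesion_pool <- function(dim = c(512L, 512L), n_ma = 6, n_hem = 30,
                             n_ex = 8, hem_area = 60) {
  h <- dim[1]
  mk <- function(k, class, row, col, r) {
    idx <- which(fundusdr:::disc_raster(dim[1], dim[2], c(row, col), r))
    lesion_region(k, class, idx, dim)
  }
  pool <- list(); k <- 0
  place <- function(n, class, r) {
    for (i in seq_len(n)) {
      k <<- k + 1
      row <- 40 + ((k * 53) %% (h - 80)); col <- 40 + ((k * 97) %% (h - 80))
      pool[[k]] <<- mk(k, class, row, col, r)
    }
  }
  place(n_ma, "microaneurysm", 2)
  place(n_hem, "hemorrhage", sqrt(hem_area / pi))
  place(n_ex, "exudate", 5)
  pool
}

# Full-frame quadrant map about the frame centre (for rule tests).
full_quadrants <- function(dim = c(512L, 512L)) {
  roi <- roi_mask(matrix(TRUE, dim[1], dim[2]))
  disc <- structure(list(center = c(dim[1] / 2, dim[2] / 2 + 40),
                         radius_px = 30, confidence = 1,
                         low_confidence = FALSE), class = "optic_disc")
  partition_quadrants(roi, disc, fix_cfg())
}

qualified_quality <- function() {
  list(fuzzy_score = 20, dark_fraction = 0, saturated_fraction = 0,
       eyelash_score = 0, decenter_px = 0, flags = character(),
       qualified = TRUE)
}

stage_rank <- function(stage) match(stage, c("DR0", "DR1", "DR2", "DR3"))
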