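# Seeded synthetic fundus-scene generator with exact per-pixel ground truth.
#
# Scenes emulate 45-degree non-mydriatic fundus photographs: a circular
# retinal field on a black background, a branching vessel tree rooted at a
# bright optic disc, a darker macula, and planted lesions whose pixel areas
# are known exactly. All randomness flows from one scene seed, so any scene
# is reproducible in isolation.

CLASS_CODES <- c(background = 0L, field = 1L, vessel = 2L, disc = 3L,
                 macula = 4L, microaneurysm = 5L, hemorrhage = 6L,
                 exudate = 7L, cottonwool = 8L, prp_scar = 9L)
LESION_CLASSES <- c("microaneurysm", "hemorrhage", "exudate", "cottonwool",
                    "prp_scar")

#' Synthetic scene specification
#'
#' Describes one synthetic fundus photograph: canvas size, field-of-view
#' radius, optic-disc/macula geometry, vessel-tree parameters, per-class
#' lesion loads and the scene seed. Lesion `count` entries may be a single
#' number or a `c(min, max)` range sampled per scene; `area` and `contrast`
#' are `c(min, max)` ranges sampled per lesion. Contrast (0, 1] scales how
#' far the lesion colour departs from the local retina colour and is the
#' difficulty dial for detection tests.
#'
#' @param size `c(H, W)` canvas in pixels.
#' @param field_radius_frac Field radius as a fraction of `min(H, W) / 2`.
#' @param laterality `"OD"` (disc nasal-right) or `"OS"` (mirrored).
#' @param disc,macula,vessels,lesions Parameter lists; see defaults.
#' @param noise_sd Per-pixel Gaussian noise, gray levels.
#' @param seed Scene seed (all randomness derives from it).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(size = c(512L, 512L), field_radius_frac = 0.46,
                       laterality = "OD",
                       disc = list(), macula = list(), vessels = list(),
                       lesions = list(), noise_sd = 3, seed = 1L) {
  stopifnot(field_radius_frac > 0, field_radius_frac < 1, all(size >= 128))
  d <- utils::modifyList(list(offset_frac = 0.55, radius_frac = 0.14,
                              brightness = 1.0), disc)
  m <- utils::modifyList(list(offset_frac = 0.45, radius_frac = 0.18,
                              darkening = 0.84), macula)
  v <- utils::modifyList(list(n_trunks = 5L, depth = 3L, init_width = 6,
                              width_decay = 0.72, wiggle = 0.18, step = 2), vessels)
  ldef <- list(
    microaneurysm = list(count = 0, area = c(5, 20), contrast = c(0.7, 1)),
    hemorrhage    = list(count = 0, area = c(50, 500), contrast = c(0.7, 1)),
    exudate       = list(count = 0, area = c(40, 300), contrast = c(0.7, 1)),
    cottonwool    = list(count = 0, area = c(150, 500), contrast = c(0.5, 0.8)),
    prp_scar      = list(count = 0, area = c(50, 120), contrast = c(0.6, 0.9)))
  for (cl in names(lesions)) {
    if (!cl %in% LESION_CLASSES) contract_error(paste0("unknown lesion class: ", cl))
    ldef[[cl]] <- utils::modifyList(ldef[[cl]], lesions[[cl]])
  }
  structure(list(size = as.integer(size), field_radius_frac = field_radius_frac,
                 laterality = match.arg(laterality, c("OD", "OS")),
                 disc = d, macula = m, vessels = v, lesions = ldef,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Exact ground truth for a synthetic scene
#'
#' @param label_raster Integer `H x W` raster of per-pixel class codes
#'   (see `CLASS_CODES` mapping in the package source).
#' @param regions Data frame: `region_id`, `class`, `pixel_area`,
#'   `centroid_row`, `centroid_col`.
#' @param masks Named list of logical rasters: `field`, `vessel`, `disc`,
#'   `macula`.
#' @param disc_center,disc_radius Planted disc geometry.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(label_raster, regions, masks, disc_center, disc_radius) {
  structure(list(label_raster = label_raster, regions = regions, masks = masks,
                 disc_center = disc_center, disc_radius = disc_radius),
            class = "ground_truth")
}

# -- low-level stamping -----------------------------------------------------

# Pixel linear indices of a rotated ellipse with the given pixel area.
ellipse_pixels <- function(h, w, center, area, aspect = 1, theta = 0) {
  b <- sqrt(area / (pi * aspect)); a <- aspect * b
  r <- ceiling(max(a, b)) + 1L
  r0 <- max(1L, floor(center[1] - r)); r1 <- min(h, ceiling(center[1] + r))
  c0 <- max(1L, floor(center[2] - r)); c1 <- min(w, ceiling(center[2] + r))
  if (r0 > r1 || c0 > c1) return(integer())
  rows <- matrix(rep(r0:r1, c1 - c0 + 1L), r1 - r0 + 1L)
  cols <- matrix(rep(c0:c1, each = r1 - r0 + 1L), r1 - r0 + 1L)
  dy <- rows - center[1]; dx <- cols - center[2]
  u <- dx * cos(theta) + dy * sin(theta)
  vq <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (vq / b)^2 <= 1
  (cols[inside] - 1L) * h + rows[inside]
}

disk_pixels <- function(h, w, center, radius) {
  ellipse_pixels(h, w, center, pi * radius^2, 1, 0)
}

# Paint linear-index pixels with an RGB colour, optionally alpha-blended.
paint <- function(channels, idx, rgb, alpha = 1) {
  for (ch in 1:3) {
    if (length(alpha) > 1 || alpha < 1) {
      channels[[ch]][idx] <- (1 - alpha) * channels[[ch]][idx] + alpha * rgb[ch]
    } else channels[[ch]][idx] <- rgb[ch]
  }
  channels
}

sample_range <- function(rng) if (length(rng) == 1) rng else runif(1, rng[1], rng[2])
sample_count <- function(cnt) {
  if (length(cnt) == 1) as.integer(cnt)
  else as.integer(round(runif(1, cnt[1], cnt[2])))
}

# -- vessel tree ------------------------------------------------------------

# Recursive branching tree rooted at the disc; stamps disks of decaying
# width along wiggling paths. Returns logical vessel mask.
grow_vessels <- function(h, w, origin, roi_center, roi_radius, vp) {
  mask <- matrix(FALSE, h, w)
  stamp <- function(center, width) {
    idx <- disk_pixels(h, w, center, max(1.2, width / 2))
    mask[idx] <<- TRUE
  }
  walk <- function(pos, angle, width, depth, steps_left) {
    while (steps_left > 0) {
      angle <- angle + rnorm(1, 0, vp$wiggle)
      pos <- pos + vp$step * c(sin(angle), cos(angle))
      if (sqrt(sum((pos - roi_center)^2)) > roi_radius - 2) return()
      stamp(pos, width)
      steps_left <- steps_left - 1
      if (depth > 0 && runif(1) < 0.05) {
        da <- runif(1, 0.35, 0.8)
        walk(pos, angle - da, width * vp$width_decay, depth - 1,
             round(steps_left * 0.9))
        angle <- angle + da * 0.8
        width <- width * vp$width_decay
        depth <- depth - 1
      }
    }
  }
  base_angles <- seq(0, 2 * pi, length.out = vp$n_trunks + 1)[- (vp$n_trunks + 1)]
  for (a in base_angles) {
    a0 <- a + runif(1, -0.25, 0.25)
    walk(origin, a0, vp$init_width, vp$depth,
         round(2.2 * roi_radius / vp$step))
  }
  mask
}

# -- scene rendering --------------------------------------------------------

#' Render a synthetic fundus scene
#'
#' Deterministically renders the photograph described by a [scene_spec()]
#' together with exact ground truth: a per-pixel class raster and a region
#' table whose `pixel_area` equals the planted pixel count of each lesion
#' exactly. Lesions are placed inside the field, clear of the optic disc;
#' red lesions are additionally placed off-vessel. Placement that still
#' fails after bounded retries raises a generation error naming the class.
#'
#' @param spec A `scene_spec`.
#' @return List with elements `image` ([fundus_image()]) and `truth`
#'   ([ground_truth()]).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, render_scene_impl(spec))
}

render_scene_impl <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  roi_center <- c((h + 1) / 2, (w + 1) / 2)
  roi_radius <- spec$field_radius_frac * min(h, w)
  side <- if (spec$laterality == "OD") 1 else -1

  lab <- matrix(CLASS_CODES["background"], h, w)
  ri <- row_index(h, w); ci <- col_index(h, w)
  dist2 <- (ri - roi_center[1])^2 + (ci - roi_center[2])^2
  field <- dist2 <= roi_radius^2
  lab[field] <- CLASS_CODES["field"]

  # retina base colour with radial vignette
  vign <- 1 - 0.12 * pmin(1, sqrt(dist2) / roi_radius)^2
  chans <- list(matrix(8, h, w), matrix(8, h, w), matrix(8, h, w))
  base_rgb <- c(185, 92, 45)
  for (ch in 1:3) chans[[ch]][field] <- (base_rgb[ch] * vign)[field]

  # macula: darker ellipse temporal to the disc
  mac_center <- roi_center + c(0, -side * spec$macula$offset_frac * roi_radius)
  mac_idx <- ellipse_pixels(h, w, mac_center,
                            pi * (spec$macula$radius_frac * roi_radius)^2,
                            aspect = 1.15, theta = 0)
  for (ch in 1:3) chans[[ch]][mac_idx] <- chans[[ch]][mac_idx] * spec$macula$darkening
  mac_mask <- matrix(FALSE, h, w); mac_mask[mac_idx] <- TRUE
  lab[mac_idx] <- CLASS_CODES["macula"]

  # optic disc: bright circle nasal to centre, soft 2-px rim
  disc_center <- roi_center + c(0, side * spec$disc$offset_frac * roi_radius)
  disc_radius <- spec$disc$radius_frac * roi_radius
  disc_rgb <- c(238, 216, 170) * spec$disc$brightness
  ddist <- sqrt((ri - disc_center[1])^2 + (ci - disc_center[2])^2)
  core <- ddist <= disc_radius
  rim <- ddist > disc_radius & ddist <= disc_radius + 2
  for (ch in 1:3) {
    chans[[ch]][core] <- disc_rgb[ch]
    a <- (disc_radius + 2 - ddist[rim]) / 2
    chans[[ch]][rim] <- (1 - a) * chans[[ch]][rim] + a * disc_rgb[ch]
  }
  disc_mask <- core & field
  lab[disc_mask] <- CLASS_CODES["disc"]

  # vessels rooted at the disc
  vessel_mask <- grow_vessels(h, w, disc_center, roi_center, roi_radius,
                              spec$vessels)
  vessel_mask <- vessel_mask & field & !disc_mask
  vrgb <- c(108, 38, 28)
  for (ch in 1:3) chans[[ch]][vessel_mask] <- vrgb[ch]
  lab[vessel_mask] <- CLASS_CODES["vessel"]

  # lesion placement
  taken <- matrix(FALSE, h, w)                       # planted lesion pixels
  disc_block <- dilate_disc(disc_mask, 4)
  vessel_block <- dilate_disc(vessel_mask, 2)
  regions <- list(); region_id <- 0L

  place_lesion <- function(class, area, contrast) {
    red <- class %in% c("microaneurysm", "hemorrhage")
    prp <- class == "prp_scar"
    shape_r <- sqrt(area / pi)
    for (try in 1:250) {
      if (prp) {
        rad <- runif(1, 0.58, 0.92) * roi_radius
        ang <- runif(1, 0, 2 * pi)
        ctr <- roi_center + rad * c(sin(ang), cos(ang))
      } else {
        rad <- sqrt(runif(1)) * (roi_radius - shape_r - 6)
        ang <- runif(1, 0, 2 * pi)
        ctr <- roi_center + rad * c(sin(ang), cos(ang))
      }
      aspect <- runif(1, 0.8, 1.3); theta <- runif(1, 0, pi)
      idx <- ellipse_pixels(h, w, ctr, area, aspect, theta)
      if (length(idx) == 0) next
      if (any(!field[idx])) next
      if (any(disc_block[idx]) || any(taken[idx])) next
      if (red) {
        # small red lesions stay strictly off-vessel; large ones may cross a
        # vessel marginally (kept well under the 20% overlap invariant)
        if (area <= 100 && any(vessel_block[idx])) next
        if (area > 100 && mean(vessel_mask[idx]) >= 0.10) next
      } else if (any(vessel_mask[idx])) next
      return(list(idx = idx, center = ctr))
    }
    fdr_error(paste0("could not place a ", class, " lesion after 250 tries"),
              "fdr_generation_error")
  }

  lesion_colour <- function(class, idx, contrast) {
    # colour relative to local retina base; contrast in (0, 1] scales the step
    local <- vapply(1:3, function(ch) mean(chans[[ch]][idx]), numeric(1))
    target <- switch(class,
      microaneurysm = c(95, 30, 22),
      hemorrhage    = c(98, 32, 24),
      exudate       = c(246, 234, 130),
      cottonwool    = c(225, 210, 185),
      prp_scar      = c(215, 190, 150))
    local + contrast * (target - local)
  }

  for (class in LESION_CLASSES) {
    lp <- spec$lesions[[class]]
    n <- sample_count(lp$count)
    if (n <= 0) next
    for (i in seq_len(n)) {
      area <- sample_range(lp$area)
      contrast <- sample_range(lp$contrast)
      pl <- place_lesion(class, area, contrast)
      col <- lesion_colour(class, pl$idx, contrast)
      if (class == "cottonwool") {
        # fuzzy edge: alpha decays towards the boundary, support unchanged
        ctr <- pl$center
        rr <- ((pl$idx - 1L) %% h) + 1L; cc <- ((pl$idx - 1L) %/% h) + 1L
        dd <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
        alpha <- 0.45 + 0.55 * pmax(0, 1 - dd / (max(dd) + 1e-9))
        chans <- paint(chans, pl$idx, col, alpha)
      } else {
        chans <- paint(chans, pl$idx, col, 1)
      }
      taken[pl$idx] <- TRUE
      lab[pl$idx] <- CLASS_CODES[class]
      region_id <- region_id + 1L
      rr <- ((pl$idx - 1L) %% h) + 1L; cc <- ((pl$idx - 1L) %/% h) + 1L
      regions[[region_id]] <- data.frame(
        region_id = region_id, class = class, pixel_area = length(pl$idx),
        centroid_row = mean(rr), centroid_col = mean(cc),
        stringsAsFactors = FALSE)
    }
  }

  vessel_mask <- vessel_mask & !taken   # lesions painted over vessels win

  # pixel noise, clipped
  noise <- matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- clip255(round(chans[[ch]] + noise))

  regions_df <- if (length(regions)) do.call(rbind, regions) else
    data.frame(region_id = integer(), class = character(),
               pixel_area = integer(), centroid_row = numeric(),
               centroid_col = numeric(), stringsAsFactors = FALSE)
  list(
    image = fundus_image(px, image_id = paste0("synth_", spec$seed)),
    truth = ground_truth(lab, regions_df,
                         masks = list(field = field, vessel = vessel_mask,
                                      disc = disc_mask, macula = mac_mask),
                         disc_center = disc_center, disc_radius = disc_radius))
}

# -- quality degradations ---------------------------------------------------

#' Apply a named quality degradation
#'
#' Applies one of the corruptions that disqualify screening photographs:
#' `blur` (Gaussian defocus), `dark_patch` (large underexposed area),
#' `eyelash` (dark lash shadows intruding across the upper field boundary),
#' `overexpose` (global saturation) or `decenter` (field shifted off
#' centre). Severity in (0, 1] maps monotonically to corruption strength;
#' at severity -> 0 the output approaches the input.
#'
#' @param image A `fundus_image`.
#' @param mode Degradation name.
#' @param severity Strength in (0, 1].
#' @param seed Seed for any stochastic placement.
#' @return The degraded `fundus_image`.
#' @export
degrade <- function(image, mode, severity, seed = 1L) {
  stopifnot(inherits(image, "fundus_image"))
  if (!mode %in% c("blur", "dark_patch", "eyelash", "overexpose", "decenter"))
    contract_error(paste0("unknown degradation mode: ", mode))
  if (severity <= 0 || severity > 1) contract_error("severity must be in (0, 1]")
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  out <- with_seed(seed, switch(mode,
    blur = {
      sigma <- 12 * severity
      if (sigma < 0.3) px else {
        a <- EBImage::gblur(px, sigma = sigma)
        clip255(a)
      }
    },
    dark_patch = {
      roi_r <- 0.46 * min(h, w)
      patch_r <- roi_r * sqrt(severity / 2)
      ctr <- c(h / 2, w / 2) + runif(2, -0.2, 0.2) * roi_r
      idx <- disk_pixels(h, w, ctr, patch_r)
      for (ch in 1:3) { p <- px[, , ch]; p[idx] <- p[idx] * 0.12; px[, , ch] <- p }
      px
    },
    eyelash = {
      n <- 2 + round(4 * severity)
      len <- 0.55 * severity * h
      for (k in seq_len(n)) {
        x0 <- runif(1, 0.2, 0.8) * w; drift <- runif(1, -0.4, 0.4)
        tpts <- seq(0, 1, length.out = max(8, round(len / 3)))
        for (t in tpts) {
          ctr <- c(1 + t * len, x0 + drift * t * len + 10 * sin(6 * t))
          idx <- disk_pixels(h, w, ctr, 2.2 + 1.5 * severity)
          for (ch in 1:3) { p <- px[, , ch]; p[idx] <- p[idx] * 0.15; px[, , ch] <- p }
        }
      }
      px
    },
    overexpose = clip255(px * (1 + 3 * severity) + 80 * severity),
    decenter = {
      dx <- round(0.5 * severity * w)
      out <- array(0, dim(px)); out[, , ] <- 6
      if (dx < w) out[, (dx + 1):w, ] <- px[, 1:(w - dx), , drop = FALSE]
      out
    }))
  fundus_image(clip255(out), paste0(image$image_id, "_", mode), image$source_path)
}

# -- cohorts ----------------------------------------------------------------

#' Specification of a stage-structured synthetic cohort
#'
#' Groups mirror the severity grouping used for lesion-burden comparisons:
#' group 1 mild+moderate NPDR, group 2 severe NPDR, group 3 PDR, with the
#' default sizes n = 39 / 29 / 23. Lesion-load templates are calibrated so
#' planted total-area means increase strictly with severity while planted
#' lesion counts peak in group 2 (severe disease shows many discrete
#' lesions; in PDR they enlarge and fuse, so counts drop but areas grow).
#'
#' @param seed Root cohort seed.
#' @param size Canvas `c(H, W)` for every scene.
#' @return A `cohort_spec` list of `(label, n, template)` groups.
#' @export
dr_cohort_spec <- function(seed = 20160401L, size = c(512L, 512L)) {
  g1 <- list(microaneurysm = list(count = c(1, 4)),
             hemorrhage = list(count = c(0, 5), area = c(60, 200)),
             exudate = list(count = c(0, 3), area = c(40, 150)),
             cottonwool = list(count = c(0, 1), area = c(150, 300)))
  g2 <- list(microaneurysm = list(count = c(2, 6)),
             hemorrhage = list(count = c(18, 30), area = c(150, 380)),
             exudate = list(count = c(8, 18), area = c(80, 300)),
             cottonwool = list(count = c(1, 2), area = c(200, 450)))
  g3 <- list(microaneurysm = list(count = c(0, 3)),
             hemorrhage = list(count = c(8, 14), area = c(900, 2000)),
             exudate = list(count = c(4, 8), area = c(400, 1200)),
             cottonwool = list(count = c(1, 2), area = c(300, 600)))
  structure(list(
    groups = list(list(label = "group1", n = 39L, lesions = g1),
                  list(label = "group2", n = 29L, lesions = g2),
                  list(label = "group3", n = 23L, lesions = g3)),
    size = as.integer(size), seed = as.integer(seed)), class = "cohort_spec")
}

#' Simulate a stage-structured cohort of scenes
#'
#' Renders every scene of a [dr_cohort_spec()] (deterministic per-scene
#' seeds split from the cohort seed) and computes the ground-truth group
#' summaries of the six quantification indices. The construction guarantees
#' (and this function verifies) that planted total-hemorrhage-area group
#' means increase strictly with severity and planted lesion counts peak in
#' group 2.
#'
#' @param spec A `cohort_spec`.
#' @return List: `scenes` (list of `(image, truth, group)`), `truth_reports`
#'   (list of [quant_report()] from ground truth), `assignment` (named group
#'   vector), `truth_summary` (data frame from [summarize_groups()]).
#' @export
simulate_cohort <- function(spec = dr_cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(vapply(spec$groups, function(g) g$n, integer(1)) < 2))
    contract_error("each cohort group needs n >= 2")
  scenes <- list(); reports <- list(); assignment <- character()
  k <- 0L
  for (g in spec$groups) {
    for (i in seq_len(g$n)) {
      k <- k + 1L
      sp <- scene_spec(size = spec$size, lesions = g$lesions,
                       seed = split_seed(spec$seed, k))
      sc <- render_scene(sp)
      sc$group <- g$label
      sc$image$image_id <- sprintf("%s_%03d", g$label, i)
      scenes[[k]] <- sc
      reports[[k]] <- quantify_truth(sc$truth, sc$image$image_id)
      assignment[sc$image$image_id] <- g$label
    }
  }
  summ <- summarize_groups(reports, assignment)
  tot <- summ[summ$index == "hemorrhage_total_area_px", ]
  cnt <- summ[summ$index == "hemorrhage_count", ]
  if (!all(diff(tot$mean[order(tot$group)]) > 0))
    fdr_error("cohort construction violated the area ordering",
              "fdr_generation_error")
  if (!(cnt$mean[cnt$group == "group2"] > cnt$mean[cnt$group == "group3"]))
    fdr_error("cohort construction violated the count ordering",
              "fdr_generation_error")
  list(scenes = scenes, truth_reports = reports, assignment = assignment,
       truth_summary = summ)
}

#' Quantify a scene's ground truth
#'
#' Computes the six quantification indices directly from planted regions —
#' the oracle against which pipeline quantification is compared.
#'
#' @param truth A [ground_truth()].
#' @param image_id Identifier for the report.
#' @param include_microaneurysms Count MAs in the hemorrhage family.
#' @return A [quant_report()].
#' @export
quantify_truth <- function(truth, image_id = "", include_microaneurysms = TRUE) {
  r <- truth$regions
  hem_cls <- if (include_microaneurysms) c("microaneurysm", "hemorrhage") else
    "hemorrhage"
  fam <- function(cls) {
    a <- r$pixel_area[r$class %in% cls]
    list(total = sum(a), count = length(a), max = if (length(a)) max(a) else 0L)
  }
  h <- fam(hem_cls); e <- fam(c("exudate", "cottonwool"))
  quant_report(image_id, h$total, h$count, h$max, e$total, e$count, e$max)
}

#' The 20-scene validation suite
#'
#' A fixed-seed suite used for detection validation: 14 scenes with mixed
#' lesion loads (hemorrhages of at least 50 px, microaneurysms, exudates,
#' occasional cotton-wool spots) and 6 lesion-free scenes for
#' false-positive accounting.
#'
#' @param seed Suite seed.
#' @param size Canvas size.
#' @return List of rendered scenes, each with a `clean` flag.
#' @export
validation_suite <- function(seed = 77L, size = c(512L, 512L)) {
  scenes <- vector("list", 20L)
  for (i in 1:20) {
    clean <- i > 14
    lesions <- if (clean) list() else list(
      microaneurysm = list(count = c(1, 3)),
      hemorrhage = list(count = c(3, 8), area = c(80, 400)),
      exudate = list(count = c(2, 5), area = c(60, 250)),
      cottonwool = list(count = c(0, 1)))
    sp <- scene_spec(size = size, lesions = lesions, seed = split_seed(seed, i))
    sc <- render_scene(sp)
    sc$image$image_id <- sprintf("suite_%02d", i)
    sc$clean <- clean
    scenes[[i]] <- sc
  }
  scenes
}

#' Write a rendered dataset to disk
#'
#' Writes each scene as a PNG plus a JSON ground-truth region table, and a
#' CSV of the ground-truth quantification indices.
#'
#' @param scenes List of rendered scenes (as from [simulate_cohort()]`$scenes`
#'   or [validation_suite()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(scenes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (sc in scenes) {
    id <- sc$image$image_id
    write_image(sc$image, file.path(dir, paste0(id, ".png")))
    jsonlite::write_json(sc$truth$regions,
                         file.path(dir, paste0(id, "_truth.json")),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    q <- quantify_truth(sc$truth, id)
    rows[[length(rows) + 1L]] <- as.data.frame(unclass(q), stringsAsFactors = FALSE)
  }
  write.csv(do.call(rbind, rows), file.path(dir, "truth_summary.csv"),
            row.names = FALSE)
  invisible(dir)
}
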