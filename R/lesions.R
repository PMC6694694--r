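# Red-lesion (microaneurysm/hemorrhage), bright-lesion (exudate/cotton-wool)
# and photocoagulation-scar detection.

#' Lesion region record
#'
#' One detected lesion: class, pixel support (linear indices into the
#' `H x W` frame), exact pixel area, centroid and shape/colour features.
#'
#' @param region_id Integer id.
#' @param class One of `microaneurysm`, `hemorrhage`, `exudate`,
#'   `cottonwool`, `prp_scar`.
#' @param pixels Integer vector of linear pixel indices.
#' @param dim `c(H, W)` of the frame.
#' @param features Named list/row of region features (may be `NULL`).
#' @return A `lesion_region`.
#' @export
lesion_region <- function(region_id, class, pixels, dim, features = NULL) {
  if (!class %in% LESION_CLASSES)
    contract_error(paste0("unknown lesion class: ", class))
  pixels <- sort(unique(as.integer(pixels)))
  h <- dim[1]
  rr <- ((pixels - 1L) %% h) + 1L; cc <- ((pixels - 1L) %/% h) + 1L
  structure(list(region_id = as.integer(region_id), class = class,
                 pixels = pixels, area_px = length(pixels),
                 centroid = c(mean(rr), mean(cc)), features = features,
                 dim = as.integer(dim)),
            class = "lesion_region")
}

#' Lesion set
#'
#' A collection of [lesion_region()]s plus per-class binary rasters (each
#' raster is the union of that class's region masks).
#'
#' @param regions List of `lesion_region` objects.
#' @param dim `c(H, W)` frame size.
#' @return A `lesion_set`.
#' @export
lesion_set <- function(regions = list(), dim) {
  rasters <- setNames(lapply(LESION_CLASSES, function(cl) {
    m <- matrix(FALSE, dim[1], dim[2])
    for (r in regions) if (r$class == cl) m[r$pixels] <- TRUE
    m
  }), LESION_CLASSES)
  structure(list(regions = regions, rasters = rasters, dim = as.integer(dim)),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  tab <- table(factor(vapply(x$regions, function(r) r$class, character(1)),
                      levels = LESION_CLASSES))
  cat("<lesion_set:", paste(names(tab), as.integer(tab), collapse = ", "), ">\n")
  invisible(x)
}

#' Merge lesion sets on the same frame
#'
#' @param ... `lesion_set` objects with identical dimensions.
#' @return A combined `lesion_set` with renumbered region ids.
#' @export
merge_lesion_sets <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  if (length(sets) == 0) contract_error("nothing to merge")
  d <- sets[[1]]$dim
  regions <- list(); k <- 0L
  for (s in sets) {
    if (!identical(s$dim, d)) contract_error("lesion sets differ in frame size")
    for (r in s$regions) { k <- k + 1L; r$region_id <- k; regions[[k]] <- r }
  }
  lesion_set(regions, d)
}

# ---------------------------------------------------------------------------
# Region features

# Gradient magnitude of the luminance (central differences), computed once
# per image for boundary-sharpness features.
gradient_magnitude <- function(L) {
  h <- nrow(L); w <- ncol(L)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (L[, 3:w] - L[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (L[3:h, ] - L[1:(h - 2), ]) / 2
  sqrt(gx^2 + gy^2)
}

# Features for each labelled candidate region. lab: integer label raster.
# Returns a data frame with one row per label id.
region_features <- function(image, lab, vessels = NULL) {
  h <- nrow(lab); w <- ncol(lab)
  nlab <- max(lab)
  if (nlab == 0) return(NULL)
  px <- image$pixels
  hsl <- rgb_to_hsl(px)
  L <- luminance(px)
  gm <- gradient_magnitude(L)
  green <- px[, , 2]
  vdist <- if (!is.null(vessels) && any(vessels$mask))
    EBImage::distmap(!vessels$mask) else NULL
  idx_by <- split(which(lab > 0), lab[lab > 0])
  out <- lapply(seq_len(nlab), function(i) {
    idx <- idx_by[[as.character(i)]]
    if (is.null(idx)) return(NULL)
    rr <- ((idx - 1L) %% h) + 1L; cc <- ((idx - 1L) %/% h) + 1L
    a <- length(idx)
    # all morphology happens on a cropped bounding box, not the full frame
    mar <- max(3L, as.integer(round(sqrt(a / pi) * 0.6)) + 1L)
    r0 <- max(1L, min(rr) - mar); r1 <- min(h, max(rr) + mar)
    c0 <- max(1L, min(cc) - mar); c1 <- min(w, max(cc) + mar)
    lh <- r1 - r0 + 1L
    m <- matrix(FALSE, lh, c1 - c0 + 1L)
    lidx <- (cc - c0) * lh + (rr - r0 + 1L)
    m[lidx] <- TRUE
    er <- EBImage::erode(m, EBImage::makeBrush(3, "box")) > 0
    bidx <- idx[!er[lidx]]
    per <- max(length(bidx), 4)
    # second moments for eccentricity
    cy <- mean(rr); cx <- mean(cc)
    mrr <- mean((rr - cy)^2); mcc <- mean((cc - cx)^2)
    mrc <- mean((rr - cy) * (cc - cx))
    tr <- mrr + mcc; det <- mrr * mcc - mrc^2
    disc2 <- max(0, tr^2 / 4 - det)
    l1 <- tr / 2 + sqrt(disc2); l2 <- tr / 2 - sqrt(disc2)
    ecc <- if (l1 > 0) sqrt(pmax(0, 1 - l2 / l1)) else 0
    ecc <- min(ecc, 0.999)
    # surround ring for contrast
    dil <- EBImage::dilate(m, EBImage::makeBrush(2L * max(2L, as.integer(round(sqrt(a / pi) * 0.6))) + 1L, "disc")) > 0
    ring_l <- which(dil & !m)
    ring <- ((ring_l - 1L) %/% lh + c0 - 1L) * h + ((ring_l - 1L) %% lh + r0)
    green_contrast <- if (length(ring)) mean(green[ring]) - mean(green[idx]) else 0
    data.frame(
      region_id = i, area_px = a,
      eccentricity = ecc,
      circularity = max(0.01, min(1, 4 * pi * a / per^2)),
      mean_hue = mean(hsl$h[idx]), mean_saturation = mean(hsl$s[idx]),
      mean_lightness = mean(hsl$l[idx]),
      green_contrast = green_contrast,
      boundary_gradient = mean(gm[bidx]),
      dist_to_vessel_px = if (is.null(vdist)) NA_real_ else
        vdist[round(cy), round(cx)],
      centroid_row = cy, centroid_col = cx)
  })
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# Margin classifier (linear SVM, JSON-serialisable weights)

#' Train a candidate margin classifier
#'
#' Fits a linear support-vector machine on labelled feature rows and stores
#' it as plain weights (scaling, coefficient vector, intercept), so the
#' model is deterministic given (data, seed) and serialisable to JSON via
#' [write_model()].
#'
#' @param candidates Data frame of numeric features plus a `label` column
#'   with exactly two classes.
#' @param seed Training seed.
#' @param cost SVM cost parameter.
#' @return A `fdr_classifier`.
#' @export
train_candidate_classifier <- function(candidates, seed = 1L, cost = 1) {
  if (!"label" %in% names(candidates)) contract_error("candidates need a 'label' column")
  y <- factor(candidates$label)
  if (nlevels(y) < 2) contract_error("need at least two classes to train")
  if (nlevels(y) > 2) contract_error("the margin classifier is binary")
  xcols <- names(candidates)[vapply(candidates, is.numeric, logical(1))]
  x <- as.matrix(candidates[, xcols, drop = FALSE])
  keep <- apply(x, 2, function(col) sd(col) > 0)
  x <- x[, keep, drop = FALSE]
  ctr <- colMeans(x); scl <- apply(x, 2, sd)
  xs <- scale(x, ctr, scl)
  fit <- with_seed(seed, e1071::svm(xs, y, kernel = "linear", cost = cost,
                                    scale = FALSE))
  wv <- drop(t(fit$coefs) %*% fit$SV)
  structure(list(features = colnames(x), center = ctr, scale = scl,
                 w = wv, rho = fit$rho, classes = levels(y),
                 positive = levels(y)[1],  # decision value > 0 -> first level
                 seed = as.integer(seed), version = "1"),
            class = "fdr_classifier")
}

#' Predict with a candidate classifier
#'
#' @param model A `fdr_classifier`.
#' @param features Data frame containing the model's feature columns.
#' @return Character vector of predicted labels.
#' @export
predict_classifier <- function(model, features) {
  if (!inherits(model, "fdr_classifier"))
    config_error("model is not a trained fdr_classifier")
  x <- as.matrix(features[, model$features, drop = FALSE])
  xs <- scale(x, model$center, model$scale)
  dv <- drop(xs %*% model$w) - model$rho
  ifelse(dv > 0, model$classes[1], model$classes[2])
}

#' Serialise / read a classifier as JSON
#'
#' @param model A `fdr_classifier`.
#' @param path JSON file path.
#' @return `path` ([write_model()]) or the classifier ([read_model()]).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fdr_classifier"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$center <- unlist(m$center); m$scale <- unlist(m$scale); m$w <- unlist(m$w)
  structure(m, class = "fdr_classifier")
}

# Feature columns used by the red-lesion candidate classifier.
red_feature_cols <- c("area_px", "eccentricity", "circularity",
                      "mean_saturation", "mean_lightness", "green_contrast",
                      "boundary_gradient")

#' Default red-lesion candidate classifier
#'
#' Trained deterministically (fixed seed) on candidates extracted from
#' generator-labelled synthetic scenes: candidates overlapping planted red
#' lesions by at least half their area are positives, the rest (vessel
#' fragments, macular shading, noise blobs) negatives. Cached per session.
#'
#' @param seed Training corpus seed.
#' @param cfg Configuration.
#' @return A `fdr_classifier`.
#' @export
default_red_lesion_model <- function(seed = 20190814L, cfg = dr_config()) {
  key <- paste0("red_model_", seed)
  if (!is.null(.fdr_cache[[key]])) return(.fdr_cache[[key]])
  corpus <- red_candidate_corpus(seed, n_scenes = 6L, cfg = cfg)
  model <- train_candidate_classifier(
    corpus[, c(red_feature_cols, "label")], seed = seed)
  .fdr_cache[[key]] <- model
  model
}

# Labelled candidate corpus from synthetic scenes (used for training and
# for held-out accuracy checks).
red_candidate_corpus <- function(seed, n_scenes = 6L, cfg = dr_config()) {
  rows <- list()
  for (i in seq_len(n_scenes)) {
    sc <- render_scene(scene_spec(
      size = cfg$synthetic$size,
      lesions = list(microaneurysm = list(count = c(2, 5)),
                     hemorrhage = list(count = c(4, 10), area = c(50, 500)),
                     exudate = list(count = c(0, 3))),
      seed = split_seed(seed, i)))
    pr <- preprocess_scene(sc$image, cfg)
    cand <- red_candidates(pr$normalized, pr$vessels, pr$disc, pr$roi, cfg)
    if (is.null(cand$features)) next
    truthred <- sc$truth$label_raster == CLASS_CODES["microaneurysm"] |
      sc$truth$label_raster == CLASS_CODES["hemorrhage"]
    lab <- vapply(seq_len(nrow(cand$features)), function(j) {
      idx <- cand$pixels[[j]]
      if (mean(truthred[idx]) >= 0.5) "lesion" else "reject"
    }, character(1))
    f <- cand$features; f$label <- lab
    rows[[length(rows) + 1L]] <- f
  }
  out <- do.call(rbind, rows)
  if (length(unique(out$label)) < 2) {
    # degenerate corpus (no negatives survived): synthesise a few rejects
    neg <- out[1, , drop = FALSE]
    neg$label <- "reject"; neg$circularity <- 0.05; neg$eccentricity <- 0.99
    out <- rbind(out, neg)
  }
  out
}

# Shared candidate extraction for red lesions (before classification).
red_candidates <- function(image, vessels, disc, roi, cfg = dr_config()) {
  rl <- cfg$red_lesions
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  g <- px[, , 2]
  r_small <- max(2L, as.integer(round(disc$radius_px / rl$tophat_radius_div)))
  closed <- EBImage::closing(g, EBImage::makeBrush(2L * r_small + 1L, "disc"))
  tophat <- closed - g                       # dark top-hat: small red lesions
  small <- tophat > rl$tophat_threshold
  hsl <- rgb_to_hsl(px)
  large <- hsl$l < rl$color_lightness_max &
    (hsl$h < 40 | hsl$h > 320)               # colour rule: large red lesions
  disc_block <- disc_raster(h, w, disc$center, disc$radius_px * 1.2)
  # cut the vessel tree out of the candidate map: the colour rule matches
  # vessels too, and dark lesions would otherwise merge with the network
  # into one giant component
  vcut <- dilate_disc(vessels$mask, 2)
  cand <- (small | large) & roi$mask & !disc_block & !vcut
  # per-region vessel-overlap suppression additionally happens below
  lab <- EBImage::bwlabel(cand)
  nlab <- max(lab)
  if (nlab == 0) return(list(features = NULL, pixels = list()))
  max_area <- rl$max_area_frac * roi$area_px
  min_area <- scale_area(rl$min_area_px, w)
  idx_by <- split(which(lab > 0), lab[lab > 0])
  keep <- logical(nlab); vfrac <- numeric(nlab)
  for (i in seq_len(nlab)) {
    idx <- idx_by[[as.character(i)]]
    a <- length(idx)
    vfrac[i] <- mean(vessels$mask[idx])
    keep[i] <- a >= min_area && a <= max_area && vfrac[i] < rl$vessel_overlap_max
  }
  relab <- matrix(0L, h, w)
  newid <- cumsum(keep)
  ki <- which(keep)
  for (i in ki) relab[idx_by[[as.character(i)]]] <- newid[i]
  feats <- region_features(image, relab, vessels)
  list(features = feats, pixels = idx_by[as.character(ki)], label_raster = relab)
}

#' Detect red lesions (microaneurysms and hemorrhages)
#'
#' Small candidates come from a dark top-hat (morphological closing minus
#' image) of the green channel at a small scale tied to the disc radius;
#' large candidates from a colour-discrimination rule (low lightness,
#' reddish hue). Candidates inside the optic disc or overlapping the vessel
#' map by at least the configured fraction are suppressed; the survivors
#' are accepted or rejected by a margin classifier on the region features
#' and split microaneurysm vs hemorrhage at the configured area boundary.
#'
#' @param image Normalised `fundus_image`.
#' @param vessels [segment_vessels()] output.
#' @param disc [locate_optic_disc()] output.
#' @param roi [roi_mask()].
#' @param model Candidate classifier; `NULL` uses
#'   [default_red_lesion_model()].
#' @param cfg Configuration (uses `cfg$red_lesions`).
#' @return A [lesion_set()] of microaneurysm/hemorrhage regions.
#' @export
detect_red_lesions <- function(image, vessels, disc, roi, model = NULL,
                               cfg = dr_config()) {
  stopifnot(inherits(image, "fundus_image"))
  if (is.null(model)) model <- default_red_lesion_model(cfg = cfg)
  if (!inherits(model, "fdr_classifier"))
    config_error("red-lesion model is not a trained classifier")
  d <- dim(image$pixels)[1:2]
  cand <- red_candidates(image, vessels, disc, roi, cfg)
  if (is.null(cand$features)) return(lesion_set(list(), d))
  pred <- predict_classifier(model, cand$features[, red_feature_cols])
  a_ma <- scale_area(cfg$red_lesions$a_ma_px, d[2])
  regions <- list(); k <- 0L
  for (j in seq_len(nrow(cand$features))) {
    if (pred[j] != "lesion") next
    k <- k + 1L
    cls <- if (cand$features$area_px[j] <= a_ma) "microaneurysm" else "hemorrhage"
    regions[[k]] <- lesion_region(k, cls, cand$pixels[[j]], d,
                                  features = cand$features[j, ])
  }
  lesion_set(regions, d)
}

#' Detect bright lesions (exudates and cotton-wool spots)
#'
#' Candidates come from a bright top-hat (image minus opening) of the HSL
#' lightness channel; the optic-disc region (with margin) is excluded.
#' Survivors are classified by a fixed two-feature rule: sharp-edged
#' candidates (high boundary gradient) are exudates, fuzzy pale ones
#' cotton-wool spots.
#'
#' @param image Normalised `fundus_image`.
#' @param disc [locate_optic_disc()] output.
#' @param roi [roi_mask()].
#' @param cfg Configuration (uses `cfg$bright_lesions`).
#' @return A [lesion_set()] of exudate/cotton-wool regions.
#' @export
detect_bright_lesions <- function(image, disc, roi, cfg = dr_config()) {
  stopifnot(inherits(image, "fundus_image"))
  bl <- cfg$bright_lesions
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  hsl <- rgb_to_hsl(px)
  l <- hsl$l
  r_se <- max(3L, as.integer(round(disc$radius_px / bl$tophat_radius_div)))
  opened <- EBImage::opening(l, EBImage::makeBrush(2L * r_se + 1L, "disc"))
  tophat <- l - opened
  cand <- tophat > bl$tophat_threshold & l > bl$lightness_min & roi$mask
  cand <- cand & !disc_raster(h, w, disc$center, disc$radius_px * bl$disc_margin_frac)
  lab <- EBImage::bwlabel(cand)
  lab <- relabel_min_area(lab, scale_area(bl$min_area_px, w))
  if (max(lab) == 0) return(lesion_set(list(), c(h, w)))
  feats <- region_features(image, lab)
  idx_by <- split(which(lab > 0), lab[lab > 0])
  regions <- list()
  for (j in seq_len(nrow(feats))) {
    cls <- if (feats$boundary_gradient[j] >= bl$gradient_cut) "exudate" else "cottonwool"
    regions[[j]] <- lesion_region(j, cls, idx_by[[as.character(feats$region_id[j])]],
                                  c(h, w), features = feats[j, ])
  }
  lesion_set(regions, c(h, w))
}

relabel_min_area <- function(lab, min_px) {
  nlab <- max(lab)
  if (nlab == 0) return(lab)
  areas <- tabulate(lab[lab > 0], nlab)
  keep <- areas >= min_px
  map <- integer(nlab); map[keep] <- seq_len(sum(keep))
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Detect photocoagulation (PRP) scars
#'
#' Looks for round, similar-sized bright spots in the peripheral annulus of
#' the field (outside a configurable central radius). The scene is called
#' PRP-positive when at least `n_min` such spots are found and their size
#' coefficient of variation stays below the configured bound.
#'
#' @param image Normalised `fundus_image`.
#' @param roi [roi_mask()].
#' @param disc [locate_optic_disc()] output.
#' @param cfg Configuration (uses `cfg$prp`).
#' @return A [lesion_set()] of `prp_scar` regions with attribute
#'   `prp_positive`.
#' @export
detect_prp_scars <- function(image, roi, disc, cfg = dr_config()) {
  stopifnot(inherits(image, "fundus_image"))
  pc <- cfg$prp
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  hsl <- rgb_to_hsl(px)
  l <- hsl$l
  r_se <- max(3L, as.integer(round(disc$radius_px / 3)))
  opened <- EBImage::opening(l, EBImage::makeBrush(2L * r_se + 1L, "disc"))
  cand <- (l - opened) > 0.08 & l > 0.5 & roi$mask
  idx <- which(roi$mask)
  roi_ctr <- c(mean(((idx - 1L) %% h) + 1L), mean(((idx - 1L) %/% h) + 1L))
  roi_r <- sqrt(roi$area_px / pi)
  central <- disc_raster(h, w, roi_ctr, pc$central_radius_frac * roi_r)
  cand <- cand & !central &
    !disc_raster(h, w, disc$center, disc$radius_px * 1.3)
  lab <- EBImage::bwlabel(cand)
  lab <- relabel_min_area(lab, scale_area(pc$min_area_px, w))
  regions <- list()
  if (max(lab) > 0) {
    feats <- region_features(image, lab)
    idx_by <- split(which(lab > 0), lab[lab > 0])
    k <- 0L
    for (j in seq_len(nrow(feats))) {
      if (feats$circularity[j] < 0.3 || feats$eccentricity[j] > 0.95) next
      if (feats$mean_saturation[j] > pc$saturation_max) next
      k <- k + 1L
      regions[[k]] <- lesion_region(k, "prp_scar",
                                    idx_by[[as.character(feats$region_id[j])]],
                                    c(h, w), features = feats[j, ])
    }
  }
  areas <- vapply(regions, function(r) r$area_px, numeric(1))
  positive <- length(regions) >= pc$n_min &&
    (length(areas) > 1 && sd(areas) / mean(areas) <= pc$size_cv_max)
  out <- lesion_set(regions, c(h, w))
  attr(out, "prp_positive") <- positive
  out
}
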