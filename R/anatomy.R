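# Vessel segmentation, optic-disc localisation, and the quadrant partition
# used by the severity rules.

# Normalised line kernel of given length and orientation (radians).
line_kernel <- function(len, theta) {
  half <- (len - 1) / 2
  k <- matrix(0, len, len)
  for (t in seq(-half, half, by = 0.5)) {
    r <- round(half + 1 + t * sin(theta)); c <- round(half + 1 + t * cos(theta))
    if (r >= 1 && r <= len && c >= 1 && c <= len) k[r, c] <- 1
  }
  k / sum(k)
}

#' Segment the retinal vessel tree
#'
#' Dark-line enhancement on the green channel: at each pixel the response is
#' the largest excess of the local neighbourhood mean over the oriented line
#' mean, taken over `n_orientations` directions and two line scales tied to
#' the expected vessel width. Responses above the intensity threshold inside
#' the ROI form the candidate map; small spurious components are removed.
#' Optionally a per-pixel colour classifier (trained on synthetic labelled
#' scenes) refines the candidates.
#'
#' @param image Normalised `fundus_image`.
#' @param roi [roi_mask()]; must be non-empty.
#' @param model Optional pixel colour classifier (a `fdr_classifier`);
#'   required when `cfg$vessels$refine` is `TRUE`.
#' @param cfg Configuration (uses `cfg$vessels`).
#' @return A `vessel_map`: `mask` (logical raster) and `vessel_fraction`.
#' @export
segment_vessels <- function(image, roi, model = NULL, cfg = dr_config()) {
  stopifnot(inherits(image, "fundus_image"), inherits(roi, "roi_mask"))
  if (roi$area_px == 0) contract_error("empty ROI")
  vc <- cfg$vessels
  if (isTRUE(vc$refine) && is.null(model))
    config_error("vessel refinement enabled but no pixel classifier supplied")
  g <- image$pixels[, , 2]
  h <- nrow(g); w <- ncol(g)
  g <- EBImage::gblur(g, sigma = 1)
  inv <- -g
  best <- matrix(-Inf, h, w)
  dark <- NULL
  for (len in as.integer(round(scale_len(vc$line_lengths, w)))) {
    len <- max(5L, len + (1L - len %% 2L))   # odd
    box <- matrix(1 / len^2, len, len)
    local_mean <- EBImage::filter2(inv, box)
    if (is.null(dark)) dark <- inv - local_mean > 2   # pixel darker than surround
    for (theta in seq(0, pi, length.out = vc$n_orientations + 1)[-(vc$n_orientations + 1)]) {
      resp <- EBImage::filter2(inv, line_kernel(len, theta)) - local_mean
      best <- pmax(best, resp)
    }
  }
  best[!dark] <- -Inf    # suppress the bright halo around lines
  # keep clear of the field boundary: the dark background would otherwise
  # drive the line response in a ring along the ROI rim
  margin <- max(as.integer(round(scale_len(max(vc$line_lengths), w) / 2)) + 2L, 4L)
  inner <- EBImage::erode(roi$mask,
                          EBImage::makeBrush(2L * margin + 1L, "disc")) > 0
  mask <- best > vc$threshold & inner
  # vessels are thin: the line operator also rims large dark blobs
  # (hemorrhages), so excise responses near the core of any thick dark-red
  # region - nothing that wide is a vessel
  hsl <- rgb_to_hsl(image$pixels)
  colorm <- hsl$l < 0.34 & (hsl$h < 40 | hsl$h > 320) & roi$mask
  core <- EBImage::distmap(colorm) > 4.5
  core <- prune_small(core, 20)
  if (any(core)) mask <- mask & !dilate_disc(core, 9)
  mask <- prune_small(mask, scale_area(vc$min_component_px, w))
  # vessels are elongated networks; drop compact blob components (lesions)
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 0) {
    idx_by <- split(which(lab > 0), lab[lab > 0])
    roi_r <- sqrt(roi$area_px / pi)
    for (idx in idx_by) {
      rr <- ((idx - 1L) %% h) + 1L; cc <- ((idx - 1L) %/% h) + 1L
      span <- max(max(rr) - min(rr), max(cc) - min(cc)) + 1
      # compact small components are lesions/noise, not vessel segments;
      # a connected vessel network spans a large part of the field
      if (span < 0.4 * roi_r && span^2 / length(idx) < 6) mask[idx] <- FALSE
    }
  }
  if (isTRUE(vc$refine)) {
    idx <- which(mask)
    if (length(idx)) {
      feats <- pixel_color_features(image, idx)
      keep <- predict_classifier(model, feats) == "vessel"
      mask[idx[!keep]] <- FALSE
    }
  }
  structure(list(mask = mask, vessel_fraction = sum(mask) / roi$area_px),
            class = "vessel_map")
}

pixel_color_features <- function(image, idx) {
  px <- image$pixels
  hsl <- rgb_to_hsl(px)
  data.frame(r = px[, , 1][idx], g = px[, , 2][idx], b = px[, , 3][idx],
             h = hsl$h[idx], s = hsl$s[idx], l = hsl$l[idx])
}

#' Train the vessel pixel colour classifier
#'
#' Fits a linear margin classifier labelling pixels `vessel` vs `other`
#' from RGB + HSL colour features sampled from synthetic labelled scenes.
#'
#' @param n_scenes Number of training scenes.
#' @param seed Training seed (fixed seed gives identical models).
#' @param cfg Configuration.
#' @return A `fdr_classifier`.
#' @export
train_vessel_classifier <- function(n_scenes = 3L, seed = 90210L,
                                    cfg = dr_config()) {
  feats <- list(); labels <- character()
  for (i in seq_len(n_scenes)) {
    sc <- render_scene(scene_spec(size = cfg$synthetic$size,
                                  seed = split_seed(seed, i)))
    vm <- sc$truth$masks$vessel; field <- sc$truth$masks$field
    vi <- which(vm); oi <- which(field & !vm)
    take <- with_seed(split_seed(seed, 100 + i), {
      list(v = sample(vi, min(1500, length(vi))),
           o = sample(oi, min(1500, length(oi))))
    })
    feats[[i]] <- rbind(pixel_color_features(sc$image, take$v),
                        pixel_color_features(sc$image, take$o))
    labels <- c(labels, rep(c("vessel", "other"), c(length(take$v), length(take$o))))
  }
  d <- do.call(rbind, feats); d$label <- labels
  train_candidate_classifier(d, seed = seed)
}

#' Locate the optic disc
#'
#' Scores bright candidate blobs by a weighted sum of three normalised
#' terms: local brightness percentile, circularity of the blob, and
#' convergence of the vessel tree toward the candidate (relative vessel
#' density in a surrounding annulus). The best candidate is returned with
#' confidence equal to its normalised score; ties break toward the brighter
#' candidate. A low-confidence result is returned flagged (it feeds the
#' quality gate), never raised as an error.
#'
#' @param image Normalised `fundus_image`.
#' @param vessels [segment_vessels()] output for the same image.
#' @param roi [roi_mask()].
#' @param cfg Configuration (uses `cfg$disc`).
#' @return An `optic_disc`: `center` (row, col), `radius_px`, `confidence`,
#'   `low_confidence` flag.
#' @export
locate_optic_disc <- function(image, vessels, roi, cfg = dr_config()) {
  stopifnot(inherits(image, "fundus_image"), inherits(roi, "roi_mask"))
  dc <- cfg$disc
  L <- luminance(image$pixels)
  h <- nrow(L); w <- ncol(L)
  roi_r <- sqrt(roi$area_px / pi)
  lv <- L[roi$mask]
  bright <- L >= quantile(lv, dc$brightness_quantile) & roi$mask
  lab <- EBImage::bwlabel(bright)
  nlab <- max(lab)
  fallback <- function() {
    idx <- which(roi$mask)
    ctr <- c(mean(((idx - 1L) %% h) + 1L), mean(((idx - 1L) %/% h) + 1L))
    structure(list(center = ctr, radius_px = 0.13 * roi_r, confidence = 0,
                   low_confidence = TRUE), class = "optic_disc")
  }
  if (nlab == 0) return(fallback())
  areas <- tabulate(lab[lab > 0], nlab)
  # a plausible disc blob cannot be much smaller than the lower radius bound
  min_area <- 0.5 * pi * (dc$radius_frac_bounds[1] * roi_r)^2
  cand <- order(areas, decreasing = TRUE)
  cand <- cand[areas[cand] >= min_area]
  if (length(cand) == 0) return(fallback())
  cand <- cand[seq_len(min(dc$max_candidates, length(cand)))]
  medL <- median(lv); hiL <- quantile(lv, 0.995)
  vmask <- vessels$mask
  vdens_global <- max(sum(vmask) / roi$area_px, 1e-6)
  score_terms <- vapply(cand, function(ci) {
    idx <- which(lab == ci)
    rr <- ((idx - 1L) %% h) + 1L; cc <- ((idx - 1L) %/% h) + 1L
    ctr <- c(mean(rr), mean(cc))
    re <- sqrt(length(idx) / pi)
    # absolute brightness contrast over the field median: on normalised
    # images a real disc is ~100 gray levels brighter than the retina, so a
    # fixed 60-level scale saturates for discs but stays low for noise
    # blobs in discless scenes, whose relative range is compressed
    brightness <- max(0, min(1, (mean(L[idx]) - medL) / 60))
    # circularity via template overlap, discounting vessel pixels: vessels
    # crossing a real disc carve its thresholded blob, and those missing
    # pixels should not count against roundness
    template <- disc_raster(h, w, ctr, re)
    m <- matrix(FALSE, h, w); m[idx] <- TRUE
    denom <- (m | template) & !vmask
    circ <- if (sum(denom) > 0) sum(m & template & denom) / sum(denom) else 0
    # convergence: vessel density excess (over the field average) in the
    # surrounding annulus - vessels radiate from the disc
    ann <- disc_raster(h, w, ctr, 2.5 * re) & !disc_raster(h, w, ctr, re) & roi$mask
    conv <- if (sum(ann) > 0)
      max(0, min(1, ((sum(vmask & ann) / sum(ann)) / vdens_global - 1) / 2)) else 0
    size <- max(0, 1 - abs(re - dc$expected_radius_frac * roi_r) / (0.10 * roi_r))
    c(brightness, circ, conv, ctr, re, size)
  }, numeric(7))
  scores <- dc$weight_brightness * score_terms[1, ] +
    dc$weight_circularity * score_terms[2, ] +
    dc$weight_convergence * score_terms[3, ] +
    dc$weight_size * score_terms[7, ]
  best <- which(scores == max(scores))
  if (length(best) > 1) best <- best[which.max(score_terms[1, best])]
  ctr <- score_terms[4:5, best]
  re <- score_terms[6, best]
  re <- min(max(re, dc$radius_frac_bounds[1] * roi_r),
            dc$radius_frac_bounds[2] * roi_r)
  conf <- scores[best]
  structure(list(center = ctr, radius_px = re, confidence = conf,
                 low_confidence = conf < dc$confidence_gate),
            class = "optic_disc")
}

#' Partition the ROI into four quadrants
#'
#' Splits the field by horizontal and vertical lines through the estimated
#' posterior-pole centre: the disc centre offset toward the macula
#' (temporal side) by a configurable fraction of the ROI-equivalent radius.
#' Quadrants are numbered 1 = upper-temporal-side clockwise via the usual
#' raster convention: 1 upper-right, 2 upper-left, 3 lower-left,
#' 4 lower-right.
#'
#' @param roi [roi_mask()].
#' @param disc [locate_optic_disc()] output; its centre must lie inside the
#'   ROI.
#' @param cfg Configuration (uses `cfg$quadrants`).
#' @return A `quadrant_map`: integer raster (0 outside ROI, 1-4 inside) and
#'   the partition `center`.
#' @export
partition_quadrants <- function(roi, disc, cfg = dr_config()) {
  stopifnot(inherits(roi, "roi_mask"), inherits(disc, "optic_disc"))
  h <- nrow(roi$mask); w <- ncol(roi$mask)
  dctr <- round(disc$center)
  if (dctr[1] < 1 || dctr[1] > h || dctr[2] < 1 || dctr[2] > w ||
      !roi$mask[dctr[1], dctr[2]])
    contract_error("disc centre lies outside the ROI")
  idx <- which(roi$mask)
  roi_ctr <- c(mean(((idx - 1L) %% h) + 1L), mean(((idx - 1L) %/% h) + 1L))
  roi_r <- sqrt(roi$area_px / pi)
  # macula is temporal: from the disc toward (and past) the ROI centre
  dir <- sign(roi_ctr[2] - disc$center[2]); if (dir == 0) dir <- 1
  center <- c(disc$center[1],
              disc$center[2] + dir * cfg$quadrants$macula_offset_frac * roi_r)
  ri <- row_index(h, w); ci <- col_index(h, w)
  q <- matrix(0L, h, w)
  upper <- ri <= center[1]; right <- ci > center[2]
  q[upper & right] <- 1L; q[upper & !right] <- 2L
  q[!upper & !right] <- 3L; q[!upper & right] <- 4L
  q[!roi$mask] <- 0L
  structure(list(labels = q, center = center), class = "quadrant_map")
}
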