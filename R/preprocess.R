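# Field-of-view extraction, denoising, and normalisation against a standard
# reference image.

#' Establish the region of interest (camera field of view)
#'
#' Extracts the circular retinal field from the black photograph background
#' by adaptive luminance thresholding (local mean minus an offset) combined
#' with a near-black floor, keeping the largest connected bright component,
#' hole-filled. The result is checked against an ideal disc template at the
#' component centroid; a poorly circular component is replaced by that
#' template. When the frame has no near-black border the whole frame minus
#' a one-pixel margin is returned.
#'
#' @param image A [fundus_image()].
#' @param cfg Configuration (uses `cfg$roi`).
#' @return A [roi_mask()].
#' @export
establish_roi <- function(image, cfg = dr_config()) {
  stopifnot(inherits(image, "fundus_image"))
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  L <- luminance(px)
  rc <- cfg$roi

  border <- c(L[1, ], L[h, ], L[, 1], L[, w])
  if (mean(border < rc$border_dark_level) < 0.5) {
    m <- matrix(FALSE, h, w)
    m[2:(h - 1), 2:(w - 1)] <- TRUE
    return(roi_mask(m))
  }

  win <- max(8L, as.integer(round(rc$adaptive_window_frac * min(h, w))))
  adaptive <- EBImage::thresh(L / 255, w = win, h = win,
                              offset = -rc$adaptive_offset / 255) > 0
  bright <- adaptive & (L > rc$border_dark_level)
  comp <- largest_component(bright)
  area <- sum(comp)
  if (area < rc$min_field_frac * h * w)
    fdr_error("no field-of-view component covering the configured minimum frame fraction",
              "fdr_no_field")
  comp <- EBImage::fillHull(comp) > 0

  # circularity check against a disc template at the centroid
  idx <- which(comp)
  cr <- mean(((idx - 1L) %% h) + 1L); cc <- mean(((idx - 1L) %/% h) + 1L)
  re <- sqrt(sum(comp) / pi)
  template <- disc_raster(h, w, c(cr, cc), re)
  jaccard <- sum(comp & template) / sum(comp | template)
  if (jaccard < rc$circularity_min) comp <- template
  roi_mask(comp)
}

#' Median denoising
#'
#' Per-channel median smoothing with the given radius; radius 0 is the
#' identity. Removes impulse noise without blurring vessel edges.
#'
#' @param image A `fundus_image`.
#' @param radius Median filter radius in pixels (>= 0).
#' @return The smoothed `fundus_image`.
#' @export
denoise <- function(image, radius = 2L) {
  stopifnot(inherits(image, "fundus_image"))
  if (radius < 0) contract_error("denoise radius must be >= 0")
  if (radius == 0) return(image)
  px <- image$pixels
  for (ch in 1:3) {
    px[, , ch] <- if (radius == 1) median3x3(px[, , ch]) else
      round(255 * EBImage::medianFilter(px[, , ch] / 255,
                                        size = as.integer(radius)))
  }
  fundus_image(clip255(px), image$image_id, image$source_path)
}

# Vectorised 3x3 median (replicated borders): a sorting network over the
# nine shifted copies, much faster than a generic median filter.
median3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- m[c(1, 1:h, h), c(1, 1:w, w)]
  sh <- function(dr, dc) pad[(1 + dr):(h + dr), (1 + dc):(w + dc)]
  v <- list(sh(0, 0), sh(0, 1), sh(0, 2), sh(1, 0), sh(1, 1), sh(1, 2),
            sh(2, 0), sh(2, 1), sh(2, 2))
  swap <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  # 19-exchange median-of-9 network (Paeth, Graphics Gems)
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 2); swap(4, 5); swap(7, 8)
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 4); swap(6, 9); swap(5, 8)
  swap(4, 7); swap(2, 5); swap(3, 6)
  swap(5, 8); swap(5, 3); swap(7, 5); swap(5, 3)
  v[[5]]
}

#' Normalisation profile of a reference image
#'
#' Summarises the lightness/saturation statistics of a standard reference
#' image over its field of view, in the HSL decomposition: target lightness
#' mean and SD (gray levels, 0-255), target saturation mean (0-1), and the
#' 1st/99th luminance percentiles as the target gray range.
#'
#' @param reference A `fundus_image`.
#' @param roi Its [roi_mask()]; must be non-empty.
#' @return A `normalization_profile` list.
#' @export
make_profile <- function(reference, roi) {
  stopifnot(inherits(reference, "fundus_image"), inherits(roi, "roi_mask"))
  if (roi$area_px == 0) contract_error("empty ROI")
  hsl <- rgb_to_hsl(reference$pixels)
  l <- hsl$l[roi$mask] * 255
  s <- hsl$s[roi$mask]
  lum <- sort(luminance(reference$pixels)[roi$mask])
  pct <- function(p) lum[max(1L, ceiling(p * length(lum)))]
  structure(list(target_lightness_mean = mean(l),
                 target_lightness_sd = sd(l),
                 target_saturation_mean = mean(s),
                 target_gray_range = c(pct(0.01), pct(0.99))),
            class = "normalization_profile")
}

#' Normalise an image against a reference profile
#'
#' Within the field of view, lightness is linearly rescaled so its mean and
#' SD match the profile, and saturation is matched multiplicatively on its
#' mean; hue is preserved. Output is clipped to `[0, 255]`; pixels outside
#' the ROI are set to black. A zero input lightness SD falls back to a mean
#' shift with a warning.
#'
#' @param image A `fundus_image`.
#' @param roi Its [roi_mask()].
#' @param profile A [make_profile()] result.
#' @return The normalised `fundus_image`.
#' @export
normalize_image <- function(image, roi, profile) {
  stopifnot(inherits(image, "fundus_image"), inherits(roi, "roi_mask"),
            inherits(profile, "normalization_profile"))
  if (roi$area_px == 0) contract_error("empty ROI")
  hsl <- rgb_to_hsl(image$pixels)
  m <- roi$mask
  l255 <- hsl$l * 255
  mu <- mean(l255[m]); sdv <- sd(l255[m])
  if (sdv == 0) {
    warning("zero lightness SD in ROI; applying mean shift only")
    lnew <- l255 + (profile$target_lightness_mean - mu)
  } else {
    lnew <- (l255 - mu) / sdv * profile$target_lightness_sd +
      profile$target_lightness_mean
  }
  smu <- mean(hsl$s[m])
  snew <- if (smu > 0) hsl$s * (profile$target_saturation_mean / smu) else hsl$s
  out <- hsl_to_rgb(hsl$h, pmin(1, pmax(0, snew)), pmin(1, pmax(0, lnew / 255)))
  for (ch in 1:3) { p <- out[, , ch]; p[!m] <- 0; out[, , ch] <- p }
  fundus_image(round(out), image$image_id, image$source_path)
}

#' Serialise / read a normalisation profile as JSON
#'
#' @param profile A `normalization_profile`.
#' @param path JSON file path.
#' @return `path` ([write_profile()]) or the profile ([read_profile()]).
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "normalization_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$target_gray_range <- unlist(p$target_gray_range)
  structure(p, class = "normalization_profile")
}

# Package-cached standard reference scene and its profile. The reference
# "standard image" is a generated clean synthetic scene; users may supply
# their own profile to normalize_image().
.fdr_cache <- new.env(parent = emptyenv())

#' The shipped standard reference profile
#'
#' Profile of a generated clean reference scene (fixed seed), cached per
#' session. Used by [grade_image()] when no user profile is supplied.
#'
#' @param cfg Configuration.
#' @return A `normalization_profile`.
#' @export
standard_profile <- function(cfg = dr_config()) {
  key <- paste0("profile_", paste(cfg$synthetic$size, collapse = "x"))
  if (!is.null(.fdr_cache[[key]])) return(.fdr_cache[[key]])
  sc <- render_scene(scene_spec(size = cfg$synthetic$size, seed = 424242L))
  roi <- roi_mask(sc$truth$masks$field)
  prof <- make_profile(sc$image, roi)
  .fdr_cache[[key]] <- prof
  prof
}
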