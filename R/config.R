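#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline live in a single nested list. The
#' defaults are complete: every entry point is runnable with `dr_config()`
#' and no user file. A user YAML file may override any subset of keys;
#' unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' Key groups: `roi` (field-of-view extraction), `preprocess` (denoise radius
#' and normalisation), `vessels`, `disc`, `quadrants`, `red_lesions`,
#' `bright_lesions`, `prp`, `quality` (gate thresholds), `grading` (stage
#' rule thresholds), `overlay`, and `synthetic` (generator defaults).
#'
#' @param path Optional path to a YAML file of overrides.
#' @param overrides Optional named list of overrides (applied after the file).
#' @return A nested list with class `"dr_config"`.
#' @examples
#' cfg <- dr_config()
#' cfg$grading$hemorrhages_per_quadrant
#' @export
dr_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) io_error(paste0("config file not found: ", path))
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, "")
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, "")
  structure(cfg, class = "dr_config")
}

default_config <- function() {
  list(
    seed = 20160401L,
    laterality = "OD",
    roi = list(
      adaptive_window_frac = 0.125,  # window = frac * min(H, W)
      adaptive_offset = 8,           # gray levels below local mean
      min_field_frac = 0.20,
      border_dark_level = 25,        # near-black border detection
      circularity_min = 0.55
    ),
    preprocess = list(
      denoise_radius = 1L,
      colorspace = "hsl"
    ),
    vessels = list(
      n_orientations = 12L,
      line_lengths = c(9L, 17L),     # px at 512 scale, scaled by width/512
      threshold = 6.0,               # gray levels of line-vs-surround contrast
      min_component_px = 60L,
      refine = FALSE                 # per-pixel colour classifier refinement
    ),
    disc = list(
      brightness_quantile = 0.97,
      max_candidates = 5L,
      weight_brightness = 0.30,
      weight_circularity = 0.20,
      weight_convergence = 0.25,
      weight_size = 0.25,
      expected_radius_frac = 0.13,
      confidence_gate = 0.50,
      radius_frac_bounds = c(0.05, 0.25)
    ),
    quadrants = list(
      macula_offset_frac = 0.35      # posterior-pole shift, fraction of ROI radius
    ),
    red_lesions = list(
      a_ma_px = 30L,                 # MA/hemorrhage area boundary at 512 scale
      tophat_radius_div = 15,        # SE radius = disc_radius / this
      tophat_threshold = 8,          # gray levels
      color_lightness_max = 0.32,    # large-lesion colour rule (HSL l)
      vessel_overlap_max = 0.20,
      min_area_px = 4L,
      max_area_frac = 0.04           # of ROI, guards against giant artefacts
    ),
    bright_lesions = list(
      tophat_radius_div = 1.4,       # SE radius = disc_radius / this; must
                                     # exceed the largest bright lesion radius
      tophat_threshold = 0.10,       # lightness units in [0, 1]
      lightness_min = 0.55,          # absolute floor: bright lesions are bright
      min_area_px = 6L,
      gradient_cut = 25,             # boundary sharpness: exudate vs cotton-wool
      disc_margin_frac = 1.3         # disc exclusion = radius * this
    ),
    prp = list(
      central_radius_frac = 0.45,    # annulus starts here (fraction of ROI radius)
      n_min = 10L,
      size_cv_max = 0.6,
      min_area_px = 20L,
      saturation_max = 0.65          # scars are pale; exudates stay yellow

    ),
    # quality thresholds: calibrated once on the seeded degradation suite
    # (scripts/calibrate_quality.R) and frozen here
    quality = list(
      fuzzy_min = 4.0,               # high-frequency energy floor
      dark_level = 30,               # luminance counted as dark
      dark_frac_max = 0.15,
      saturated_level = 250,
      saturated_frac_max = 0.25,
      eyelash_max = 0.002,           # boundary-crossing dark intrusion score
      decenter_frac_max = 0.13       # ROI centroid offset, frac of ROI radius
    ),
    grading = list(
      hemorrhages_per_quadrant = 20L,  # 4-2-1-style severe rule
      a_severe_px = 8000L,             # red-lesion area fallback at 512 scale
      pdr_mode = FALSE,
      a_pdr_px = 20000L,
      collapse_pdr_to_dr3 = FALSE
    ),
    overlay = list(
      hemorrhage_rgb = c(0L, 255L, 0L),
      exudate_rgb = c(0L, 0L, 255L),
      tie = "green"
    ),
    quantify = list(
      include_microaneurysms = TRUE
    ),
    eval = list(
      disqualified_label = "",
      dr_labels = character(),
      positive_labels = character()
    ),
    synthetic = list(
      size = c(512L, 512L),
      field_radius_frac = 0.46
    )
  )
}

merge_config <- function(base, user, prefix) {
  if (!is.list(user)) config_error(paste0("config section must be a mapping: ", prefix))
  nm <- names(user)
  if (is.null(nm) || any(nm == "")) config_error(paste0("unnamed config entry under '", prefix, "'"))
  for (k in nm) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (!k %in% names(base)) config_error(paste0("unknown config key: ", full))
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Write a configuration to YAML
#'
#' @param cfg A `dr_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Resolution scaling: pixel thresholds are quoted at 512 px width and scale
# with area for area-valued thresholds, linearly for length-valued ones.
scale_area <- function(px, width) as.numeric(px) * (width / 512)^2
scale_len  <- function(px, width) as.numeric(px) * (width / 512)
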