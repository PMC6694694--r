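#' Fundus image container
#'
#' An 8-bit RGB raster with identity metadata. Pixels are stored as an
#' `H x W x 3` numeric array in `[0, 255]`, indexed `[row, col, channel]`
#' with row 1 at the top and channels in RGB order.
#'
#' @param pixels `H x W x 3` array in `[0, 255]`; `H, W >= 128`.
#' @param image_id Identifier string.
#' @param source_path Originating file path, or `""`.
#' @return A `fundus_image` object.
#' @export
fundus_image <- function(pixels, image_id = "", source_path = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    contract_error("pixels must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 128 || d[2] < 128)
    size_error(sprintf("image %dx%d below the 128x128 minimum", d[1], d[2]))
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255)
    contract_error("pixel samples must lie in [0, 255]")
  structure(list(pixels = pixels, image_id = as.character(image_id),
                 source_path = as.character(source_path)),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image '%s' %dx%d RGB>\n", x$image_id, d[1], d[2]))
  invisible(x)
}

#' @export
dim.fundus_image <- function(x) dim(x$pixels)

#' Field-of-view mask
#'
#' Binary mask of the circular camera field on the black photograph
#' background, with its pixel count.
#'
#' @param mask Logical `H x W` matrix.
#' @return A `roi_mask` object with fields `mask` and `area_px`.
#' @export
roi_mask <- function(mask) {
  if (!is.matrix(mask)) contract_error("ROI mask must be a matrix")
  mask <- mask > 0
  structure(list(mask = mask, area_px = sum(mask)), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %dx%d, %d px (%.1f%% of frame)>\n",
              nrow(x$mask), ncol(x$mask), x$area_px,
              100 * x$area_px / length(x$mask)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Image file I/O

#' Read a fundus photograph
#'
#' Reads PNG, JPEG or TIFF into a [fundus_image()]. Grayscale inputs are
#' replicated to three channels with a warning.
#'
#' @param path Path to the image file.
#' @param image_id Identifier; defaults to the file name without extension.
#' @return A `fundus_image`.
#' @export
read_image <- function(path, image_id = NULL) {
  if (!file.exists(path)) io_error(paste0("no such image file: ", path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) io_error(paste0("unreadable image '", path, "': ",
                                                      conditionMessage(e))))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) {
    warning("grayscale input replicated to 3 channels: ", path)
    a <- array(rep(a, 3), c(dim(a), 3))
  }
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  pixels <- aperm(a, c(2, 1, 3)) * 255
  pixels <- round(pixels)
  d <- dim(pixels)
  if (d[1] < 128 || d[2] < 128)
    size_error(sprintf("image %dx%d below the 128x128 minimum: %s", d[1], d[2], path))
  fundus_image(pixels, image_id %||% sub("\\.[^.]*$", "", basename(path)), path)
}

#' Write a fundus image to disk
#'
#' PNG output is lossless; JPEG/TIFF are supported for interchange.
#'
#' @param image A `fundus_image`.
#' @param path Output path; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "fundus_image"))
  a <- aperm(image$pixels, c(2, 1, 3)) / 255
  ok <- tryCatch({
    EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) io_error(paste0("could not write image: ", path))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Lesion overlay rendering

#' Render the lesion overlay
#'
#' Marks red-lesion pixels (microaneurysm + hemorrhage family) in saturated
#' green and bright-lesion pixels (exudate + cotton-wool family) in saturated
#' blue on a copy of the photograph, so marked areas can be recounted
#' bit-exactly from the rendered file. Pixels belonging to both families are
#' painted by the configured tie colour (green by default).
#'
#' @param image A `fundus_image`.
#' @param lesions A [lesion_set()] whose rasters match the image shape.
#' @param cfg Configuration list (uses `cfg$overlay`).
#' @return A `fundus_image` with lesions painted.
#' @export
render_overlay <- function(image, lesions, cfg = dr_config()) {
  stopifnot(inherits(image, "fundus_image"), inherits(lesions, "lesion_set"))
  d <- dim(image$pixels)
  if (!identical(dim(lesions$rasters$hemorrhage), d[1:2]))
    contract_error("lesion rasters do not match the image shape")
  red  <- lesions$rasters$microaneurysm | lesions$rasters$hemorrhage
  brt  <- lesions$rasters$exudate | lesions$rasters$cottonwool
  both <- red & brt
  if (identical(cfg$overlay$tie, "green")) brt[both] <- FALSE else red[both] <- FALSE
  px <- image$pixels
  hrgb <- cfg$overlay$hemorrhage_rgb; ergb <- cfg$overlay$exudate_rgb
  for (ch in 1:3) {
    pl <- px[, , ch]
    pl[red] <- hrgb[ch]; pl[brt] <- ergb[ch]
    px[, , ch] <- pl
  }
  fundus_image(px, image$image_id, image$source_path)
}

#' Write the lesion overlay to an image file
#'
#' @inheritParams render_overlay
#' @param path Output path (PNG recommended: counts are then exact).
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, lesions, path, cfg = dr_config()) {
  write_image(render_overlay(image, lesions, cfg), path)
}

#' Write a binary mask as a PNG image
#'
#' White where the mask is true, black elsewhere. Used to export vessel,
#' ROI and per-class lesion masks.
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' Export a lesion set as per-class masks plus a region table
#'
#' Writes one PNG mask per lesion class that has regions, and a JSON table
#' of (region_id, class, area_px, centroid).
#'
#' @param lesions A [lesion_set()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The region table data frame, invisibly.
#' @export
write_lesion_set <- function(lesions, dir, prefix = "lesions") {
  stopifnot(inherits(lesions, "lesion_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(lesions$rasters)) {
    if (any(lesions$rasters[[cl]]))
      write_mask(lesions$rasters[[cl]],
                 file.path(dir, paste0(prefix, "_", cl, ".png")))
  }
  tab <- do.call(rbind, lapply(lesions$regions, function(r)
    data.frame(region_id = r$region_id, class = r$class, area_px = r$area_px,
               centroid_row = r$centroid[1], centroid_col = r$centroid[2])))
  if (is.null(tab)) tab <- data.frame(region_id = integer(),
                                      class = character(),
                                      area_px = integer(),
                                      centroid_row = numeric(),
                                      centroid_col = numeric())
  jsonlite::write_json(tab, file.path(dir, paste0(prefix, "_regions.json")),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(tab)
}

# ---------------------------------------------------------------------------
# Grading records and report I/O

#' Per-image grading record
#'
#' Bundles the stage decision with the quality gate outcome and the six
#' quantification indices for one photograph. `stage` is `"UNGRADABLE"`
#' exactly when the quality gate failed.
#'
#' @param image_id Identifier.
#' @param stage One of `r paste(dr_stages(), collapse = ", ")`.
#' @param quality A [quality_report] (list) or `NULL`.
#' @param quant A [quant_report] (list) or `NULL`.
#' @return A `grading_record`.
#' @export
grading_record <- function(image_id, stage, quality = NULL, quant = NULL) {
  stage <- match.arg(stage, dr_stages())
  if (!is.null(quality)) {
    if (xor(identical(stage, "UNGRADABLE"), !quality$qualified))
      contract_error("stage is UNGRADABLE iff the image is disqualified")
  }
  structure(list(image_id = as.character(image_id), stage = stage,
                 quality = quality, quant = quant),
            class = "grading_record")
}

#' DR stage labels
#'
#' The ordered stage vocabulary of the grader: no DR, mild/moderate/severe
#' non-proliferative DR, proliferative DR, post-photocoagulation, other
#' findings, and ungradable image quality.
#' @return Character vector of stage names.
#' @export
dr_stages <- function() {
  c("DR0", "DR1", "DR2", "DR3", "PDR", "PRP", "OTHER", "UNGRADABLE")
}

report_columns <- c("image_id", "stage", "qualified", "flags",
                    "hemorrhage_total_area_px", "hemorrhage_count",
                    "hemorrhage_max_area_px", "exudate_total_area_px",
                    "exudate_count", "exudate_max_area_px", "status")

record_row <- function(rec) {
  q <- rec$quant %||% list(hemorrhage_total_area_px = NA_integer_,
                           hemorrhage_count = NA_integer_,
                           hemorrhage_max_area_px = NA_integer_,
                           exudate_total_area_px = NA_integer_,
                           exudate_count = NA_integer_,
                           exudate_max_area_px = NA_integer_)
  data.frame(image_id = rec$image_id, stage = rec$stage,
             qualified = if (is.null(rec$quality)) NA else rec$quality$qualified,
             flags = if (is.null(rec$quality)) "" else
               paste(rec$quality$flags, collapse = ";"),
             hemorrhage_total_area_px = q$hemorrhage_total_area_px,
             hemorrhage_count = q$hemorrhage_count,
             hemorrhage_max_area_px = q$hemorrhage_max_area_px,
             exudate_total_area_px = q$exudate_total_area_px,
             exudate_count = q$exudate_count,
             exudate_max_area_px = q$exudate_max_area_px,
             status = rec$status %||% "ok",
             stringsAsFactors = FALSE)
}

#' Write a grading report
#'
#' One row (CSV) or object (JSON) per image: identifier, stage (serialised
#' as its literal name, e.g. `"DR2"`), quality-gate outcome and flags, and
#' the six lesion-quantification indices. The CSV header is fixed:
#' `image_id, stage, qualified, flags, hemorrhage_total_area_px,
#' hemorrhage_count, hemorrhage_max_area_px, exudate_total_area_px,
#' exudate_count, exudate_max_area_px`.
#'
#' @param records Non-empty list of [grading_record()] objects.
#' @param path Output file path.
#' @param format `"csv"` (RFC 4180, UTF-8) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (length(records) == 0) contract_error("empty record list")
  df <- do.call(rbind, lapply(records, record_row))
  ok <- tryCatch({
    if (format == "csv") {
      write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
    } else {
      jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null")
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) io_error(paste0("could not write report: ", path))
  invisible(path)
}

#' Read a grading report back into records
#'
#' Inverse of [write_report()] for the stage/quality/quantification fields.
#'
#' @param path Report file path.
#' @param format `"csv"` or `"json"`.
#' @return List of `grading_record` objects.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) io_error(paste0("no such report: ", path))
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, colClasses = c(flags = "character"))
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  if (!"flags" %in% names(df)) df$flags <- ""
  df$flags[is.na(df$flags)] <- ""
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    qual <- if (is.na(r$qualified)) NULL else {
      flags <- if (nzchar(r$flags)) strsplit(r$flags, ";")[[1]] else character()
      list(flags = flags, qualified = as.logical(r$qualified))
    }
    quant <- if (is.na(r$hemorrhage_total_area_px)) NULL else
      quant_report(r$image_id,
                   hemorrhage_total_area_px = r$hemorrhage_total_area_px,
                   hemorrhage_count = r$hemorrhage_count,
                   hemorrhage_max_area_px = r$hemorrhage_max_area_px,
                   exudate_total_area_px = r$exudate_total_area_px,
                   exudate_count = r$exudate_count,
                   exudate_max_area_px = r$exudate_max_area_px)
    grading_record(r$image_id, r$stage, qual, quant)
  })
}
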