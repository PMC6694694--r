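# Internal helpers shared across modules.

# Contract / configuration / IO error constructors: distinct condition classes
# so callers and tests can discriminate failure modes.
fdr_error <- function(msg, class) {
  stop(structure(class = c(class, "fdr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
contract_error <- function(msg) fdr_error(msg, "fdr_contract_error")
config_error   <- function(msg) fdr_error(msg, "fdr_config_error")
io_error       <- function(msg) fdr_error(msg, "fdr_io_error")
size_error     <- function(msg) fdr_error(msg, "fdr_size_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Luminance (ITU-R BT.601) of an HxWx3 raster in [0, 255].
luminance <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

# Disc-shaped logical kernel of radius r (odd-sided matrix).
disc_kernel <- function(r) {
  r <- max(1L, as.integer(round(r)))
  d <- 2L * r + 1L
  i <- matrix(rep(-r:r, d), d, d)
  k <- (i^2 + t(i)^2) <= r^2
  storage.mode(k) <- "double"
  k
}

# Row/col index matrices for an H x W frame.
row_index <- function(h, w) matrix(rep(seq_len(h), w), h, w)
col_index <- function(h, w) matrix(rep(seq_len(w), each = h), h, w)

# Binary raster of a filled disc.
disc_raster <- function(h, w, center, radius) {
  (row_index(h, w) - center[1])^2 + (col_index(h, w) - center[2])^2 <= radius^2
}

# Largest connected component of a logical matrix (8-connectivity via EBImage).
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(mask & FALSE)
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

# Remove connected components smaller than min_px.
prune_small <- function(mask, min_px) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Binary dilation with a disc structuring element.
dilate_disc <- function(mask, r) {
  if (r < 1) return(mask)
  EBImage::dilate(mask, EBImage::makeBrush(2L * as.integer(round(r)) + 1L, "disc")) > 0
}

clip255 <- function(x) pmin(pmax(x, 0), 255)  # x first: pmin/pmax keep its dims

# Deterministic child seed derivation: one root seed fans out to independent
# per-purpose streams while staying inside 32-bit integer range.
split_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

# Evaluate expr with a temporarily-set RNG seed, restoring prior RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
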