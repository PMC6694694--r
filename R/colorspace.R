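# RGB <-> HSL conversion, vectorised over whole rasters.
#
# All colour handling in the package is defined from 8-bit RGB. HSL is the
# hue-preserving decomposition used for normalisation and lesion colour rules:
# lightness L = (max + min)/2, saturation relative to L, hue in degrees.

# pixels: H x W x 3 in [0, 255]. Returns list of H x W matrices h (degrees,
# [0, 360)), s in [0, 1], l in [0, 1].
rgb_to_hsl <- function(pixels) {
  r <- pixels[, , 1] / 255; g <- pixels[, , 2] / 255; b <- pixels[, , 3] / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- ifelse(d == 0, 0, d / (1 - abs(2 * l - 1)))
  s[!is.finite(s)] <- 0
  h <- matrix(0, nrow(r), ncol(r))
  im <- d > 0 & mx == r
  h[im] <- ((g[im] - b[im]) / d[im]) %% 6
  im <- d > 0 & mx == g & !(mx == r)
  h[im] <- (b[im] - r[im]) / d[im] + 2
  im <- d > 0 & mx == b & !(mx == r) & !(mx == g)
  h[im] <- (r[im] - g[im]) / d[im] + 4
  list(h = h * 60, s = pmin(1, pmax(0, s)), l = l)
}

# Inverse transform; returns H x W x 3 in [0, 255] (double, clipped).
hsl_to_rgb <- function(h, s, l) {
  s <- pmin(1, pmax(0, s)); l <- pmin(1, pmax(0, l))
  c1 <- (1 - abs(2 * l - 1)) * s
  hp <- (h %% 360) / 60
  x <- c1 * (1 - abs(hp %% 2 - 1))
  m <- l - c1 / 2
  r <- g <- b <- matrix(0, nrow(h), ncol(h))
  seg <- floor(hp)
  set <- function(idx, rv, gv, bv) {
    r[idx] <<- rv[idx]; g[idx] <<- gv[idx]; b[idx] <<- bv[idx]
  }
  zero <- matrix(0, nrow(h), ncol(h))
  set(seg == 0, c1, x, zero); set(seg == 1, x, c1, zero)
  set(seg == 2, zero, c1, x); set(seg == 3, zero, x, c1)
  set(seg == 4, x, zero, c1); set(seg >= 5, c1, zero, x)
  out <- array(0, c(nrow(h), ncol(h), 3))
  out[, , 1] <- (r + m) * 255; out[, , 2] <- (g + m) * 255; out[, , 3] <- (b + m) * 255
  clip255(out)
}
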