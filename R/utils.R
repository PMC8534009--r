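## Internal helpers shared across stages.

# Deterministic per-stage seed derived from one global seed. Keeps results
# below .Machine$integer.max so set.seed() always accepts them.
stageSeed <- function(globalSeed, stageIndex) {
  s <- (as.double(globalSeed) %% 2147483647) * 1009 + stageIndex * 9973
  as.integer(s %% 2147483647)
}

# Bilinear interpolation of a matrix img[y, x] at fractional pixel-center
# coordinates (x, y), 1-based. Points outside the image return NA.
interp2 <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nx & y >= 1 & y <= ny
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  v <- img[cbind(y0, x0)]         * (1 - fx) * (1 - fy) +
       img[cbind(y0, x0 + 1)]     * fx       * (1 - fy) +
       img[cbind(y0 + 1, x0)]     * (1 - fx) * fy +
       img[cbind(y0 + 1, x0 + 1)] * fx       * fy
  out[ok] <- v
  out
}

# Distance from points (px, py) to the segment (x0,y0)-(x1,y1).
pointSegmentDistance <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x0)^2 + (py - y0)^2))
  t <- ((px - x0) * dx + (py - y0) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - x0 - t * dx)^2 + (py - y0 - t * dy)^2)
}

# Minimum distance from every pixel center of an ny x nx image to a set of
# segments (data.frame x0, y0, x1, y1 in pixel units).
segmentDistanceMap <- function(ny, nx, segments) {
  px <- rep(seq_len(nx), each = ny)
  py <- rep(seq_len(ny), times = nx)
  dmin <- rep(Inf, ny * nx)
  for (i in seq_len(nrow(segments))) {
    d <- pointSegmentDistance(px, py, segments$x0[i], segments$y0[i],
                              segments$x1[i], segments$y1[i])
    dmin <- pmin(dmin, d)
  }
  matrix(dmin, nrow = ny, ncol = nx)
}

assertScalar <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

# FNV-1a hash of a character string; used to fingerprint configs in reports
# without an external digest dependency.
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
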