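## Synthetic confocal-like fields: a Voronoi cell mosaic whose borders carry
## a Gaussian-cross-section ridge (junction staining), and a smooth textured
## field (endothelial surface glycocalyx staining).

# Sutherland-Hodgman clipping of a convex polygon by the half-plane
# a*x + b*y <= c. Edges keep a provenance label; new edges created along the
# clip line are labelled `lab`. poly is list(x, y, lab) with lab[k] the label
# of the edge leaving vertex k.
clipHalfPlane <- function(poly, a, b, c, lab) {
  n <- length(poly$x)
  if (n == 0L) return(poly)
  ox <- numeric(0); oy <- numeric(0); oin <- numeric(0)
  side <- a * poly$x + b * poly$y - c
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    pIn <- side[k] <= 1e-9; qIn <- side[k2] <= 1e-9
    if (pIn && qIn) {
      ox <- c(ox, poly$x[k2]); oy <- c(oy, poly$y[k2]); oin <- c(oin, poly$lab[k])
    } else if (pIn && !qIn) {
      t <- side[k] / (side[k] - side[k2])
      ox <- c(ox, poly$x[k] + t * (poly$x[k2] - poly$x[k]))
      oy <- c(oy, poly$y[k] + t * (poly$y[k2] - poly$y[k]))
      oin <- c(oin, poly$lab[k])
    } else if (!pIn && qIn) {
      t <- side[k] / (side[k] - side[k2])
      ox <- c(ox, poly$x[k] + t * (poly$x[k2] - poly$x[k]),  poly$x[k2])
      oy <- c(oy, poly$y[k] + t * (poly$y[k2] - poly$y[k]),  poly$y[k2])
      oin <- c(oin, lab, poly$lab[k])
    }
  }
  if (length(ox) == 0L) return(list(x = numeric(0), y = numeric(0), lab = numeric(0)))
  # oin[i] = label of the edge arriving at output vertex i; edge labels leave
  # vertex i, i.e. lab[i] = label arriving at vertex i+1
  lab_out <- c(oin[-1L], oin[1L])
  list(x = ox, y = oy, lab = lab_out)
}

# Voronoi edge segments of a set of sites inside the rectangle
# [0.5, nx+0.5] x [0.5, ny+0.5] (pixel-center convention: pixel (1,1) has
# center (1,1)). Returns data.frame(x0, y0, x1, y1, site_a, site_b).
voronoiSegments <- function(sx, sy, nx, ny) {
  nsite <- length(sx)
  segs <- list()
  for (i in seq_len(nsite)) {
    poly <- list(x = c(0.5, nx + 0.5, nx + 0.5, 0.5),
                 y = c(0.5, 0.5, ny + 0.5, ny + 0.5),
                 lab = c(0, 0, 0, 0))
    for (j in seq_len(nsite)) {
      if (j == i) next
      a <- 2 * (sx[j] - sx[i]); b <- 2 * (sy[j] - sy[i])
      c <- sx[j]^2 + sy[j]^2 - sx[i]^2 - sy[i]^2
      poly <- clipHalfPlane(poly, a, b, c, j)
      if (length(poly$x) == 0L) break
    }
    n <- length(poly$x)
    if (n < 2L) next
    for (k in seq_len(n)) {
      j <- poly$lab[k]
      if (j > i) {           # each shared border emitted once
        k2 <- if (k == n) 1L else k + 1L
        segs[[length(segs) + 1L]] <-
          c(poly$x[k], poly$y[k], poly$x[k2], poly$y[k2], i, j)
      }
    }
  }
  if (length(segs) == 0L)
    return(data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), site_a = integer(0), site_b = integer(0)))
  m <- do.call(rbind, segs)
  data.frame(x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4],
             site_a = as.integer(m[, 5]), site_b = as.integer(m[, 6]))
}

# z intensity envelope: peaked at the central slice, maximum exactly 1, with
# a large gap to the next slice so that a max projection recovers the focal
# plane essentially noise-bias-free.
zEnvelope <- function(nz) {
  if (nz == 1L) return(1)
  z <- seq_len(nz)
  zc <- (nz + 1) / 2
  env <- 0.4^((abs(z - zc) / max(abs(z - zc)))^1) # geometric falloff to 0.4
  env[which.min(abs(z - zc))] <- 1
  env
}

#' Simulate a junction-stained endothelial monolayer field
#'
#' Builds a Voronoi cell mosaic (each cell one endothelial cell) and renders
#' the cell-cell borders as ridges with a Gaussian cross-section: peak
#' intensity `junctionAmplitude * deficitFactor` above the background level,
#' mimicking tight-junction immunostaining. A patient-like deficit is
#' expressed by `deficitFactor < 1`. The ground-truth border segments are
#' returned for downstream perpendicular profile sampling.
#'
#' @param cellCount number of cells (>= 2; fewer has no junctions).
#' @param junctionAmplitude control-condition ridge peak above background.
#' @param backgroundLevel diffuse background intensity.
#' @param deficitFactor multiplicative junction deficit in (0, 1].
#' @param noiseSd additive Gaussian voxel noise SD.
#' @param fieldPx image side length in pixels.
#' @param pixelSize um per pixel.
#' @param nz number of z slices.
#' @param zStepUm z spacing (um).
#' @param ridgeFwhm full width at half maximum of the junction ridge (um);
#'   sub-resolution junctions appear widened to roughly the PSF width.
#' @param seed integer seed.
#'
#' @return A list with components `stack` ([ImageStack-class]), `segments`
#'   (data.frame of border segments, pixel-center coordinates, columns
#'   x0, y0, x1, y1, site_a, site_b) and `truth` (the input parameters).
#'
#' @examples
#' f <- simulateJunctionField(cellCount = 6, noiseSd = 0, fieldPx = 64, seed = 1)
#' range(voxels(f$stack))
#' @export
simulateJunctionField <- function(cellCount = 20, junctionAmplitude = 100,
                                  backgroundLevel = 10, deficitFactor = 1,
                                  noiseSd = 0, fieldPx = 128, pixelSize = 0.5,
                                  nz = 5, zStepUm = 0.2, ridgeFwhm = 1.0,
                                  seed = 1L) {
  if (cellCount < 2) stop("'cellCount' must be >= 2 (no junctions otherwise)")
  if (deficitFactor <= 0 || deficitFactor > 1)
    stop("'deficitFactor' must be in (0, 1]")
  assertScalar(junctionAmplitude, "junctionAmplitude", positive = TRUE)
  assertScalar(pixelSize, "pixelSize", positive = TRUE)
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  set.seed(as.integer(seed))

  nx <- ny <- as.integer(fieldPx)
  # dart-throwing site placement with a minimum separation for well-formed cells
  minSep <- 0.35 * fieldPx / sqrt(cellCount)
  sx <- stats::runif(1, 1, nx); sy <- stats::runif(1, 1, ny)
  tries <- 0L
  while (length(sx) < cellCount && tries < 20000L) {
    cx <- stats::runif(1, 1, nx); cy <- stats::runif(1, 1, ny)
    if (min(sqrt((sx - cx)^2 + (sy - cy)^2)) >= minSep) {
      sx <- c(sx, cx); sy <- c(sy, cy)
    }
    tries <- tries + 1L
  }
  segments <- voronoiSegments(sx, sy, nx, ny)

  sigmaPx <- (ridgeFwhm / pixelSize) / (2 * sqrt(2 * log(2)))
  dmap <- segmentDistanceMap(ny, nx, segments)
  plane <- backgroundLevel +
    junctionAmplitude * deficitFactor * exp(-dmap^2 / (2 * sigmaPx^2))

  # out-of-focus slices are dimmer everywhere (background included), so a
  # max projection recovers the focal plane without a noise-max bias
  env <- zEnvelope(nz)
  vox <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz))
    vox[z, , ] <- plane * env[z]
  if (noiseSd > 0)
    vox <- pmax(vox + stats::rnorm(length(vox), 0, noiseSd), 0)

  stack <- imageStack(vox, pixelSize = pixelSize, zStep = zStepUm,
                      channel = "junction")
  list(stack = stack, segments = segments,
       truth = list(junctionAmplitude = junctionAmplitude,
                    backgroundLevel = backgroundLevel,
                    deficitFactor = deficitFactor, noiseSd = noiseSd,
                    pixelSize = pixelSize, ridgeFwhm = ridgeFwhm,
                    seed = as.integer(seed)))
}

#' Simulate a glycocalyx-stained field
#'
#' Generates a spatially textured intensity field whose mean intensity above
#' background equals `amplitude * deficitFactor`, emulating heparan-sulfate
#' staining of the endothelial surface glycocalyx over a confluent monolayer.
#' The texture is a smooth zero-mean modulation, so the ground-truth field
#' mean is exact at zero noise.
#'
#' @param amplitude control-condition mean intensity above background.
#' @param backgroundLevel additive background.
#' @param deficitFactor multiplicative deficit in (0, 1].
#' @param noiseSd additive Gaussian voxel noise SD.
#' @param fieldPx image side length (pixels).
#' @param pixelSize um per pixel.
#' @param nz number of z slices.
#' @param zStepUm z spacing (um).
#' @param textureAmp relative amplitude of the smooth texture (0 disables).
#' @param seed integer seed.
#'
#' @return An [ImageStack-class] whose max projection has mean
#'   `backgroundLevel + amplitude * deficitFactor` at zero noise.
#' @examples
#' st <- simulateEsgField(deficitFactor = 0.42, noiseSd = 0, seed = 1)
#' mean(projectStack(st))
#' @export
simulateEsgField <- function(amplitude = 100, backgroundLevel = 0,
                             deficitFactor = 1, noiseSd = 0, fieldPx = 64,
                             pixelSize = 5, nz = 5, zStepUm = 0.32,
                             textureAmp = 0.25, seed = 1L) {
  if (deficitFactor <= 0 || deficitFactor > 1)
    stop("'deficitFactor' must be in (0, 1]")
  assertScalar(amplitude, "amplitude", positive = TRUE)
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  set.seed(as.integer(seed))

  nx <- ny <- as.integer(fieldPx)
  level <- amplitude * deficitFactor
  tex <- matrix(0, ny, nx)
  if (textureAmp > 0) {
    # low-resolution Gaussian grid, bilinearly upscaled -> smooth texture
    ng <- 8L
    g <- matrix(stats::rnorm(ng * ng), ng, ng)
    xi <- seq(1, ng, length.out = nx); yi <- seq(1, ng, length.out = ny)
    x0 <- pmin(floor(xi), ng - 1L); y0 <- pmin(floor(yi), ng - 1L)
    fx <- xi - x0; fy <- yi - y0
    tex <- outer(seq_len(ny), seq_len(nx), function(iy, ix) {
      g[cbind(y0[iy], x0[ix])] * (1 - fx[ix]) * (1 - fy[iy]) +
      g[cbind(y0[iy], x0[ix] + 1)] * fx[ix] * (1 - fy[iy]) +
      g[cbind(y0[iy] + 1, x0[ix])] * (1 - fx[ix]) * fy[iy] +
      g[cbind(y0[iy] + 1, x0[ix] + 1)] * fx[ix] * fy[iy]
    })
    tex <- pmin(pmax(tex, -3), 3)
    tex <- tex - mean(tex)                 # exact zero mean after clamping
    tex <- tex / max(1, max(abs(tex * textureAmp)) / 0.95) # keep field positive
  }
  plane <- backgroundLevel + level * (1 + textureAmp * tex)

  env <- zEnvelope(nz)
  vox <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz))
    vox[z, , ] <- plane * env[z]
  if (noiseSd > 0)
    vox <- pmax(vox + stats::rnorm(length(vox), 0, noiseSd), 0)

  imageStack(vox, pixelSize = pixelSize, zStep = zStepUm, channel = "ESG")
}
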