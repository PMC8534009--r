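#' @rdname projectStack
#' @export
setMethod("projectStack", "ImageStack", function(stack, method = c("max", "sum")) {
  method <- match.arg(method)
  projectStack(voxels(stack), method)
})

#' @rdname projectStack
#' @export
setMethod("projectStack", "array", function(stack, method = c("max", "sum")) {
  method <- match.arg(method)
  if (length(dim(stack)) != 3L) stop("expected a 3-D array (z, y, x)")
  if (dim(stack)[1L] == 0L) stop("empty stack")
  f <- if (method == "max") max else sum
  apply(stack, c(2L, 3L), f)
})

#' Perpendicular intensity profiles across junction segments
#'
#' For each cell-cell border segment, samples 3-5 short lines perpendicular
#' to the segment, equally distributed along its length, reads the image by
#' bilinear interpolation at fixed steps along each line, and averages the
#' lines into one intensity profile per junction. The per-junction peak is
#' the maximum of the averaged profile.
#'
#' @param image 2-D numeric matrix (y, x), typically a max projection.
#' @param segments data.frame with columns `x0, y0, x1, y1` in pixel-center
#'   coordinates (1-based), e.g. from [simulateJunctionField()].
#' @param pixelSize um per pixel.
#' @param lineLengthUm length of each perpendicular line (um, default 3).
#' @param linesPerJunction number of perpendicular lines per junction (3-5).
#' @param stepUm sampling step along each line (um); defaults to a quarter
#'   pixel, fine enough that the profile maximum is not undersampled.
#'
#' @return A list of class `junctionProfileSet`: `profiles` (matrix, one row
#'   per junction), `positions` (um, relative to the border), `peaks`,
#'   `clipped` (logical, line partially outside the image),
#'   `junctionCount`, and the sampling parameters.
#' @examples
#' f <- simulateJunctionField(cellCount = 6, noiseSd = 0, fieldPx = 64, seed = 1)
#' pr <- sampleJunctionProfiles(projectStack(f$stack), f$segments,
#'                              pixelSize = pixelSize(f$stack))
#' head(pr$peaks)
#' @export
sampleJunctionProfiles <- function(image, segments, pixelSize,
                                   lineLengthUm = 3, linesPerJunction = 3,
                                   stepUm = pixelSize / 4) {
  stopifnot(is.matrix(image))
  assertScalar(pixelSize, "pixelSize", positive = TRUE)
  if (!all(c("x0", "y0", "x1", "y1") %in% names(segments)))
    stop("'segments' needs columns x0, y0, x1, y1")
  if (linesPerJunction < 3 || linesPerJunction > 5)
    stop("'linesPerJunction' must be between 3 and 5")

  len <- sqrt((segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2)
  keep <- len >= 2
  if (!any(keep)) stop("no segment is at least 2 px long")
  segments <- segments[keep, , drop = FALSE]
  len <- len[keep]

  offsets <- seq(-lineLengthUm / 2, lineLengthUm / 2, by = stepUm) / pixelSize
  nJ <- nrow(segments)
  prof <- matrix(NA_real_, nJ, length(offsets))
  clipped <- logical(nJ)
  fracs <- seq_len(linesPerJunction) / (linesPerJunction + 1)
  for (i in seq_len(nJ)) {
    ux <- (segments$x1[i] - segments$x0[i]) / len[i]
    uy <- (segments$y1[i] - segments$y0[i]) / len[i]
    acc <- matrix(NA_real_, linesPerJunction, length(offsets))
    for (l in seq_len(linesPerJunction)) {
      cx <- segments$x0[i] + fracs[l] * (segments$x1[i] - segments$x0[i])
      cy <- segments$y0[i] + fracs[l] * (segments$y1[i] - segments$y0[i])
      px <- cx - offsets * uy      # normal direction (-uy, ux)
      py <- cy + offsets * ux
      acc[l, ] <- interp2(image, px, py)
    }
    if (anyNA(acc)) clipped[i] <- TRUE
    prof[i, ] <- colMeans(acc, na.rm = TRUE)
  }
  structure(list(profiles = prof,
                 positions = seq(-lineLengthUm / 2, lineLengthUm / 2,
                                 by = stepUm),
                 peaks = apply(prof, 1L, max, na.rm = TRUE),
                 clipped = clipped, junctionCount = nJ,
                 pixelSize = pixelSize, segments = segments),
            class = "junctionProfileSet")
}

#' Subtract the non-border background from junction profiles
#'
#' Estimates the background as the median intensity of pixels farther than
#' `marginUm` from every junction segment (the non-border region) and
#' subtracts it from profiles and peaks, clamping at zero.
#'
#' @param profiles a `junctionProfileSet` from [sampleJunctionProfiles()].
#' @param image the 2-D image the profiles were sampled from.
#' @param segments the segment table (defaults to the one stored in
#'   `profiles`).
#' @param marginUm distance from borders beyond which pixels count as
#'   background (um, default 2).
#'
#' @return The profile set with background-subtracted `profiles` and
#'   `peaks`, plus a `background` element.
#' @export
subtractBackground <- function(profiles, image, segments = profiles$segments,
                               marginUm = 2) {
  stopifnot(inherits(profiles, "junctionProfileSet"), is.matrix(image))
  dmap <- segmentDistanceMap(nrow(image), ncol(image), segments)
  marginPx <- marginUm / profiles$pixelSize
  bgPix <- image[dmap > marginPx]
  if (length(bgPix) == 0L)
    stop("no non-border region: segments cover the entire image")
  bg <- stats::median(bgPix)
  profiles$profiles <- pmax(profiles$profiles - bg, 0)
  profiles$peaks <- pmax(profiles$peaks - bg, 0)
  profiles$background <- bg
  profiles
}

#' Excess kurtosis (Fisher, population moments)
#'
#' \eqn{g_2 = m_4 / m_2^2 - 3} with central population moments. Used to
#' compare the shapes of junction-intensity distributions between patient
#' and control groups.
#'
#' @param values numeric vector, n >= 4, non-constant.
#' @return The excess kurtosis (0 for a normal distribution, -1.2 for a
#'   uniform one).
#' @examples
#' kurtosisExcess(c(-1, -1, 1, 1))   # -2
#' @export
kurtosisExcess <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L) stop("need at least 4 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("constant input: kurtosis undefined")
  mean((values - m)^4) / m2^2 - 3
}

#' Normalize patient junction peaks to the control mean
#'
#' Divides all per-junction peak intensities by the mean of the control (WT)
#' peaks, so the WT group has mean 1 by construction, and reports group
#' means, standard errors and per-group excess kurtosis.
#'
#' @param delPeaks,wtPeaks numeric vectors of background-subtracted peaks.
#' @return A list of class `intensityReport`: `normalizedDel`,
#'   `normalizedWt`, `meanDel`, `meanWt` (= 1), `seDel`, `seWt`,
#'   `kurtosisDel`, `kurtosisWt`, `wtReferenceMean`.
#' @export
normalizeToControl <- function(delPeaks, wtPeaks) {
  if (length(wtPeaks) == 0L || length(delPeaks) == 0L)
    stop("both groups must be non-empty")
  ref <- mean(wtPeaks)
  if (ref <= 0) stop("control mean must be positive")
  se <- function(x) stats::sd(x) / sqrt(length(x))
  kur <- function(x) if (length(x) >= 4L && stats::var(x) > 0)
    kurtosisExcess(x) else NA_real_
  structure(list(normalizedDel = delPeaks / ref,
                 normalizedWt = wtPeaks / ref,
                 meanDel = mean(delPeaks) / ref, meanWt = 1,
                 seDel = se(delPeaks / ref), seWt = se(wtPeaks / ref),
                 kurtosisDel = kur(delPeaks), kurtosisWt = kur(wtPeaks),
                 wtReferenceMean = ref),
            class = "intensityReport")
}

#' Glycocalyx field intensity, normalized to control
#'
#' Computes, for each sample, the mean of its field-mean intensities (each
#' field a z-stack reduced by max projection, background subtracted), then
#' normalizes every sample value by the mean of the control (WT) samples.
#' When the two groups are paired and equally sized, an exact Wilcoxon
#' signed-rank p-value on the per-sample values is included.
#'
#' @param wtStacks,delStacks lists of samples; each sample is a list of
#'   [ImageStack-class] fields (typically 3 fields per sample).
#' @param backgroundLevel constant background to subtract from field means.
#' @return A list of class `intensityReport` with per-sample `normalizedDel`
#'   and `normalizedWt` values, group summaries, `wtReferenceMean` and
#'   `wilcoxonP`.
#' @examples
#' wt <- list(list(simulateEsgField(seed = 1)))
#' del <- list(list(simulateEsgField(deficitFactor = 0.42, seed = 2)))
#' esgFieldIntensity(wt, del)$meanDel   # ~0.42
#' @export
esgFieldIntensity <- function(wtStacks, delStacks, backgroundLevel = 0) {
  sampleValue <- function(fields) {
    if (length(fields) == 0L) stop("a sample with no fields was supplied")
    mean(vapply(fields, function(st) mean(projectStack(st)) - backgroundLevel,
                numeric(1)))
  }
  asSamples <- function(x) if (is(x, "ImageStack")) list(list(x)) else
    lapply(x, function(s) if (is(s, "ImageStack")) list(s) else s)
  wtVals <- vapply(asSamples(wtStacks), sampleValue, numeric(1))
  delVals <- vapply(asSamples(delStacks), sampleValue, numeric(1))
  ref <- mean(wtVals)
  if (ref <= 0) stop("control mean intensity must be positive")
  se <- function(x) stats::sd(x) / sqrt(length(x))
  wp <- if (length(wtVals) == length(delVals) &&
            any(delVals - wtVals != 0))
    wilcoxonExactSignedRank(delVals - wtVals)$p.value else NA_real_
  structure(list(normalizedDel = delVals / ref, normalizedWt = wtVals / ref,
                 meanDel = mean(delVals) / ref, meanWt = 1,
                 seDel = se(delVals / ref), seWt = se(wtVals / ref),
                 kurtosisDel = NA_real_, kurtosisWt = NA_real_,
                 wtReferenceMean = ref, wilcoxonP = wp),
            class = "intensityReport")
}

#' @export
print.intensityReport <- function(x, ...) {
  cat(sprintf("Normalized intensity: DEL %.3f +/- %.3f (WT reference mean %.4g)\n",
              x$meanDel, x$seDel, x$wtReferenceMean))
  if (!is.null(x$wilcoxonP) && !is.na(x$wilcoxonP))
    cat(sprintf("  Wilcoxon signed-rank p = %.4g\n", x$wilcoxonP))
  if (!is.na(x$kurtosisDel))
    cat(sprintf("  excess kurtosis: DEL %.3f, WT %.3f\n",
                x$kurtosisDel, x$kurtosisWt))
  invisible(x)
}
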