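#' @import methods
NULL

#' Transwell assay geometry
#'
#' Physical description of a Transwell permeability assay: the insert
#' membrane area, chamber volumes, donor (upper chamber) tracer
#' concentration, and the draw-and-replace sampling schedule.
#'
#' The default constructor values reproduce the standard small-solute setup
#' used for induced blood-brain-barrier (iBBB) monolayers: a 0.9 cm^2 insert,
#' 1.5 mL lower chamber, 0.5 mL upper chamber loaded at 30 uM sodium
#' fluorescein, with 50 uL samples drawn from the lower chamber every 10 min
#' for 90 min and replaced with fresh medium.
#'
#' @slot membraneArea membrane area S in cm^2.
#' @slot lowerVolume lower (receiver) chamber volume V_L in mL.
#' @slot upperVolume upper (donor) chamber volume in mL.
#' @slot upperConc initial donor concentration C_U in uM.
#' @slot sampleVolume volume drawn per sampling event in mL.
#' @slot sampleInterval minutes between draws.
#' @slot duration total assay duration in minutes.
#'
#' @seealso [assayGeometry()] for the user-facing constructor.
#' @export
setClass("AssayGeometry",
  representation(
    membraneArea  = "numeric",
    lowerVolume   = "numeric",
    upperVolume   = "numeric",
    upperConc     = "numeric",
    sampleVolume  = "numeric",
    sampleInterval = "numeric",
    duration      = "numeric"
  )
)

setValidity("AssayGeometry", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  for (sl in c("membraneArea", "lowerVolume", "upperVolume", "upperConc",
               "sampleInterval", "duration")) {
    v <- slot(object, sl)
    if (!one(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", sl))
  }
  if (!one(object@sampleVolume) || object@sampleVolume < 0)
    msg <- c(msg, "'sampleVolume' must be a single non-negative number")
  if (length(msg) == 0L) {
    if (object@sampleVolume >= object@lowerVolume)
      msg <- c(msg, "'sampleVolume' must be smaller than 'lowerVolume'")
    if (object@duration < object@sampleInterval)
      msg <- c(msg, "'duration' must be at least one 'sampleInterval'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Transwell assay geometry
#'
#' @param membraneArea membrane area S (cm^2).
#' @param lowerVolume lower-chamber volume V_L (mL).
#' @param upperVolume upper-chamber volume (mL).
#' @param upperConc initial donor concentration C_U (uM).
#' @param sampleVolume volume withdrawn at each sampling event (mL); 0 means
#'   no medium is exchanged.
#' @param sampleInterval minutes between draws.
#' @param duration assay duration (minutes).
#'
#' @return An [AssayGeometry-class] object.
#' @examples
#' geom <- assayGeometry()          # 0.9 cm^2, 1.5/0.5 mL, 30 uM, 50 uL/10 min
#' membraneArea(geom)
#' @export
assayGeometry <- function(membraneArea = 0.9, lowerVolume = 1.5,
                          upperVolume = 0.5, upperConc = 30,
                          sampleVolume = 0.05, sampleInterval = 10,
                          duration = 90) {
  new("AssayGeometry", membraneArea = membraneArea, lowerVolume = lowerVolume,
      upperVolume = upperVolume, upperConc = upperConc,
      sampleVolume = sampleVolume, sampleInterval = sampleInterval,
      duration = duration)
}

#' Sampled lower-chamber tracer time series
#'
#' Concentrations measured in the lower chamber of a Transwell assay at each
#' sampling time, together with the assay geometry. Optionally annotated with
#' the ground-truth permeability when the series was simulated.
#'
#' @slot times sampling times in minutes, strictly increasing, starting at 0.
#' @slot lowerConc measured lower-chamber concentration (uM) at each time.
#' @slot geometry an [AssayGeometry-class].
#' @slot pTrue ground-truth permeability (cm/s) for simulated series, or NA.
#'
#' @export
setClass("TranswellSeries",
  representation(
    times     = "numeric",
    lowerConc = "numeric",
    geometry  = "AssayGeometry",
    pTrue     = "numeric"
  ),
  prototype(pTrue = NA_real_)
)

setValidity("TranswellSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@lowerConc))
    msg <- c(msg, "'times' and 'lowerConc' must have equal length")
  if (length(object@times) > 0L) {
    if (object@times[1L] != 0)
      msg <- c(msg, "'times' must start at 0")
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "'times' must be strictly increasing")
  }
  if (any(object@lowerConc < 0))
    msg <- c(msg, "'lowerConc' must be non-negative")
  if (length(object@pTrue) != 1L)
    msg <- c(msg, "'pTrue' must be a single value (possibly NA)")
  if (length(msg)) msg else TRUE
})

#' Construct a Transwell tracer time series
#'
#' @param times sampling times (minutes), strictly increasing from 0.
#' @param lowerConc lower-chamber concentrations (uM), one per time point.
#' @param geometry an [AssayGeometry-class].
#' @param pTrue optional ground-truth permeability (cm/s) for simulated data.
#' @return A [TranswellSeries-class].
#' @export
transwellSeries <- function(times, lowerConc, geometry = assayGeometry(),
                            pTrue = NA_real_) {
  new("TranswellSeries", times = as.numeric(times),
      lowerConc = as.numeric(lowerConc), geometry = geometry,
      pTrue = as.numeric(pTrue))
}

#' Permeability decomposition of a Transwell measurement
#'
#' Holds the apparent (total) permeability of monolayer plus insert, the
#' blank-insert permeability, and the derived monolayer-only permeability
#' obtained from the series-barrier relation 1/P_t = 1/P_iBBB + 1/P_i.
#'
#' @slot pTotal apparent permeability P_t (cm/s) of monolayer + insert.
#' @slot pInsert blank-insert permeability P_i (cm/s), NA if not supplied.
#' @slot pBarrier monolayer permeability P_iBBB (cm/s), NA until resolved.
#' @slot slope fitted accumulation slope dC_L/dt (uM/s).
#' @slot slopeR2 R^2 of the linear fit of corrected cumulative concentration.
#'
#' @export
setClass("PermeabilityResult",
  representation(
    pTotal   = "numeric",
    pInsert  = "numeric",
    pBarrier = "numeric",
    slope    = "numeric",
    slopeR2  = "numeric"
  ),
  prototype(pInsert = NA_real_, pBarrier = NA_real_, slopeR2 = NA_real_)
)

setValidity("PermeabilityResult", function(object) {
  msg <- character()
  for (sl in c("pTotal", "pInsert", "pBarrier", "slope", "slopeR2"))
    if (length(slot(object, sl)) != 1L)
      msg <- c(msg, sprintf("'%s' must be a single value", sl))
  if (length(msg) == 0L && is.finite(object@pTotal) &&
      is.finite(object@pBarrier) && is.finite(object@pInsert)) {
    lhs <- 1 / object@pTotal
    rhs <- 1 / object@pBarrier + 1 / object@pInsert
    if (abs(lhs - rhs) > 1e-9 * abs(lhs))
      msg <- c(msg, "series-barrier identity 1/pTotal = 1/pBarrier + 1/pInsert violated")
    if (object@pBarrier < object@pTotal)
      msg <- c(msg, "'pBarrier' must be >= 'pTotal'")
  }
  if (length(msg)) msg else TRUE
})

#' Multi-channel confocal-like image stack
#'
#' A 3-D intensity array indexed (z, y, x), with isotropic in-plane pixel
#' size and the z spacing, as produced by confocal z-stack acquisition of an
#' endothelial monolayer.
#'
#' @slot voxels numeric 3-D array, dimensions (z, y, x), non-negative.
#' @slot pixelSize in-plane pixel size (um/px).
#' @slot zStep z spacing between slices (um).
#' @slot channel channel label (e.g. "ZO-1", "HS").
#'
#' @export
setClass("ImageStack",
  representation(
    voxels    = "array",
    pixelSize = "numeric",
    zStep     = "numeric",
    channel   = "character"
  ),
  prototype(zStep = 0.2, channel = "unlabeled")
)

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "'voxels' must be a 3-D array (z, y, x)")
  if (any(object@voxels < 0))
    msg <- c(msg, "'voxels' must be non-negative")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number")
  if (length(object@zStep) != 1L || object@zStep <= 0)
    msg <- c(msg, "'zStep' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an image stack
#'
#' @param voxels 3-D numeric array (z, y, x); a 2-D matrix is promoted to a
#'   single-slice stack.
#' @param pixelSize in-plane pixel size (um/px).
#' @param zStep z spacing (um).
#' @param channel channel label.
#' @return An [ImageStack-class].
#' @export
imageStack <- function(voxels, pixelSize, zStep = 0.2, channel = "unlabeled") {
  if (is.matrix(voxels))
    voxels <- array(voxels, dim = c(1L, nrow(voxels), ncol(voxels)))
  new("ImageStack", voxels = voxels, pixelSize = pixelSize, zStep = zStep,
      channel = channel)
}
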