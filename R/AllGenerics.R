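#' @include AllClasses.R
NULL

#' Accessors for assay and image objects
#'
#' Small accessor generics for the S4 containers: geometry slots of an
#' [AssayGeometry-class] or [TranswellSeries-class], the sampled time/
#' concentration vectors, permeability components, and voxel data of an
#' [ImageStack-class].
#'
#' @param object an object of the documented class.
#' @return The slot value (a numeric scalar, vector, array, or S4 object).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("membraneArea", function(object) standardGeneric("membraneArea"))
#' @rdname accessors
#' @export
setGeneric("lowerVolume", function(object) standardGeneric("lowerVolume"))
#' @rdname accessors
#' @export
setGeneric("upperVolume", function(object) standardGeneric("upperVolume"))
#' @rdname accessors
#' @export
setGeneric("upperConc", function(object) standardGeneric("upperConc"))
#' @rdname accessors
#' @export
setGeneric("sampleVolume", function(object) standardGeneric("sampleVolume"))
#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setGeneric("lowerConc", function(object) standardGeneric("lowerConc"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("pTotal", function(object) standardGeneric("pTotal"))
#' @rdname accessors
#' @export
setGeneric("pInsert", function(object) standardGeneric("pInsert"))
#' @rdname accessors
#' @export
setGeneric("pBarrier", function(object) standardGeneric("pBarrier"))
#' @rdname accessors
#' @export
setGeneric("accumulationSlope", function(object) standardGeneric("accumulationSlope"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("zStep", function(object) standardGeneric("zStep"))
#' @rdname accessors
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))

#' Maximum-intensity projection of an image stack
#'
#' @param stack an [ImageStack-class] (or 3-D array).
#' @param method `"max"` (default) for maximum-intensity projection or
#'   `"sum"` for a sum projection.
#' @return A 2-D numeric matrix (y, x).
#' @export
setGeneric("projectStack", function(stack, method = c("max", "sum"))
  standardGeneric("projectStack"))

#' @rdname accessors
#' @export
setMethod("membraneArea", "AssayGeometry", function(object) object@membraneArea)
#' @rdname accessors
#' @export
setMethod("lowerVolume", "AssayGeometry", function(object) object@lowerVolume)
#' @rdname accessors
#' @export
setMethod("upperVolume", "AssayGeometry", function(object) object@upperVolume)
#' @rdname accessors
#' @export
setMethod("upperConc", "AssayGeometry", function(object) object@upperConc)
#' @rdname accessors
#' @export
setMethod("sampleVolume", "AssayGeometry", function(object) object@sampleVolume)
#' @rdname accessors
#' @export
setMethod("membraneArea", "TranswellSeries",
          function(object) object@geometry@membraneArea)
#' @rdname accessors
#' @export
setMethod("sampleTimes", "TranswellSeries", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("lowerConc", "TranswellSeries", function(object) object@lowerConc)
#' @rdname accessors
#' @export
setMethod("geometry", "TranswellSeries", function(object) object@geometry)
#' @rdname accessors
#' @export
setMethod("pTotal", "PermeabilityResult", function(object) object@pTotal)
#' @rdname accessors
#' @export
setMethod("pInsert", "PermeabilityResult", function(object) object@pInsert)
#' @rdname accessors
#' @export
setMethod("pBarrier", "PermeabilityResult", function(object) object@pBarrier)
#' @rdname accessors
#' @export
setMethod("accumulationSlope", "PermeabilityResult", function(object) object@slope)
#' @rdname accessors
#' @export
setMethod("voxels", "ImageStack", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ImageStack", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("zStep", "ImageStack", function(object) object@zStep)
#' @rdname accessors
#' @export
setMethod("channelName", "ImageStack", function(object) object@channel)

setMethod("show", "AssayGeometry", function(object) {
  cat("AssayGeometry:",
      sprintf("S = %g cm^2, V_L = %g mL, V_U = %g mL, C_U = %g uM",
              object@membraneArea, object@lowerVolume, object@upperVolume,
              object@upperConc), "\n")
  cat(sprintf("  draws: %g mL every %g min for %g min\n",
              object@sampleVolume, object@sampleInterval, object@duration))
})

setMethod("show", "TranswellSeries", function(object) {
  cat(sprintf("TranswellSeries: %d timepoints over %g min\n",
              length(object@times), max(object@times)))
  if (is.finite(object@pTrue))
    cat(sprintf("  simulated (ground-truth P = %.3g cm/s)\n", object@pTrue))
  show(object@geometry)
})

setMethod("show", "PermeabilityResult", function(object) {
  cat(sprintf("PermeabilityResult: P_t = %.4g cm/s", object@pTotal))
  if (is.finite(object@pBarrier))
    cat(sprintf(", P_iBBB = %.4g cm/s (P_i = %.4g)",
                object@pBarrier, object@pInsert))
  cat("\n")
  if (is.finite(object@slopeR2))
    cat(sprintf("  slope = %.4g uM/s (R^2 = %.4f)\n",
                object@slope, object@slopeR2))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack '%s': %d x %d px, %d z-slices, %g um/px, z-step %g um\n",
              object@channel, d[3L], d[2L], d[1L], object@pixelSize,
              object@zStep))
})
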