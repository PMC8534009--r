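#' Simulate a Transwell tracer accumulation series
#'
#' Integrates the two-compartment mass balance of a Transwell permeability
#' assay and returns the lower-chamber concentrations that a plate reader
#' would see at each sampling time. Tracer flux across the monolayer+insert
#' is J = P * S * (C_U - C_L); both chambers are finite, so the donor
#' concentration declines and a back-gradient builds as tracer accumulates.
#' At every sampling event a fixed volume is withdrawn from the lower chamber
#' (instantaneously, perfectly mixed) and replaced with fresh medium, diluting
#' the receiver by `sampleVolume / lowerVolume`.
#'
#' The integration uses explicit sub-stepping (steps of at most `dt` seconds)
#' rather than assuming a perfect sink, so the simulation stays valid when
#' the lower-chamber concentration becomes non-negligible - exactly the
#' regime in which the linear single-slope estimator
#' ([permeabilityTotal()]) starts to degrade.
#'
#' @param geometry an [AssayGeometry-class].
#' @param pTrue ground-truth permeability in cm/s (>= 0).
#' @param noiseSd additive Gaussian measurement noise on each sampled
#'   concentration (uM).
#' @param seed integer seed; the generator is fully deterministic given the
#'   seed.
#' @param dt maximum integration sub-step in seconds (default 1).
#'
#' @return A [TranswellSeries-class] with attribute-free slots plus the
#'   ground truth in `pTrue`. The returned object additionally carries the
#'   attribute `massBalance`: a list with components `upper`, `lower`,
#'   `withdrawn` and `initial` (nmol) for mass-conservation checks.
#'
#' @details Units: volumes in mL (= cm^3), concentrations in uM, area in
#'   cm^2, permeability in cm/s, so flux P*S*C has units nmol/s.
#'
#' @examples
#' s <- simulateTranswell(assayGeometry(), pTrue = 1e-5, noiseSd = 0, seed = 1)
#' lowerConc(s)
#' @export
simulateTranswell <- function(geometry = assayGeometry(), pTrue, noiseSd = 0,
                              seed = 1L, dt = 1) {
  validObject(geometry)
  assertScalar(pTrue, "pTrue"); assertScalar(noiseSd, "noiseSd")
  if (pTrue < 0) stop("'pTrue' must be >= 0")
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  set.seed(as.integer(seed))

  S  <- geometry@membraneArea
  VL <- geometry@lowerVolume
  VU <- geometry@upperVolume
  CU <- geometry@upperConc
  Vs <- geometry@sampleVolume
  interval <- geometry@sampleInterval * 60   # s
  nDraw <- floor(geometry@duration / geometry@sampleInterval)

  CL <- 0
  withdrawn <- 0
  times <- 0
  concTrue <- 0
  nSub <- ceiling(interval / dt)
  h <- interval / nSub
  for (k in seq_len(nDraw)) {
    for (i in seq_len(nSub)) {
      J <- pTrue * S * (CU - CL)            # nmol/s
      CU <- CU - J * h / VU
      CL <- CL + J * h / VL
    }
    times <- c(times, k * geometry@sampleInterval)
    concTrue <- c(concTrue, CL)
    withdrawn <- withdrawn + CL * Vs        # mass taken out for measurement
    CL <- CL * (1 - Vs / VL)                # replace with fresh medium
  }

  measured <- concTrue
  if (noiseSd > 0)
    measured <- pmax(0, measured + stats::rnorm(length(measured), 0, noiseSd))

  out <- transwellSeries(times, measured, geometry, pTrue = pTrue)
  attr(out, "massBalance") <- list(
    upper = CU * VU, lower = CL * VL, withdrawn = withdrawn,
    initial = geometry@upperConc * VU)
  out
}

#' Simulate paired raw TEER readings
#'
#' Generates `n` paired (total, blank) resistance readings as measured by a
#' volt-ohm meter: `total` is the monolayer-plus-blank-filter reading and
#' `blank` the cell-free filter background, each with independent additive
#' Gaussian noise.
#'
#' @param trueResistance net monolayer resistance in Ohm (> 0).
#' @param blankResistance blank-filter resistance in Ohm (> 0).
#' @param n number of paired readings (>= 1).
#' @param noiseSd meter noise standard deviation in Ohm.
#' @param seed integer seed.
#'
#' @return A data.frame with columns `sample_id`, `total_ohm`, `blank_ohm`.
#'   As noise goes to zero, `mean(total_ohm - blank_ohm)` equals
#'   `trueResistance` exactly.
#' @examples
#' simulateTeer(70, 30, n = 3, noiseSd = 0, seed = 1)
#' @export
simulateTeer <- function(trueResistance, blankResistance, n, noiseSd = 0,
                         seed = 1L) {
  assertScalar(trueResistance, "trueResistance", positive = TRUE)
  assertScalar(blankResistance, "blankResistance", positive = TRUE)
  if (length(n) != 1L || n < 1) stop("'n' must be >= 1")
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  set.seed(as.integer(seed))
  n <- as.integer(n)
  total <- blankResistance + trueResistance + stats::rnorm(n, 0, noiseSd)
  blank <- blankResistance + stats::rnorm(n, 0, noiseSd)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             total_ohm = total, blank_ohm = blank)
}
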