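#' Dilution-corrected cumulative lower-chamber concentration
#'
#' Each draw-and-replace sampling event removes a fraction
#' `sampleVolume / lowerVolume` of the tracer already accumulated in the
#' receiver chamber. The corrected cumulative concentration restores that
#' withdrawn tracer so that, under a constant flux, the corrected series is
#' exactly linear in time:
#' \deqn{C_{corr}(t_k) = C_L(t_k) + \frac{V_s}{V_L} \sum_{j<k} C_L(t_j).}
#'
#' @param series a [TranswellSeries-class] (>= 3 timepoints), or a numeric
#'   vector of concentrations if `sampleVolume` and `lowerVolume` are given.
#' @param sampleVolume,lowerVolume override volumes (mL) when `series` is a
#'   plain vector.
#' @param corrected if `FALSE`, returns the input concentrations unchanged
#'   (uncorrected mode, for sensitivity checks).
#'
#' @return Numeric vector of corrected cumulative concentrations (uM), one
#'   per timepoint; monotone non-decreasing for noise-free input.
#' @examples
#' s <- simulateTranswell(pTrue = 5e-6, noiseSd = 0, seed = 1)
#' correctedCumulative(s)
#' @export
correctedCumulative <- function(series, sampleVolume = NULL,
                                lowerVolume = NULL, corrected = TRUE) {
  if (is(series, "TranswellSeries")) {
    validObject(series)
    if (any(diff(series@times) <= 0)) stop("times must be strictly increasing")
    conc <- series@lowerConc
    Vs <- series@geometry@sampleVolume
    VL <- series@geometry@lowerVolume
  } else {
    conc <- as.numeric(series)
    if (is.null(sampleVolume) || is.null(lowerVolume))
      stop("supply 'sampleVolume' and 'lowerVolume' with a plain vector")
    Vs <- sampleVolume; VL <- lowerVolume
  }
  if (length(conc) < 3L) stop("need at least 3 timepoints")
  if (!corrected || Vs == 0) return(conc)
  prior <- c(0, cumsum(conc)[-length(conc)])
  conc + (Vs / VL) * prior
}

#' Apparent permeability from a Transwell series
#'
#' Estimates the apparent permeability of monolayer + insert from the
#' dilution-corrected accumulation of tracer in the lower chamber:
#' \deqn{P = \frac{\Delta C_L}{\Delta t} \times \frac{V_L}{C_U \, S}}
#' with the slope taken as the least-squares slope of the corrected
#' cumulative concentration against time (in seconds) over all timepoints.
#'
#' The estimator assumes sink conditions (constant donor concentration,
#' negligible receiver back-gradient). A warning is emitted when the maximum
#' corrected concentration exceeds 10\% of the donor concentration, where
#' the single-slope linear model visibly under-estimates permeability.
#'
#' @param series a [TranswellSeries-class] with at least 3 timepoints.
#' @param corrected apply the draw-and-replace dilution correction
#'   (default TRUE).
#'
#' @return A [PermeabilityResult-class] with `pTotal`, `slope` (uM/s) and
#'   `slopeR2` populated; `pBarrier`/`pInsert` remain NA until
#'   [permeabilityBarrier()] is applied.
#' @examples
#' s <- simulateTranswell(pTrue = 2e-6, noiseSd = 0, seed = 1)
#' pTotal(permeabilityTotal(s))
#' @export
permeabilityTotal <- function(series, corrected = TRUE) {
  stopifnot(is(series, "TranswellSeries"))
  validObject(series)
  geom <- series@geometry
  if (geom@upperConc <= 0) stop("donor concentration C_U must be positive")
  if (length(series@times) < 3L) stop("need at least 3 timepoints")
  cc <- correctedCumulative(series, corrected = corrected)
  tSec <- series@times * 60
  fit <- stats::lm(cc ~ tSec)
  slope <- unname(stats::coef(fit)[2L])
  ssTot <- sum((cc - mean(cc))^2)
  r2 <- if (ssTot == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / ssTot
  if (max(cc) > 0.1 * geom@upperConc)
    warning("corrected lower-chamber concentration exceeds 10% of C_U; ",
            "sink-condition assumption of the linear estimator is degraded")
  p <- slope * geom@lowerVolume / (geom@upperConc * geom@membraneArea)
  new("PermeabilityResult", pTotal = p, slope = slope, slopeR2 = r2)
}

#' Monolayer permeability by series-barrier correction
#'
#' The monolayer and the blank insert act as two barriers in series, so
#' their resistances (reciprocal permeabilities) add:
#' \deqn{\frac{1}{P_t} = \frac{1}{P_{iBBB}} + \frac{1}{P_i}
#'   \quad\Rightarrow\quad P_{iBBB} = \frac{1}{1/P_t - 1/P_i}.}
#'
#' @param pTotal apparent permeability of monolayer + insert (cm/s).
#' @param pInsert blank-insert permeability (cm/s); may be `Inf`, in which
#'   case the monolayer permeability equals `pTotal`. Alternatively, a
#'   [PermeabilityResult-class] may be given as `pTotal`, in which case the
#'   resolved result object is returned.
#'
#' @return The monolayer permeability in cm/s (or an updated
#'   [PermeabilityResult-class]).
#' @examples
#' permeabilityBarrier(2e-6, 6e-6)   # 3e-6
#' @export
permeabilityBarrier <- function(pTotal, pInsert) {
  if (is(pTotal, "PermeabilityResult")) {
    res <- pTotal
    p <- permeabilityBarrier(res@pTotal, pInsert)
    res@pInsert <- pInsert
    res@pBarrier <- p
    validObject(res)
    return(res)
  }
  assertScalar(pTotal, "pTotal", positive = TRUE)
  if (length(pInsert) != 1L || is.na(pInsert) || pInsert <= 0)
    stop("'pInsert' must be a single positive number (possibly Inf)")
  if (is.infinite(pInsert)) return(pTotal)
  if (pTotal >= pInsert)
    stop("pTotal >= pInsert: series-barrier model violated ",
         "(monolayer adds no measurable resistance)")
  1 / (1 / pTotal - 1 / pInsert)
}

#' Area-normalized TEER with blank-filter subtraction
#'
#' Subtracts the blank-filter background resistance from the total
#' (monolayer + filter) reading and normalizes by the membrane area:
#' `TEER = (total - blank) * area`, in Ohm cm^2.
#'
#' @param total total resistance reading (Ohm).
#' @param blank blank-filter resistance (Ohm), `0 <= blank < total`.
#' @param area membrane area (cm^2).
#' @return TEER in Ohm cm^2. Vectorized over `total`/`blank`.
#' @examples
#' teerArea(100, 30, 0.9)   # 63
#' @export
teerArea <- function(total, blank, area) {
  assertScalar(area, "area", positive = TRUE)
  if (any(blank < 0)) stop("'blank' must be >= 0")
  if (any(total <= blank))
    stop("total <= blank: no barrier resistance measured")
  (total - blank) * area
}

#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Computes the signed-rank statistic W (sum of ranks of positive
#' differences, mid-ranks for tied absolute differences, zeros dropped) and
#' its exact two-sided p-value by enumerating the null distribution over all
#' 2^n equally likely sign assignments. The two-sided p is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param diffs numeric vector of paired differences. Up to 20 non-zero
#'   differences are supported (the enumeration is carried out by
#'   convolution over ranks, so mid-ranks from ties are handled exactly).
#'
#' @return A list with `statistic` (W), `p.value`, `n` (non-zero pairs) and
#'   `nZero` (dropped zero differences).
#' @examples
#' wilcoxonExactSignedRank(c(3, 1, 4, 1, 5, 9))$p.value   # 2/64
#' @export
wilcoxonExactSignedRank <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (anyNA(diffs)) stop("'diffs' must not contain NA")
  nZero <- sum(diffs == 0)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  if (n > 20L) stop("exact enumeration supported for at most 20 non-zero pairs")
  r <- rank(abs(d))                       # mid-ranks for ties
  w <- sum(r[d > 0])

  # distribution of W: convolve each rank in (absent, present) with prob 1/2
  sums <- 0; probs <- 1
  for (rk in r) {
    sums <- c(sums, sums + rk)
    probs <- c(probs, probs) / 2
    key <- round(sums, 8)
    agg <- tapply(probs, key, sum)
    sums <- as.numeric(names(agg))
    probs <- as.numeric(agg)
  }
  eps <- 1e-8
  pLe <- sum(probs[sums <= w + eps])
  pGe <- sum(probs[sums >= w - eps])
  list(statistic = w, p.value = min(1, 2 * min(pLe, pGe)),
       n = n, nZero = nZero)
}

#' Patient-to-control group ratio
#'
#' Ratio of a patient (DEL) group mean to the matched control (WT) group
#' mean, either as a percentage (TEER-style reporting: "62\% of control") or
#' as a fold change (permeability-style reporting: "1.4-fold of control").
#'
#' @param delMean patient group mean.
#' @param wtMean control group mean (> 0).
#' @param mode `"percent"` returns `100 * del/wt`; `"fold"` returns `del/wt`.
#' @return A single number.
#' @examples
#' groupRatio(42.6, 68.3, "percent")   # ~62
#' groupRatio(0.34, 0.24, "fold")      # ~1.4
#' @export
groupRatio <- function(delMean, wtMean, mode = c("percent", "fold")) {
  mode <- match.arg(mode)
  assertScalar(delMean, "delMean")
  assertScalar(wtMean, "wtMean")
  if (wtMean <= 0) stop("'wtMean' must be positive")
  if (mode == "percent") 100 * delMean / wtMean else delMean / wtMean
}

#' Summarize a patient vs control barrier comparison
#'
#' Convenience wrapper producing group means, standard errors, the exact
#' Wilcoxon signed-rank p-value on the paired differences, and both ratio
#' reductions: the ratio of group means and the mean of per-pair ratios
#' (which generally differ for noisy data).
#'
#' @param del,wt numeric vectors of paired per-sample values (same length).
#' @param mode passed to [groupRatio()].
#' @return A list with `meanDel`, `meanWt`, `seDel`, `seWt`,
#'   `ratioOfMeans`, `meanOfRatios`, `wilcoxonP`.
#' @export
compareGroups <- function(del, wt, mode = c("percent", "fold")) {
  mode <- match.arg(mode)
  if (length(del) != length(wt)) stop("'del' and 'wt' must be paired")
  se <- function(x) stats::sd(x) / sqrt(length(x))
  wp <- if (any(del - wt != 0))
    wilcoxonExactSignedRank(del - wt)$p.value else NA_real_
  scale <- if (mode == "percent") 100 else 1
  list(meanDel = mean(del), meanWt = mean(wt),
       seDel = se(del), seWt = se(wt),
       ratioOfMeans = groupRatio(mean(del), mean(wt), mode),
       meanOfRatios = scale * mean(del / wt),
       wilcoxonP = wp)
}
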