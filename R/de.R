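## Minimal negative-binomial differential-expression stage. Exists so that
## synthetic counts can flow through the pipeline end to end; externally
## produced DEG tables (e.g. from a full shrinkage-based NB fit) are accepted
## by the downstream filtering functions unchanged.

# median-of-ratios size factors (geometric-mean reference over genes with
# all-positive counts)
medianOfRatios <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  geo <- exp(rowMeans(lg))
  ok <- is.finite(geo) & geo > 0
  if (!any(ok)) stop("no gene has all-positive counts; cannot normalize")
  sf <- apply(counts[ok, , drop = FALSE], 2L, function(cl)
    stats::median(cl / geo[ok]))
  if (any(sf <= 0)) stop("a sample has an all-zero (or degenerate) library")
  sf / exp(mean(log(sf)))           # geometric mean 1
}

#' Minimal negative-binomial Wald test
#'
#' Two-group (WT vs DEL) differential-expression test on integer counts:
#' median-of-ratios size factors, per-gene method-of-moments NB dispersion
#' moderated toward a common (clipped-mean) dispersion, a Wald test on the
#' log2 fold change (DEL/WT) with a delta-method standard error
#' \eqn{Var(\log\hat\mu) = 1/(n\mu) + \alpha/n} per group, and
#' Benjamini-Hochberg adjustment. `base_mean` is the mean of normalized
#' counts across all samples.
#'
#' With few replicates a raw per-gene moment dispersion is far too noisy to
#' calibrate a Wald test, so by default the dispersion is fully moderated to
#' the common value (`moderation = 1`); lower values interpolate toward the
#' per-gene estimate.
#'
#' @param counts integer matrix (genes x samples) or a
#'   [SummarizedExperiment::SummarizedExperiment] with assay `counts` and
#'   `colData$group`.
#' @param groups factor/character of sample groups when `counts` is a
#'   matrix; must contain exactly the levels WT and DEL, >= 2 samples each.
#' @param moderation weight in \[0, 1\] on the common dispersion
#'   (1 = common-dispersion test, 0 = raw per-gene moments).
#' @param dispersionFloor lower bound for the dispersion estimate.
#'
#' @return A `data.frame` DEG table with columns `gene_id`, `base_mean`,
#'   `log2fc` (DEL/WT), `pvalue`, `fdr`, `dispersion`, and `in_deletion`
#'   when the input carried that annotation.
#' @examples
#' se <- simulateCounts(nGenes = 200, deletionGenes = sprintf("g%d", 1:5), seed = 1)
#' deg <- nbDeTest(se)
#' head(deg[order(deg$fdr), ])
#' @export
nbDeTest <- function(counts, groups = NULL, moderation = 1,
                     dispersionFloor = 1e-8) {
  inDel <- NULL
  if (is(counts, "SummarizedExperiment")) {
    groups <- SummarizedExperiment::colData(counts)$group
    rd <- SummarizedExperiment::rowData(counts)
    if ("in_deletion" %in% colnames(rd)) inDel <- rd$in_deletion
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  if (is.null(groups)) stop("supply 'groups' with a plain count matrix")
  groups <- as.character(groups)
  if (!setequal(unique(groups), c("WT", "DEL")))
    stop("'groups' must consist of the two labels WT and DEL")
  w <- groups == "WT"; d <- !w
  if (sum(w) < 2L || sum(d) < 2L) stop("need >= 2 samples per group")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers")

  sf <- medianOfRatios(counts)
  nc <- sweep(counts, 2L, sf, "/")
  nw <- sum(w); nd <- sum(d)
  muW <- rowMeans(nc[, w, drop = FALSE])
  muD <- rowMeans(nc[, d, drop = FALSE])
  baseMean <- rowMeans(nc)

  varW <- apply(nc[, w, drop = FALSE], 1L, stats::var)
  varD <- apply(nc[, d, drop = FALSE], 1L, stats::var)
  s2 <- (varW * (nw - 1) + varD * (nd - 1)) / (nw + nd - 2)
  mu <- (nw * muW + nd * muD) / (nw + nd)
  alphaMom <- (s2 - mu) / mu^2
  keep <- is.finite(alphaMom) & mu > 50
  alphaCommon <- if (any(keep)) mean(pmax(alphaMom[keep], 0)) else 0.1
  alpha <- pmax(dispersionFloor,
                (1 - moderation) * pmax(alphaMom, 0) + moderation * alphaCommon)

  muW2 <- pmax(muW, 0.5); muD2 <- pmax(muD, 0.5)   # continuity for empty groups
  log2fc <- log2(muD2 / muW2)
  varLn <- (1 / (nw * muW2) + alpha / nw) + (1 / (nd * muD2) + alpha / nd)
  se <- sqrt(varLn) / log(2)
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))

  out <- data.frame(gene_id = rownames(counts) %||% sprintf("gene%04d", seq_len(nrow(counts))),
                    base_mean = baseMean, log2fc = log2fc,
                    pvalue = p, fdr = stats::p.adjust(p, "BH"),
                    dispersion = alpha, row.names = NULL)
  if (!is.null(inDel)) out$in_deletion <- inDel
  attr(out, "sizeFactors") <- sf
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter a DEG table at printed significance thresholds
#'
#' Applies the strict inequalities `fdr < fdrMax` and
#' `base_mean > baseMeanMin` (defaults 0.01 and 100).
#'
#' @param deg a DEG table as returned by [nbDeTest()] (or any data.frame
#'   with `fdr` and `base_mean` columns).
#' @param fdrMax FDR threshold (strict `<`).
#' @param baseMeanMin base-mean threshold (strict `>`).
#' @return The subset of rows passing both filters.
#' @export
filterDegs <- function(deg, fdrMax = 0.01, baseMeanMin = 100) {
  stopifnot(all(c("fdr", "base_mean") %in% names(deg)))
  deg[deg$fdr < fdrMax & deg$base_mean > baseMeanMin, , drop = FALSE]
}

#' Split significant DEGs by fold change
#'
#' Partitions a (filtered) DEG table into up-regulated (`FC > upFc`, i.e.
#' `log2fc > log2(upFc)`), down-regulated (`FC < downFc`) and
#' significant-but-unsplit genes whose fold change lies between the two
#' cutoffs.
#'
#' @param deg a DEG table with a `log2fc` column.
#' @param upFc,downFc fold-change cutoffs (defaults 2 and 0.5).
#' @return A list with data.frames `up`, `down` and `unsplit`.
#' @export
splitByFold <- function(deg, upFc = 2, downFc = 0.5) {
  stopifnot("log2fc" %in% names(deg))
  up <- deg$log2fc > log2(upFc)
  down <- deg$log2fc < log2(downFc)
  list(up = deg[up, , drop = FALSE],
       down = deg[down, , drop = FALSE],
       unsplit = deg[!up & !down, , drop = FALSE])
}

#' Deletion-region positive control
#'
#' Among deletion-region genes that reach significance, the fraction that
#' are down-regulated. For a hemizygous deletion every deletion-region gene
#' is expected to be down-regulated (~0.5-fold), so this fraction acts as a
#' positive control for the whole expression stage; a value below 1 flags
#' the offending genes.
#'
#' @param deg a full DEG table (unfiltered) with `gene_id`, `log2fc`,
#'   `fdr`, `base_mean`.
#' @param deletionIds character vector of deletion-region gene ids.
#' @param fdrMax,baseMeanMin significance thresholds (as in [filterDegs()]).
#' @return A list with `applicable` (FALSE when `deletionIds` is empty or
#'   none are present), `fraction` (NA when not applicable), `nSignificant`,
#'   `flagged` (significant deletion genes that are not down-regulated) and
#'   `table` (per-gene log2fc/fdr for all deletion genes found).
#' @export
deletionRegionCheck <- function(deg, deletionIds, fdrMax = 0.01,
                                baseMeanMin = 100) {
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(deg)))
  tab <- deg[deg$gene_id %in% deletionIds, , drop = FALSE]
  if (length(deletionIds) == 0L || nrow(tab) == 0L)
    return(list(applicable = FALSE, fraction = NA_real_, nSignificant = 0L,
                flagged = character(0), table = tab))
  sig <- filterDegs(tab, fdrMax, baseMeanMin)
  if (nrow(sig) == 0L)
    return(list(applicable = TRUE, fraction = NA_real_, nSignificant = 0L,
                flagged = character(0), table = tab))
  down <- sig$log2fc < 0
  list(applicable = TRUE, fraction = mean(down),
       nSignificant = nrow(sig),
       flagged = sig$gene_id[!down], table = tab)
}

#' PCA of samples on log-normalized counts
#'
#' Principal-component analysis of the samples on `log2(normalized count
#' + 1)`, genes centered. Reports per-component variance fractions (summing
#' to 1) and sample scores; with a strong group effect the first component
#' separates patient from control samples.
#'
#' @param counts count matrix or SummarizedExperiment (as in [nbDeTest()]).
#' @param groups optional group labels for the score table.
#' @return A list with `varianceFraction`, `scores` (samples x components,
#'   with a `group` column when available) and the `prcomp` object.
#' @export
pcaSamples <- function(counts, groups = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    groups <- groups %||% as.character(SummarizedExperiment::colData(counts)$group)
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  if (ncol(counts) < 3L) stop("need at least 3 samples")
  sf <- medianOfRatios(counts)
  lg <- log2(sweep(counts, 2L, sf, "/") + 1)
  x <- t(lg)                                  # samples x genes
  x <- x[, apply(x, 2L, stats::var) > 0, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as.data.frame(pc$x)
  if (!is.null(groups)) scores$group <- groups
  list(varianceFraction = vf, scores = scores, prcomp = pc)
}
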