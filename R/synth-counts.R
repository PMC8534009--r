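#' Simulate an RNA-seq count matrix with a down-regulated deletion block
#'
#' Draws negative-binomial gene-by-sample counts for a two-group (WT vs DEL)
#' design. Genes listed in `deletionGenes` form a hemizygous-deletion block
#' whose DEL-group mean is `deletionFc` times the WT mean (default 0.5, i.e.
#' true log2 fold change -1, the expectation for one lost gene copy). A
#' fraction `deFraction` of the remaining genes receive a random fold change
#' with `log2 FC ~ Normal(0, deLog2Sd)`; all other genes are null. Library
#' sizes vary by per-sample factors drawn uniformly from `libSizeRange`.
#'
#' @param nGenes total number of genes.
#' @param nPerGroup samples per group.
#' @param deletionGenes character vector of deletion-region gene ids (must be
#'   unique; may be empty). Ids not of the form `gene%04d` are appended to
#'   the gene universe.
#' @param deletionFc DEL/WT mean ratio for deletion genes, in (0, 1).
#' @param deFraction fraction of non-deletion genes with a true effect, in
#'   \[0, 1).
#' @param deLog2Sd SD of the log2 fold change of perturbed genes.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2), > 0.
#' @param baselineMeanlog,baselineSdlog log-normal parameters of baseline
#'   gene means (defaults give a median around 200 normalized counts, i.e.
#'   moderately expressed genes that pass typical expression filters).
#' @param deletionMeanlog,deletionSdlog log-normal parameters of the
#'   deletion-block baseline means; deletion-region positive controls are
#'   drawn well-expressed (median ~800) so they are not lost to expression
#'   filters.
#' @param libSizeRange range of per-sample library size factors.
#' @param seed integer seed.
#'
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `colData$group` (factor WT/DEL), and per-gene `rowData`
#'   columns `in_deletion` and `true_log2fc`.
#' @examples
#' se <- simulateCounts(nGenes = 50, deletionGenes = c("gene0001", "gene0002"),
#'                      seed = 1)
#' table(SummarizedExperiment::rowData(se)$in_deletion)
#' @export
simulateCounts <- function(nGenes = 1000, nPerGroup = 3,
                           deletionGenes = character(), deletionFc = 0.5,
                           deFraction = 0.3, deLog2Sd = 2, dispersion = 0.05,
                           baselineMeanlog = log(200), baselineSdlog = 1.2,
                           deletionMeanlog = log(800), deletionSdlog = 0.5,
                           libSizeRange = c(0.7, 1.4), seed = 1L) {
  if (anyDuplicated(deletionGenes))
    stop("'deletionGenes' must be unique")
  if (deletionFc <= 0 || deletionFc >= 1)
    stop("'deletionFc' must be in (0, 1)")
  if (deFraction < 0 || deFraction >= 1)
    stop("'deFraction' must be in [0, 1)")
  assertScalar(dispersion, "dispersion", positive = TRUE)
  set.seed(as.integer(seed))

  geneIds <- sprintf("gene%04d", seq_len(nGenes))
  extra <- setdiff(deletionGenes, geneIds)
  if (length(extra)) {
    # named deletion genes replace the first anonymous ids
    stopifnot(length(extra) <= nGenes)
    geneIds[seq_along(extra)] <- extra
  }
  inDel <- geneIds %in% deletionGenes

  mu0 <- stats::rlnorm(nGenes, baselineMeanlog, baselineSdlog)
  if (any(inDel))
    mu0[inDel] <- stats::rlnorm(sum(inDel), deletionMeanlog, deletionSdlog)
  l2fc <- numeric(nGenes)
  de <- !inDel & stats::runif(nGenes) < deFraction
  l2fc[de] <- stats::rnorm(sum(de), 0, deLog2Sd)
  l2fc[inDel] <- log2(deletionFc)

  n <- as.integer(nPerGroup)
  sf <- stats::runif(2L * n, libSizeRange[1L], libSizeRange[2L])
  muW <- outer(mu0, sf[seq_len(n)])
  muD <- outer(mu0 * 2^l2fc, sf[n + seq_len(n)])
  counts <- cbind(
    matrix(stats::rnbinom(nGenes * n, mu = muW, size = 1 / dispersion), nGenes),
    matrix(stats::rnbinom(nGenes * n, mu = muD, size = 1 / dispersion), nGenes))
  dimnames(counts) <- list(geneIds,
                           c(sprintf("WT_%d", seq_len(n)),
                             sprintf("DEL_%d", seq_len(n))))

  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      group = factor(rep(c("WT", "DEL"), each = n), levels = c("WT", "DEL")),
      size_factor_true = sf,
      row.names = colnames(counts)),
    rowData = S4Vectors::DataFrame(
      in_deletion = inDel, true_log2fc = l2fc, baseline_mean = mu0,
      row.names = geneIds))
}
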