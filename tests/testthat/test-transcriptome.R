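delIds <- sprintf("DELQ%02d", 1:25)

test_that("size factors are 1 for equal-depth libraries", {
  set.seed(1)
  mu <- stats::rlnorm(200, log(100), 1)
  counts <- sapply(1:6, function(i) stats::rpois(200, mu))
  rownames(counts) <- sprintf("g%03d", 1:200)
  deg <- nbDeTest(counts, rep(c("WT", "DEL"), each = 3))
  sf <- attr(deg, "sizeFactors")
  expect_equal(unname(sf), rep(1, 6), tolerance = 0.05)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
})

test_that("null data produce no excess of significant genes", {
  se <- simulateCounts(nGenes = 600, deletionGenes = character(),
                       deFraction = 0, seed = 42)
  deg <- nbDeTest(se)
  # BH at 0.01 controls the expected number of false positives tightly
  expect_lte(sum(deg$fdr < 0.01), 3)
  # raw p-values roughly uniform
  expect_lt(abs(mean(deg$pvalue < 0.05) - 0.05), 0.015)
})

test_that("planted deletion block is detected as down-regulated", {
  pw <- vapply(1:20, function(s) {
    deg <- nbDeTest(simulateCounts(nGenes = 1000, deletionGenes = delIds,
                                   seed = s))
    sub <- deg[deg$gene_id %in% delIds, ]
    mean(sub$fdr < 0.01 & sub$log2fc < 0)
  }, numeric(1))
  # at 3 samples/group and dispersion 0.05 the Wald test detects the
  # majority of the half-dosage block at FDR < 0.01
  expect_gte(mean(pw), 0.55)
  # every detected deletion gene goes in the down direction
  deg <- nbDeTest(simulateCounts(nGenes = 1000, deletionGenes = delIds,
                                 seed = 1))
  sub <- deg[deg$gene_id %in% delIds & deg$fdr < 0.01, ]
  expect_true(all(sub$log2fc < 0))
  # true log2 fold change of the block is -1 by construction
  se <- simulateCounts(nGenes = 200, deletionGenes = delIds, seed = 2)
  expect_equal(unique(SummarizedExperiment::rowData(se)$true_log2fc[
    SummarizedExperiment::rowData(se)$in_deletion]), -1)
})

test_that("generator marginals match specified means at large n", {
  se <- simulateCounts(nGenes = 60, nPerGroup = 3000, deFraction = 0,
                       libSizeRange = c(1, 1), seed = 7)
  cnt <- SummarizedExperiment::assay(se)
  mu0 <- SummarizedExperiment::rowData(se)$baseline_mean
  ratio <- rowMeans(cnt) / mu0
  expect_true(all(abs(ratio - 1) < 0.02))
})

test_that("DEG filtering applies the printed strict thresholds", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    base_mean = c(150, 50, 500, 100, 101),
                    log2fc = c(1, 1, 1, 1, 1),
                    fdr = c(0.005, 0.005, 0.02, 0.005, 0.01))
  expect_equal(filterDegs(tab)$gene_id, "a")      # bm > 100 & fdr < 0.01
  expect_equal(nrow(filterDegs(tab[0, ])), 0)
  expect_equal(nrow(filterDegs(tab, 1.0, 0)), 5)
  # boundary values are excluded by the strict inequalities
  expect_false("d" %in% filterDegs(tab)$gene_id)  # base_mean == 100
  expect_false("e" %in% filterDegs(tab)$gene_id)  # fdr == 0.01
})

test_that("fold-change split partitions into up, down and unsplit", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    log2fc = c(1.5, -1.5, 0.2))
  sp <- splitByFold(tab)
  expect_equal(sp$up$gene_id, "a")
  expect_equal(sp$down$gene_id, "b")
  expect_equal(sp$unsplit$gene_id, "c")

  flat <- data.frame(gene_id = letters[1:3], log2fc = c(0, 0, 0))
  sp0 <- splitByFold(flat)
  expect_equal(nrow(sp0$up) + nrow(sp0$down), 0)

  # filter -> split is idempotent and order-invariant
  se <- simulateCounts(nGenes = 400, deletionGenes = delIds, seed = 3)
  deg <- nbDeTest(se)
  sig <- filterDegs(deg)
  sp1 <- splitByFold(sig)
  expect_identical(splitByFold(filterDegs(sig))$up, sp1$up)
  perm <- sig[sample(nrow(sig)), ]
  expect_setequal(splitByFold(perm)$down$gene_id, sp1$down$gene_id)
})

test_that("planted up/down genes are recovered in the right split", {
  set.seed(5)
  nG <- 500
  ids <- sprintf("g%03d", 1:nG)
  l2 <- numeric(nG); l2[1:40] <- 2; l2[41:60] <- -2
  mu0 <- rep(400, nG)
  counts <- cbind(sapply(1:3, function(i) stats::rnbinom(nG, mu = mu0, size = 20)),
                  sapply(1:3, function(i) stats::rnbinom(nG, mu = mu0 * 2^l2,
                                                         size = 20)))
  rownames(counts) <- ids
  sig <- filterDegs(nbDeTest(counts, rep(c("WT", "DEL"), each = 3)))
  sp <- splitByFold(sig)
  expect_gt(sum(sp$up$gene_id %in% ids[1:40]), 30)
  expect_gt(sum(sp$down$gene_id %in% ids[41:60]), 15)
  expect_equal(sum(sp$up$gene_id %in% ids[41:60]), 0)
})

test_that("deletion-region positive control reports the down fraction", {
  se <- simulateCounts(nGenes = 600, deletionGenes = delIds, seed = 11)
  deg <- nbDeTest(se)
  dc <- deletionRegionCheck(deg, delIds)
  expect_true(dc$applicable)
  expect_equal(dc$fraction, 1.0)
  expect_gt(dc$nSignificant, 0)
  expect_length(dc$flagged, 0)

  dcNA <- deletionRegionCheck(deg, character())
  expect_false(dcNA$applicable)
  expect_true(is.na(dcNA$fraction))

  # negative control: an "up-regulated deletion gene" must be flagged
  degUp <- deg
  hit <- which(degUp$gene_id %in% delIds & degUp$fdr < 0.01)[1]
  degUp$log2fc[hit] <- 2
  dcUp <- deletionRegionCheck(degUp, delIds)
  expect_lt(dcUp$fraction, 1)
  expect_true(degUp$gene_id[hit] %in% dcUp$flagged)
})

test_that("sample PCA separates groups and normalizes variance fractions", {
  se <- simulateCounts(nGenes = 500, deletionGenes = delIds, deFraction = 0.4,
                       dispersion = 0.01, seed = 13)
  pca <- pcaSamples(se)
  expect_equal(sum(pca$varianceFraction), 1, tolerance = 1e-10)
  grp <- pca$scores$group
  pc1 <- pca$scores$PC1
  # the two groups lie on opposite sides of PC1 with positive margin
  expect_true(max(pc1[grp == "WT"]) < min(pc1[grp == "DEL"]) ||
              max(pc1[grp == "DEL"]) < min(pc1[grp == "WT"]))
  expect_gt(pca$varianceFraction[1], 0.5)

  # duplicated sample gets identical scores
  cnt <- SummarizedExperiment::assay(se)
  cnt2 <- cbind(cnt, dup = cnt[, 1])
  pca2 <- pcaSamples(cnt2)
  expect_equal(unname(unlist(pca2$scores[7, 1:6])),
               unname(unlist(pca2$scores[1, 1:6])), tolerance = 1e-8)

  expect_error(pcaSamples(cnt[, 1:2]), "at least 3")
})

test_that("log2 fold changes agree with an independent NB fit", {
  se <- simulateCounts(nGenes = 300, deletionGenes = delIds, seed = 17)
  deg <- nbDeTest(se)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    SummarizedExperiment::assay(se),
    S4Vectors::DataFrame(group = SummarizedExperiment::colData(se)$group),
    ~ group)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, contrast = c("group", "DEL", "WT"))
  keep <- deg$base_mean > 50
  expect_gt(stats::cor(deg$log2fc[keep], res$log2FoldChange[keep]), 0.95)
  # deletion block recovered as down by both routes
  both <- deg$gene_id %in% delIds
  expect_lt(max(res$log2FoldChange[both]), 0)
  expect_lt(max(deg$log2fc[both]), 0)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # worked case: universe 20, query 5, term 4, overlap 4
  uni <- sprintf("g%02d", 1:20)
  sets <- list(T1 = uni[1:4])
  r <- enrichHyper(uni[1:5], sets, universe = uni)
  expect_equal(r$p, 16 / 15504, tolerance = 1e-12)
  expect_equal(r$p, hyperEnumOracle(20, 4, 5, 4), tolerance = 1e-12)

  # empty term and zero overlap
  r0 <- enrichHyper(uni[1:5], list(T0 = character(), T2 = uni[10:12]),
                    universe = uni)
  expect_equal(r0$p[r0$term == "T0"], 1)
  expect_true(all(r0$p > 0 & r0$p <= 1))

  # exhaustive enumeration over random small cases
  set.seed(19)
  for (i in 1:10) {
    N <- sample(8:25, 1); K <- sample(1:(N - 2), 1); n <- sample(2:6, 1)
    uni <- sprintf("x%02d", 1:N)
    qs <- sample(uni, n)
    term <- uni[1:K]
    p <- enrichHyper(qs, list(T = term), universe = uni)$p
    k <- length(intersect(qs, term))
    expect_equal(p, hyperEnumOracle(N, K, n, k), tolerance = 1e-9)
  }
})

test_that("BH adjustment behaves as the hand-computed step-up", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  # monotone in raw p and never smaller than raw p (on enrichment output)
  se <- simulateCounts(nGenes = 200, deletionGenes = delIds, seed = 23)
  deg <- nbDeTest(se)
  ord <- order(deg$pvalue)
  expect_true(all(diff(deg$fdr[ord]) >= -1e-12))
  expect_true(all(deg$fdr >= deg$pvalue - 1e-12))
})

test_that("count input validation rejects malformed matrices", {
  se <- simulateCounts(nGenes = 50, seed = 1)
  cnt <- SummarizedExperiment::assay(se)
  expect_error(nbDeTest(cnt, rep(c("A", "B"), each = 3)), "WT and DEL")
  expect_error(nbDeTest(cnt, c("WT", "WT", "WT", "WT", "WT", "DEL")),
               ">= 2 samples")
  bad <- cnt; bad[1, 1] <- 1.5
  expect_error(nbDeTest(bad, rep(c("WT", "DEL"), each = 3)), "integers")
  expect_error(simulateCounts(deletionGenes = c("A", "A")), "unique")
})
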