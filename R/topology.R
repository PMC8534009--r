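#' Select the most informative centrality measure by PCA
#'
#' Runs a principal-component analysis on the normalized node x measure
#' score matrix and selects the measure with the largest absolute loading on
#' the first principal component, after sign-aligning PC1 so that it
#' correlates positively with degree. PC1 captures the dominant shared
#' "central vs peripheral" axis of the catalog, so the measure loading most
#' strongly on it is the one that best determines central nodes.
#'
#' @param cm a centrality matrix from [computeCentralities()] (>= 2
#'   measures, >= 3 nodes).
#' @return A list with `measure` (selected name), `loadings` (PC1 loadings,
#'   sign-aligned), `varianceFraction` per component, and `tied` (measures
#'   whose |loading| equals the maximum; ties are broken by catalog order).
#' @examples
#' g <- simulateNetwork(30, seed = 1)
#' selectInformativeMeasure(computeCentralities(g))$measure
#' @export
selectInformativeMeasure <- function(cm) {
  if (ncol(cm) < 2L || nrow(cm) < 3L)
    stop("need at least 2 measures and 3 nodes")
  if (all(apply(cm, 2L, stats::sd) == 0))
    stop("zero-variance centrality matrix")
  pc <- stats::prcomp(cm, center = TRUE, scale. = FALSE)
  load1 <- pc$rotation[, 1L]
  scores1 <- pc$x[, 1L]
  refCol <- if ("degree" %in% colnames(cm)) cm[, "degree"] else cm[, 1L]
  if (stats::sd(refCol) > 0) {
    al <- stats::cor(scores1, refCol)
    if (!is.na(al) && al < 0) load1 <- -load1
  }
  absLoad <- abs(load1)
  best <- max(absLoad)
  tied <- colnames(cm)[absLoad >= best - 1e-12]
  list(measure = tied[1L], loadings = load1,
       varianceFraction = pc$sdev^2 / sum(pc$sdev^2), tied = tied)
}

#' Ward clustering of nodes with silhouette-optimal k
#'
#' Agglomerative clustering (Ward's minimum-variance linkage on Euclidean
#' distances) of the rows of a centrality matrix; the number of clusters is
#' chosen as the k in `kRange` maximizing the mean silhouette width.
#'
#' @param cm numeric matrix of node scores (rows = nodes).
#' @param kRange candidate cluster counts, within 2..n-1.
#' @return A list of class `nodeClustering`: `labels` (named cluster
#'   assignment), `k`, `silhouette` (mean width per candidate k), `hclust`.
#' @export
clusterNodes <- function(cm, kRange = 2:min(8L, nrow(cm) - 1L)) {
  cm <- as.matrix(cm)
  n <- nrow(cm)
  if (n < 4L) stop("need at least 4 nodes")
  if (any(kRange < 2L | kRange > n - 1L))
    stop("'kRange' must lie within 2..n-1")
  d <- stats::dist(cm)
  if (all(d == 0)) stop("all rows identical: zero variance, nothing to cluster")
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- vapply(kRange, function(k) {
    lab <- stats::cutree(hc, k = k)
    if (length(unique(lab)) < 2L) return(NA_real_)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  k <- kRange[which.max(sil)]
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(cm) %||% as.character(seq_len(n))
  structure(list(labels = labels, k = k,
                 silhouette = stats::setNames(sil, kRange), hclust = hc),
            class = "nodeClustering")
}

#' Jaccard similarity of two clusterings
#'
#' Similarity on co-clustered node pairs: the number of pairs placed
#' together in both clusterings divided by the number of pairs placed
#' together in at least one. Two all-singleton clusterings (no co-clustered
#' pair in either) are identical and score 1.
#'
#' @param a,b cluster label vectors over the same nodes (same length;
#'   labelings may differ, only co-membership matters).
#' @return A number in \[0, 1\]; 1 iff the co-membership structures
#'   coincide.
#' @examples
#' jaccardClusterSimilarity(c(1, 1, 2, 2), c(1, 1, 1, 2))   # 1/3
#' @export
jaccardClusterSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have the same length")
  ut <- upper.tri(matrix(0, length(a), length(a)))
  coA <- outer(a, a, "==")[ut]
  coB <- outer(b, b, "==")[ut]
  union <- sum(coA | coB)
  if (union == 0L) return(1)
  sum(coA & coB) / union
}

#' Rank network nodes by an influence score
#'
#' Computes the centrality catalog, selects the most informative measure by
#' PCA (unless a measure is forced), and returns the nodes ranked by their
#' raw score on that measure, ties broken lexicographically by node id. The
#' top-ranked deletion-flagged node - the deletion-region gene contributing
#' most to the network - is recorded in the `topDeletionNode` attribute.
#'
#' @param net an [igraph::graph] with optional vertex attributes `log2fc`
#'   and `in_deletion`.
#' @param lambda diffusion-degree propagation weight.
#' @param measure force a catalog measure (e.g. `"diffusion_degree"`);
#'   `NULL` selects by PCA.
#' @return A data.frame (one row per node, ranked): `rank`, `node`,
#'   `score`, `measure`, `in_deletion`, `log2fc`; attribute
#'   `topDeletionNode` holds the highest-ranked deletion-flagged node (or
#'   NA if none is flagged).
#' @examples
#' g <- simulateNetwork(30, seed = 1)
#' head(rankNodes(g, measure = "diffusion_degree"), 3)
#' @export
rankNodes <- function(net, lambda = 1, measure = NULL) {
  cm <- computeCentralities(net, lambda = lambda)
  sel <- if (is.null(measure)) selectInformativeMeasure(cm)$measure
         else match.arg(measure, colnames(cm))
  raw <- attr(cm, "raw")
  nodes <- attr(cm, "nodes")
  score <- raw[, sel]

  vAttr <- function(attrName, default) {
    v <- igraph::vertex_attr(net, attrName)
    if (is.null(v)) return(rep(default, length(nodes)))
    names(v) <- igraph::V(net)$name %||% as.character(seq_along(v))
    v[nodes]
  }
  inDel <- vAttr("in_deletion", NA)
  l2fc <- vAttr("log2fc", NA_real_)

  ord <- order(-score, nodes)
  out <- data.frame(rank = seq_along(nodes), node = nodes[ord],
                    score = unname(score[ord]), measure = sel,
                    in_deletion = unname(inDel[ord]),
                    log2fc = unname(l2fc[ord]), row.names = NULL)
  topDel <- if (any(out$in_deletion %in% TRUE))
    out$node[which(out$in_deletion %in% TRUE)[1L]] else NA_character_
  attr(out, "topDeletionNode") <- topDel
  out
}
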