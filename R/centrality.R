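## Centrality catalog for undirected PPI networks. Standard measures are
## delegated to igraph; measures igraph does not provide (Katz, semi-local,
## leverage, lobby, Laplacian, diffusion degree) are implemented from their
## definitions on the adjacency matrix.

centralityCatalog <- c("degree", "closeness", "harmonic", "betweenness",
                       "eigenvector", "katz", "pagerank", "subgraph",
                       "semilocal", "leverage", "lobby", "laplacian",
                       "diffusion_degree")

#' Diffusion degree centrality
#'
#' The diffusion degree of a node v with propagation weight lambda is the
#' weighted degree of v plus the weighted degrees of its neighbors:
#' \deqn{DD(v) = \lambda\, d(v) + \sum_{u \in N(v)} \lambda\, d(u).}
#' It scores a node's capacity to seed a diffusion process: a node spreads
#' directly through its own links and indirectly through its neighbors'
#' links. Scaling lambda scales every score linearly, so rankings are
#' lambda-invariant.
#'
#' @param net an [igraph::graph] (undirected, simple).
#' @param lambda propagation weight (> 0, default 1).
#' @return Named numeric vector of scores.
#' @examples
#' star <- igraph::make_star(4, mode = "undirected")
#' diffusionDegree(star)   # hub 6, leaves 4
#' @export
diffusionDegree <- function(net, lambda = 1) {
  assertScalar(lambda, "lambda", positive = TRUE)
  d <- igraph::degree(net)
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  out <- lambda * d + lambda * as.numeric(A %*% d)
  names(out) <- igraph::V(net)$name %||% as.character(seq_along(d))
  out
}

# Katz centrality: x = sum_k a^k A^k 1, attenuation a set below the spectral
# radius bound.
katzCentrality <- function(A, attenuation = NULL) {
  n <- nrow(A)
  lamMax <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  a <- attenuation %||% (0.85 / max(lamMax, 1e-12))
  as.numeric(solve(diag(n) - a * A, rep(1, n))) - 1
}

# semi-local centrality: CL(v) = sum_{u in N(v)} sum_{w in N(u)} N2(w),
# N2(w) = number of nodes within distance <= 2 of w (excluding w)
semilocalCentrality <- function(A) {
  reach <- (A + A %*% A) > 0
  diag(reach) <- FALSE
  n2 <- rowSums(reach)
  q <- as.numeric(A %*% n2)
  as.numeric(A %*% q)
}

# leverage centrality: mean relative degree advantage over neighbors
leverageCentrality <- function(A) {
  d <- rowSums(A)
  n <- nrow(A)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    out[v] <- if (length(nb)) mean((d[v] - d[nb]) / (d[v] + d[nb])) else 0
  }
  out
}

# lobby index: largest k such that the node has >= k neighbors of degree >= k
lobbyIndex <- function(A) {
  d <- rowSums(A)
  vapply(seq_len(nrow(A)), function(v) {
    nd <- sort(d[A[v, ] > 0], decreasing = TRUE)
    if (!length(nd)) return(0)
    max(c(0, which(nd >= seq_along(nd))))
  }, numeric(1))
}

# Laplacian centrality via the closed form for the drop in Laplacian energy
# when removing v: d(v)^2 + d(v) + 2 * sum_{u in N(v)} d(u)
laplacianCentrality <- function(A) {
  d <- rowSums(A)
  d^2 + d + 2 * as.numeric(A %*% d)
}

#' Compute a catalog of centrality measures
#'
#' Evaluates a documented catalog of 13 node-centrality measures on an
#' undirected simple graph: degree, closeness, harmonic closeness,
#' betweenness, eigenvector, Katz, PageRank, subgraph centrality,
#' semi-local centrality, leverage centrality, lobby index, Laplacian
#' centrality and diffusion degree. If the graph is disconnected, the
#' analysis is restricted to the largest connected component (with a
#' warning), since shortest-path measures are undefined across components.
#'
#' @param net an [igraph::graph]; self-loops/multi-edges are removed.
#' @param lambda diffusion-degree propagation weight.
#' @param normalization column normalization of the returned matrix:
#'   `"zscore"` (default), `"minmax"` or `"none"`.
#' @param measures subset of the catalog to compute.
#' @return A nodes x measures numeric matrix (the normalized scores), with
#'   attributes `raw` (unnormalized matrix) and `nodes` (vertex names of
#'   the analyzed component).
#' @examples
#' g <- simulateNetwork(30, seed = 1)
#' cm <- computeCentralities(g)
#' colnames(cm)
#' @export
computeCentralities <- function(net, lambda = 1,
                                normalization = c("zscore", "minmax", "none"),
                                measures = centralityCatalog) {
  normalization <- match.arg(normalization)
  measures <- match.arg(measures, centralityCatalog, several.ok = TRUE)
  net <- igraph::simplify(net)
  comp <- igraph::components(net)
  if (comp$no > 1L) {
    warning("graph is disconnected; restricting to the largest connected ",
            "component (", max(comp$csize), " of ", igraph::vcount(net),
            " nodes)")
    net <- igraph::induced_subgraph(
      net, which(comp$membership == which.max(comp$csize)))
  }
  if (igraph::vcount(net) < 4L)
    stop("need a connected component with >= 4 nodes")
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  nodes <- igraph::V(net)$name %||% as.character(seq_len(nrow(A)))

  vals <- list(
    degree       = igraph::degree(net),
    closeness    = igraph::closeness(net, normalized = TRUE),
    harmonic     = igraph::harmonic_centrality(net, normalized = TRUE),
    betweenness  = igraph::betweenness(net),
    eigenvector  = igraph::eigen_centrality(net)$vector,
    katz         = katzCentrality(A),
    pagerank     = igraph::page_rank(net)$vector,
    subgraph     = igraph::subgraph_centrality(net),
    semilocal    = semilocalCentrality(A),
    leverage     = leverageCentrality(A),
    lobby        = lobbyIndex(A),
    laplacian    = laplacianCentrality(A),
    diffusion_degree = diffusionDegree(net, lambda)
  )
  raw <- sapply(vals[measures], as.numeric)
  rownames(raw) <- nodes
  if (anyNA(raw) || any(!is.finite(raw)))
    stop("a centrality measure produced non-finite values")

  m <- raw
  if (normalization == "zscore") {
    m <- apply(raw, 2L, function(x) {
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    })
  } else if (normalization == "minmax") {
    m <- apply(raw, 2L, function(x) {
      r <- diff(range(x))
      if (r == 0) rep(0, length(x)) else (x - min(x)) / r
    })
  }
  rownames(m) <- nodes
  attr(m, "raw") <- raw
  attr(m, "nodes") <- nodes
  attr(m, "lambda") <- lambda
  m
}
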