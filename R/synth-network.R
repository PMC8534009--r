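#' Simulate a protein-protein interaction network with node annotations
#'
#' Generates a connected, undirected, simple graph whose nodes carry the
#' annotations the topology stage consumes: an expression fold change
#' (`log2fc`, DEL/WT) and a deletion-region flag (`in_deletion`).
#'
#' Two wiring models are available. `"planted_hub"` builds a sparse
#' ring-plus-chords backbone and wires one designated node (the hub) to a
#' large fraction of the network, guaranteeing its degree is at least three
#' times the median degree - a known most-influential node for recovery
#' tests. `"preferential_attachment"` grows a scale-free-like graph
#' (Barabasi-Albert, via igraph) with no planted structure.
#'
#' @param nNodes number of nodes (>= 4).
#' @param model `"planted_hub"` or `"preferential_attachment"`.
#' @param hubId name of the planted hub node (planted_hub only); defaults to
#'   `"CRKL"`, flagged as a deletion-region gene.
#' @param nDeletion number of deletion-flagged nodes (including the hub for
#'   the planted-hub model).
#' @param hubWiring fraction of nodes the hub connects to (planted_hub).
#' @param chordProb probability of extra random backbone chords.
#' @param seed integer seed; generation is fully deterministic given it.
#'
#' @return An [igraph::graph] with vertex attributes `name`, `log2fc`,
#'   `in_deletion`.
#' @examples
#' g <- simulateNetwork(50, seed = 1)
#' igraph::vcount(g)
#' @export
simulateNetwork <- function(nNodes = 50,
                            model = c("planted_hub", "preferential_attachment"),
                            hubId = "CRKL", nDeletion = 5, hubWiring = 0.5,
                            chordProb = 0.04, seed = 1L) {
  model <- match.arg(model)
  if (nNodes < 4) stop("'nNodes' must be >= 4")
  set.seed(as.integer(seed))
  nodeNames <- sprintf("GENE%03d", seq_len(nNodes))

  if (model == "planted_hub") {
    nodeNames[1L] <- hubId
    # ring backbone keeps the graph connected; chords add degree variation
    edges <- cbind(seq_len(nNodes), c(seq_len(nNodes)[-1L], 1L))
    chord <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
    chord <- chord[abs(chord[, 1] - chord[, 2]) > 1 &
                     stats::runif(nrow(chord)) < chordProb, , drop = FALSE]
    # hub (node 1) wired to a large random subset
    nWire <- max(3L, ceiling(hubWiring * (nNodes - 1L)))
    wired <- sample(2:nNodes, nWire)
    edges <- rbind(edges, chord, cbind(1L, wired))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- nodeNames
    delIdx <- c(1L, sample(2:nNodes, max(0L, nDeletion - 1L)))
  } else {
    g <- igraph::sample_pa(nNodes, m = 2, directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- nodeNames
    delIdx <- sample(seq_len(nNodes), nDeletion)
  }

  l2fc <- stats::rnorm(nNodes, 0, 0.8)
  l2fc[delIdx] <- stats::rnorm(length(delIdx), -1, 0.2)
  igraph::V(g)$log2fc <- l2fc
  igraph::V(g)$in_deletion <- seq_len(nNodes) %in% delIdx
  g
}
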