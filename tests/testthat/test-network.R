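test_that("diffusion degree matches hand evaluation on canonical graphs", {
  star <- igraph::make_star(4, mode = "undirected")   # hub is vertex 1
  dd <- diffusionDegree(star, lambda = 1)
  expect_equal(unname(dd), c(6, 4, 4, 4))

  tri <- igraph::make_ring(3)
  expect_equal(unname(diffusionDegree(tri)), c(6, 6, 6))

  # lambda scales scores linearly; ranking invariant
  g <- simulateNetwork(20, seed = 2)
  expect_equal(diffusionDegree(g, 2.5), 2.5 * diffusionDegree(g, 1))
  expect_identical(order(-diffusionDegree(g, 2.5)),
                   order(-diffusionDegree(g, 1)))
  expect_error(diffusionDegree(g, 0), "positive")
})

test_that("diffusion degree equals the neighbor-degree-sum oracle exhaustively", {
  # all connected graphs on 4 and 5 vertices, by enumeration of edge subsets
  for (n in 4:5) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    m <- nrow(pairs)
    for (code in seq_len(2^m) - 1L) {
      bits <- as.integer(intToBits(code))[seq_len(m)]
      if (sum(bits) < n - 1) next
      A <- matrix(0L, n, n)
      A[pairs[bits == 1L, , drop = FALSE]] <- 1L
      A <- A + t(A)
      R <- diag(n) + A
      reach <- R
      for (i in seq_len(n - 1)) reach <- (reach %*% R > 0) * 1
      if (any(reach == 0)) next
      dd <- diffusionDegree(graphFromAdj(A), lambda = 1)
      expect_equal(unname(dd), oracleDiffusionDegree(A), tolerance = 1e-12)
    }
  }
  # random connected graphs on 6 vertices
  set.seed(31)
  for (i in 1:50) {
    A <- randomConnectedGraph(6)
    expect_equal(unname(diffusionDegree(graphFromAdj(A), 1.7)),
                 oracleDiffusionDegree(A, 1.7), tolerance = 1e-12)
  }
})

test_that("every catalog measure is maximal at the star hub and flat on cycles", {
  star <- igraph::make_star(6, mode = "undirected")
  cm <- computeCentralities(star, normalization = "none")
  for (msr in colnames(cm))
    expect_equal(unname(which.max(cm[, msr])), 1L, label = msr)

  ring <- igraph::make_ring(7)
  cmR <- computeCentralities(ring, normalization = "none")
  for (msr in colnames(cmR))
    expect_lt(diff(range(cmR[, msr])), 1e-8)
})

test_that("catalog measures agree with definition-level oracles on small graphs", {
  set.seed(33)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    A <- randomConnectedGraph(n)
    g <- graphFromAdj(A)
    cm <- computeCentralities(g, normalization = "none")
    raw <- attr(cm, "raw")
    expect_equal(unname(raw[, "degree"]), oracleDegree(A))
    expect_equal(unname(raw[, "closeness"]), oracleCloseness(A),
                 tolerance = 1e-9)
    expect_equal(unname(raw[, "harmonic"]), oracleHarmonic(A),
                 tolerance = 1e-9)
    expect_equal(unname(raw[, "betweenness"]), oracleBetweenness(A),
                 tolerance = 1e-9)
    expect_equal(unname(raw[, "eigenvector"]), oracleEigenvector(A),
                 tolerance = 1e-6)
    lamMax <- max(abs(eigen(A, symmetric = TRUE)$values))
    expect_equal(unname(raw[, "katz"]), oracleKatz(A, 0.85 / lamMax),
                 tolerance = 1e-8)
    expect_equal(unname(raw[, "pagerank"]), oraclePagerank(A),
                 tolerance = 1e-9)
    expect_equal(unname(raw[, "subgraph"]), oracleSubgraph(A),
                 tolerance = 1e-8)
    expect_equal(unname(raw[, "semilocal"]), oracleSemilocal(A))
    expect_equal(unname(raw[, "leverage"]), oracleLeverage(A),
                 tolerance = 1e-12)
    expect_equal(unname(raw[, "lobby"]), oracleLobby(A))
    expect_equal(unname(raw[, "laplacian"]), oracleLaplacian(A),
                 tolerance = 1e-6)
    expect_equal(unname(raw[, "diffusion_degree"]), oracleDiffusionDegree(A),
                 tolerance = 1e-12)
  }
})

test_that("disconnected graphs are restricted to the largest component", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_ring(3))
  igraph::V(g)$name <- letters[1:8]
  expect_warning(cm <- computeCentralities(g), "largest connected component")
  expect_equal(nrow(cm), 5)
})

test_that("PCA selects the only informative measure and reports ties", {
  set.seed(35)
  n <- 30
  deg <- stats::rpois(n, 5)
  cm <- cbind(degree = deg + stats::rnorm(n, 0, 0.1),
              flat1 = rep(0, n), flat2 = rep(0, n))
  sel <- selectInformativeMeasure(cm)
  expect_equal(sel$measure, "degree")

  cm2 <- cbind(a = deg, b = deg, c = stats::rnorm(n, 0, 0.01))
  sel2 <- selectInformativeMeasure(cm2)
  expect_equal(sel2$measure, "a")          # tie broken by column order
  expect_true(all(c("a", "b") %in% sel2$tied))

  expect_error(selectInformativeMeasure(matrix(1, 5, 3)), "zero-variance")
})

test_that("Ward clustering finds two planted blobs with silhouette-optimal k", {
  set.seed(37)
  cm <- rbind(matrix(stats::rnorm(40, 0, 0.2), 20, 2),
              matrix(stats::rnorm(40, 8, 0.2), 20, 2))
  rownames(cm) <- sprintf("n%02d", 1:40)
  cl <- clusterNodes(cm, kRange = 2:6)
  expect_equal(cl$k, 2)
  expect_equal(length(unique(cl$labels[1:20])), 1)
  expect_equal(length(unique(cl$labels[21:40])), 1)
  expect_error(clusterNodes(matrix(1, 10, 3)), "zero variance")

  # row permutation changes nothing up to relabeling
  perm <- sample(40)
  cl2 <- clusterNodes(cm[perm, ], kRange = 2:6)
  expect_equal(jaccardClusterSimilarity(cl2$labels[order(perm)], cl$labels), 1)
})

test_that("Jaccard clustering similarity counts co-membership pairs", {
  # pairs together in both: {(1,2)}; together in at least one:
  # {(1,2), (3,4), (1,3), (2,3)} -> 1/4
  expect_equal(jaccardClusterSimilarity(c(1, 1, 2, 2), c(1, 1, 1, 2)), 1 / 4)
  expect_equal(jaccardClusterSimilarity(c(1, 2, 1, 2), c(4, 3, 4, 3)), 1)
  expect_equal(jaccardClusterSimilarity(1:5, c(1, 1, 2, 2, 3)), 0)
  expect_equal(jaccardClusterSimilarity(1:4, 1:4), 1)   # both all-singleton
  # symmetry
  set.seed(39)
  a <- sample(3, 12, TRUE); b <- sample(3, 12, TRUE)
  expect_equal(jaccardClusterSimilarity(a, b), jaccardClusterSimilarity(b, a))
  expect_error(jaccardClusterSimilarity(1:3, 1:4), "same length")
})

test_that("node ranking recovers the planted hub and breaks ties by name", {
  g <- simulateNetwork(50, model = "planted_hub", hubId = "CRKL", seed = 41)
  expect_equal(unname(which.max(igraph::degree(g))),
               which(igraph::V(g)$name == "CRKL"))
  rk <- rankNodes(g, measure = "diffusion_degree")
  expect_equal(rk$node[1], "CRKL")
  expect_equal(attr(rk, "topDeletionNode"), "CRKL")

  # no deletion flags -> no highlight, ranking still complete
  g2 <- igraph::delete_vertex_attr(g, "in_deletion")
  rk2 <- rankNodes(g2, measure = "degree")
  expect_true(is.na(attr(rk2, "topDeletionNode")))
  expect_equal(nrow(rk2), igraph::vcount(g))

  # vertex-transitive graph: all scores tie, order is lexicographic
  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- c("E", "C", "A", "D", "B")
  rkR <- rankNodes(ring, measure = "degree")
  expect_equal(rkR$node, c("A", "B", "C", "D", "E"))
})

test_that("ranking is invariant under graph isomorphism", {
  g <- simulateNetwork(25, seed = 43)
  perm <- sample(25)
  g2 <- igraph::permute(g, perm)
  rk1 <- rankNodes(g, measure = "diffusion_degree")
  rk2 <- rankNodes(g2, measure = "diffusion_degree")
  expect_equal(rk1$node, rk2$node)
  expect_equal(rk1$score, rk2$score)
})

test_that("network generator is deterministic and plants a dominant hub", {
  a <- simulateNetwork(100, model = "preferential_attachment", seed = 5)
  b <- simulateNetwork(100, model = "preferential_attachment", seed = 5)
  expect_identical(igraph::as_edgelist(a), igraph::as_edgelist(b))
  expect_identical(igraph::V(a)$log2fc, igraph::V(b)$log2fc)

  for (s in 1:5) {
    g <- simulateNetwork(50, model = "planted_hub", seed = s)
    d <- igraph::degree(g)
    expect_gte(d[["CRKL"]], 3 * stats::median(d))
    expect_true(igraph::is_connected(g))
    expect_true(igraph::is_simple(g))
  }
  expect_error(simulateNetwork(3), ">= 4")
})
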