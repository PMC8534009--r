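# Independent, definition-level oracles used to validate the package
# implementations. These deliberately use brute force / dense enumeration /
# external integrators, never the code paths they check.

# --- two-compartment ODE oracle (piecewise high-accuracy integration with
#     instantaneous draw-and-replace events between intervals) -----------
odeTranswellOracle <- function(geom, pTrue, dt_out = NULL) {
  S <- membraneArea(geom); VL <- lowerVolume(geom); VU <- upperVolume(geom)
  Vs <- sampleVolume(geom)
  interval <- geom@sampleInterval * 60
  nDraw <- floor(geom@duration / geom@sampleInterval)
  deriv <- function(t, y, parms) {
    J <- pTrue * S * (y[1] - y[2])
    list(c(-J / VU, J / VL))
  }
  y <- c(CU = upperConc(geom), CL = 0)
  times <- 0; conc <- 0
  for (k in seq_len(nDraw)) {
    sol <- deSolve::ode(y, c(0, interval), deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
    y <- sol[nrow(sol), c("CU", "CL")]
    times <- c(times, k * geom@sampleInterval)
    conc <- c(conc, unname(y["CL"]))
    y["CL"] <- y["CL"] * (1 - Vs / VL)
  }
  transwellSeries(times, conc, geom, pTrue = pTrue)
}

# --- exact Wilcoxon signed-rank p by direct enumeration of sign vectors ---
wilcoxonEnumOracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  pLe <- mean(ws <= w + 1e-9)
  pGe <- mean(ws >= w - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

# --- dense profile resampling oracle: 0.1-px stepping along the normal ---
denseProfilePeak <- function(image, seg, pixelSize, lineLengthUm = 3,
                             linesPerJunction = 3) {
  len <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2)
  ux <- (seg$x1 - seg$x0) / len; uy <- (seg$y1 - seg$y0) / len
  offs <- seq(-lineLengthUm / 2, lineLengthUm / 2, by = 0.1 * pixelSize) /
    pixelSize
  fr <- seq_len(linesPerJunction) / (linesPerJunction + 1)
  prof <- rep(0, length(offs))
  for (f in fr) {
    cx <- seg$x0 + f * (seg$x1 - seg$x0)
    cy <- seg$y0 + f * (seg$y1 - seg$y0)
    v <- ibbb:::interp2(image, cx - offs * uy, cy + offs * ux)
    prof <- prof + v / linesPerJunction
  }
  max(prof, na.rm = TRUE)
}

# --- hypergeometric enrichment p by exhaustive enumeration of query sets --
hyperEnumOracle <- function(N, K, n, k) {
  # P(overlap >= k) when drawing n genes from a universe of N containing K
  # term genes: enumerate all C(N, n) draws is infeasible; instead sum the
  # exact pmf terms, which *is* the closed form - so enumerate combinations
  # only for tiny cases to stay independent.
  sets <- utils::combn(N, n)
  mean(colSums(sets <= K) >= k)   # term genes are 1..K
}

# --- small-graph utilities ------------------------------------------------
randomConnectedGraph <- function(n, p = 0.5) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.integer(stats::runif(length(up)) < p)
    A <- A + t(A)
    R <- diag(n) + A
    reach <- R
    for (i in seq_len(n)) reach <- (reach %*% R > 0) * 1
    if (all(reach > 0)) return(A)
  }
}

graphFromAdj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# definition-level centrality oracles on an adjacency matrix
oracleDegree <- function(A) rowSums(A)
oracleCloseness <- function(A) {
  D <- shortestPathsFW(A)
  (nrow(A) - 1) / rowSums(D)       # normalized closeness
}
oracleHarmonic <- function(A) {
  D <- shortestPathsFW(A)
  vapply(seq_len(nrow(A)), function(v)
    sum(1 / D[v, -v]) / (nrow(A) - 1), numeric(1))
}
shortestPathsFW <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}
oracleBetweenness <- function(A) {
  # enumerate all shortest paths by BFS-free brute force over simple paths
  n <- nrow(A)
  D <- shortestPathsFW(A)
  cnt <- matrix(0, n, n)        # number of shortest paths
  via <- array(0, c(n, n, n))   # shortest paths through v (v interior)
  allPaths <- function(path, target) {
    last <- path[length(path)]
    if (last == target) return(list(path))
    out <- list()
    for (nb in which(A[last, ] > 0)) {
      if (nb %in% path) next
      if (length(path) - 1 + 1 + D[nb, target] == D[path[1], target])
        out <- c(out, allPaths(c(path, nb), target))
    }
    out
  }
  bt <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- allPaths(s, t)
    if (!length(ps)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      frac <- mean(vapply(ps, function(p) v %in% p[-c(1, length(p))],
                          logical(1)))
      bt[v] <- bt[v] + frac
    }
  }
  bt
}
oracleEigenvector <- function(A) {
  # power iteration on A + I (same eigenvectors, strictly dominant
  # eigenvalue even for bipartite graphs)
  M <- A + diag(nrow(A))
  x <- rep(1, nrow(A))
  for (i in 1:5000) { x <- M %*% x; x <- x / sqrt(sum(x^2)) }
  x <- as.numeric(x)
  x / max(x)
}
oracleKatz <- function(A, a) {
  # truncated series sum_k a^k A^k 1
  x <- rep(0, nrow(A)); term <- rep(1, nrow(A))
  for (k in 1:5000) {
    term <- a * as.numeric(A %*% term)
    x <- x + term
    if (max(abs(term)) < 1e-14) break
  }
  x
}
oraclePagerank <- function(A, damping = 0.85) {
  n <- nrow(A)
  d <- rowSums(A)
  x <- rep(1 / n, n)
  for (i in 1:5000) {
    xn <- (1 - damping) / n + damping * as.numeric(t(A / d) %*% x)
    if (max(abs(xn - x)) < 1e-14) { x <- xn; break }
    x <- xn
  }
  x
}
oracleSubgraph <- function(A) {
  # matrix exponential by scaling-free series (small graphs only)
  n <- nrow(A)
  E <- diag(n); term <- diag(n)
  for (k in 1:200) {
    term <- term %*% A / k
    E <- E + term
  }
  diag(E)
}
oracleSemilocal <- function(A) {
  n <- nrow(A)
  D <- shortestPathsFW(A)
  N2 <- vapply(seq_len(n), function(w) sum(D[w, ] <= 2) - 1L, numeric(1))
  Q <- vapply(seq_len(n), function(u) sum(N2[which(A[u, ] > 0)]), numeric(1))
  vapply(seq_len(n), function(v) sum(Q[which(A[v, ] > 0)]), numeric(1))
}
oracleLeverage <- function(A) {
  d <- rowSums(A)
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] > 0)
    mean((d[v] - d[nb]) / (d[v] + d[nb]))
  }, numeric(1))
}
oracleLobby <- function(A) {
  d <- rowSums(A)
  vapply(seq_len(nrow(A)), function(v) {
    nd <- d[A[v, ] > 0]
    k <- 0
    while (sum(nd >= k + 1) >= k + 1) k <- k + 1
    k
  }, numeric(1))
}
oracleLaplacian <- function(A) {
  # Laplacian energy drop when deleting each vertex, computed literally
  energy <- function(M) {
    L <- diag(rowSums(M)) - M
    sum(eigen(L, symmetric = TRUE, only.values = TRUE)$values^2)
  }
  full <- energy(A)
  vapply(seq_len(nrow(A)), function(v)
    full - energy(A[-v, -v, drop = FALSE]), numeric(1))
}
oracleDiffusionDegree <- function(A, lambda = 1) {
  d <- rowSums(A)
  vapply(seq_len(nrow(A)), function(v)
    lambda * d[v] + sum(lambda * d[which(A[v, ] > 0)]), numeric(1))
}
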