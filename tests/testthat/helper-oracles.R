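# Independent brute-force oracles and small fixture builders. These
# deliberately use explicit loops / first-principles definitions so
# they share no code path with the package implementations they check.

# Explicit BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- (m / (i:m)) * ps[i:m]
    q[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Per-node Zi and Pi by explicit loops over modules and members.
bruteZiPi <- function(g, membership) {
  nodes <- igraph::V(g)$name
  mods <- unique(membership[nodes])
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  res <- data.frame(node = nodes, zi = NA_real_, pi = NA_real_,
                    stringsAsFactors = FALSE)
  kin <- setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    nb <- nodes[adj[v, ] > 0]
    kin[v] <- sum(membership[nb] == membership[v])
  }
  for (v in nodes) {
    members <- nodes[membership[nodes] == membership[v]]
    mu <- mean(kin[members])
    sdp <- sqrt(sum((kin[members] - mu)^2) / length(members))
    res$zi[res$node == v] <- if (sdp > 0) (kin[v] - mu) / sdp else 0
    k <- sum(adj[v, ])
    if (k == 0) { res$pi[res$node == v] <- 0; next }
    frac2 <- 0
    for (m in mods) {
      nb <- nodes[adj[v, ] > 0]
      kt <- sum(membership[nb] == m)
      frac2 <- frac2 + (kt / k)^2
    }
    res$pi[res$node == v] <- 1 - frac2
  }
  res
}

# All-pairs BFS shortest paths on an adjacency matrix.
bruteBFS <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (d[s, w] > depth) { d[s, w] <- depth; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# Topology metrics from first principles (diameter / mean path on the
# largest component; global transitivity as closed triplets ratio).
bruteTopology <- function(adj) {
  n <- nrow(adj)
  d <- bruteBFS(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1
    comp[is.finite(d[v, ])] <- cid
  }
  largest <- which(comp == which.max(tabulate(comp)))
  dl <- d[largest, largest, drop = FALSE]
  paths <- dl[upper.tri(dl)]
  triplets <- 0; closed <- 0
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) next
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a == b) next
      triplets <- triplets + 1
      if (adj[nb[a], nb[b]] > 0) closed <- closed + 1
    }
  }
  list(
    diameter = if (length(paths)) max(paths) else 0,
    average_path_length = if (length(paths)) mean(paths) else NA_real_,
    average_degree = sum(adj) / n,
    clustering_coefficient = if (triplets > 0) closed / triplets else 0)
}

# Elementwise Bray-Curtis between sample columns.
bruteBray <- function(v) {
  n <- ncol(v)
  d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(abs(v[, i] - v[, j])) / sum(v[, i] + v[, j])
  d
}

# Random simple graph with named vertices; guaranteed >= 1 edge.
randomTestGraph <- function(n, pEdge = 0.15) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(runif(n * (n - 1) / 2) < pEdge)
  if (sum(adj) == 0) adj[1, 2] <- 1L
  adj <- adj + t(adj)
  nm <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(nm, nm)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::E(g)$sign <- 1L
  igraph::E(g)$weight <- 1
  list(graph = g, adj = adj)
}

# Small helper: counts table wrapped in an AbundanceTable.
makeTable <- function(m, taxa = NULL, samples = NULL, ...) {
  if (is.null(taxa)) taxa <- sprintf("t%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(taxa, samples)
  AbundanceTable(m, ...)
}

# CoNetwork from an adjacency + optional membership, via the package
# constructor path used everywhere else in the suite.
networkFromAdj <- function(adj, membership = NULL) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::E(g)$sign <- 1L
  igraph::E(g)$weight <- 1
  net <- new("CoNetwork", graph = g,
             moduleOf = if (is.null(membership)) integer() else membership,
             detection = list())
  net
}
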