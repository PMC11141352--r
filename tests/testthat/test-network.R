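edgeFrame <- function(a, b, sign = 1L, weight = 0.8) {
  data.frame(taxon_a = as.character(a), taxon_b = as.character(b),
             sign = rep_len(sign, length(a)),
             weight = rep_len(weight, length(a)),
             stringsAsFactors = FALSE)
}

test_that("network construction dedupes, drops isolates, rejects self-loops", {
  e <- edgeFrame(c("a", "b", "c"), c("b", "c", "a"))
  net <- buildNetwork(e, allNodes = c("a", "b", "c", "d"))
  expect_equal(igraph::vcount(networkGraph(net)), 3)  # d isolated
  keep <- buildNetwork(e, allNodes = c("a", "b", "c", "d"),
                       dropIsolated = FALSE)
  expect_equal(igraph::vcount(networkGraph(keep)), 4)

  dup <- edgeFrame(c("a", "b"), c("b", "a"))
  expect_equal(igraph::ecount(networkGraph(buildNetwork(dup))), 1)

  expect_error(buildNetwork(edgeFrame("a", "a")), class = "mnInputError")
  expect_error(buildNetwork(edgeFrame("a", "z"), allNodes = c("a", "b")),
               class = "mnInputError")
  expect_warning(buildNetwork(edgeFrame(character(), character())),
                 "empty")
})

test_that("module detection separates two cliques joined by a bridge", {
  pairs <- t(combn(1:5, 2))
  e <- rbind(
    edgeFrame(sprintf("a%d", pairs[, 1]), sprintf("a%d", pairs[, 2])),
    edgeFrame(sprintf("b%d", pairs[, 1]), sprintf("b%d", pairs[, 2])),
    edgeFrame("a1", "b1"))
  net <- detectModules(buildNetwork(e))
  m <- moduleMembership(net)
  expect_identical(length(unique(m)), 2L)
  expect_identical(length(unique(m[sprintf("a%d", 1:5)])), 1L)
  expect_identical(length(unique(m[sprintf("b%d", 1:5)])), 1L)
  expect_false(m[["a1"]] == m[["b1"]])

  k5 <- edgeFrame(sprintf("k%d", pairs[, 1]), sprintf("k%d", pairs[, 2]))
  expect_identical(length(unique(moduleMembership(
    detectModules(buildNetwork(k5))))), 1L)
})

test_that("module detection is deterministic given algorithm and seed", {
  set.seed(21)
  rg <- randomTestGraph(40, 0.1)
  net <- new("CoNetwork", graph = rg$graph, moduleOf = integer(),
             detection = list())
  m1 <- moduleMembership(detectModules(net, "greedy", seed = 3))
  m2 <- moduleMembership(detectModules(net, "greedy", seed = 3))
  expect_identical(m1, m2)
  l1 <- moduleMembership(detectModules(net, "louvain", seed = 3))
  l2 <- moduleMembership(detectModules(net, "louvain", seed = 3))
  expect_identical(l1, l2)
})

test_that("zi/pi match the brute-force cartography oracle on random graphs", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(8:50, 1)
    rg <- randomTestGraph(n, runif(1, 0.08, 0.3))
    membership <- sample(1:sample(2:5, 1), n, replace = TRUE)
    names(membership) <- igraph::V(rg$graph)$name
    net <- networkFromAdj(rg$adj, membership)
    got <- ziPi(net)
    want <- bruteZiPi(rg$graph, membership)
    expect_lt(max(abs(got$zi - want$zi[match(got$node, want$node)])), 1e-12)
    expect_lt(max(abs(got$pi - want$pi[match(got$node, want$node)])), 1e-12)
    # internal consistency: per-module degree fractions sum to one
    expect_true(all(got$pi[got$degree > 0] <= 1 - 1 / got$degree[got$degree > 0] + 1e-12))
    expect_true(all(got$pi >= 0))
  }
})

test_that("zi/pi handle the textbook special cases", {
  # star inside one module: all 4 edges internal -> pi = 0
  e <- edgeFrame(rep("hub", 4), sprintf("leaf%d", 1:4))
  m <- setNames(rep(1L, 5), c("hub", sprintf("leaf%d", 1:4)))
  net0 <- buildNetwork(e)
  net <- new("CoNetwork", graph = networkGraph(net0),
             moduleOf = m[igraph::V(networkGraph(net0))$name],
             detection = list())
  r <- ziPi(net)
  expect_equal(r$pi[r$node == "hub"], 0)

  # 2/2 split across two modules -> pi = 0.5
  m2 <- setNames(c(1L, 1L, 1L, 2L, 2L), c("hub", "leaf1", "leaf2",
                                          "leaf3", "leaf4"))
  net2 <- new("CoNetwork", graph = networkGraph(net0),
              moduleOf = m2[igraph::V(networkGraph(net0))$name],
              detection = list())
  r2 <- ziPi(net2)
  expect_equal(r2$pi[r2$node == "hub"], 0.5)

  # equal within-module degree everywhere -> zi = 0 (sd = 0 convention)
  pairs <- t(combn(1:4, 2))
  k4 <- edgeFrame(sprintf("k%d", pairs[, 1]), sprintf("k%d", pairs[, 2]))
  netK <- detectModules(buildNetwork(k4))
  expect_true(all(ziPi(netK)$zi == 0))

  expect_error(ziPi(buildNetwork(k4)), class = "mnStateError")
})

test_that("role classification partitions the zi-pi plane as published", {
  probe <- data.frame(node = sprintf("p%d", 1:4),
                      zi = c(2, 2, 3, 3), pi = c(0.3, 0.7, 0.3, 0.7))
  got <- classifyRoles(probe)
  expect_identical(as.character(got$category),
                   c("peripheral", "connector", "module_hub", "network_hub"))
  expect_identical(got$is_keystone, c(FALSE, TRUE, TRUE, TRUE))

  # all-low input: everyone peripheral; categories always partition
  set.seed(23)
  low <- data.frame(node = sprintf("n%d", 1:30),
                    zi = runif(30, -2, 2.4), pi = runif(30, 0, 0.61))
  gotLow <- classifyRoles(low)
  expect_true(all(gotLow$category == "peripheral"))
  expect_identical(sum(table(gotLow$category)), 30L)

  # boundary values fall on the hub/connector side
  edge <- classifyRoles(data.frame(node = "x", zi = 2.5, pi = 0.62))
  expect_identical(as.character(edge$category), "network_hub")
})

test_that("topology summary equals the brute-force BFS oracle", {
  # path graph P4: diameter 3, average degree 1.5
  p4 <- edgeFrame(c("n1", "n2", "n3"), c("n2", "n3", "n4"))
  topo <- topologySummary(buildNetwork(p4))
  expect_identical(topo$diameter, 3L)
  expect_equal(topo$average_degree, 1.5)
  expect_equal(topo$average_path_length, (1 + 1 + 1 + 2 + 2 + 3) / 6)

  # K4: complete, all positive
  pairs <- t(combn(1:4, 2))
  k4 <- topologySummary(buildNetwork(
    edgeFrame(sprintf("n%d", pairs[, 1]), sprintf("n%d", pairs[, 2]))))
  expect_identical(k4$n_edges, 6L)
  expect_identical(k4$n_negative_edges, 0L)
  expect_equal(k4$average_path_length, 1)
  expect_equal(k4$clustering_coefficient, 1)

  set.seed(24)
  for (i in 1:25) {
    rg <- randomTestGraph(sample(10:50, 1), runif(1, 0.05, 0.3))
    net <- networkFromAdj(rg$adj)
    got <- topologySummary(net)
    want <- bruteTopology(rg$adj)
    expect_identical(got$diameter, as.integer(want$diameter))
    expect_equal(got$average_path_length, want$average_path_length)
    expect_equal(got$average_degree, want$average_degree)
    expect_equal(got$clustering_coefficient, want$clustering_coefficient)
    expect_identical(got$n_positive_edges + got$n_negative_edges,
                     got$n_edges)
  }
  expect_error(
    topologySummary(suppressWarnings(
      buildNetwork(edgeFrame(character(), character())))),
    class = "mnDegenerateResultError")
})

test_that("per-sample subnetworks are induced subgraphs on detected taxa", {
  m <- rbind(A = c(3, 0), B = c(2, 5), C = c(0, 4))
  colnames(m) <- c("s1", "s2")
  tab <- AbundanceTable(m)
  e <- edgeFrame(c("A", "B"), c("B", "C"))
  net <- detectModules(buildNetwork(e))

  s1 <- sampleSubnetwork(net, tab, "s1")       # A, B present
  expect_setequal(igraph::V(networkGraph(s1))$name, c("A", "B"))
  expect_equal(igraph::ecount(networkGraph(s1)), 1)
  expect_identical(moduleMembership(s1)[["A"]],
                   moduleMembership(net)[["A"]])

  # sample with every networked taxon gives the full network back
  m2 <- cbind(m, s3 = c(1, 1, 1))
  full <- sampleSubnetwork(detectModules(buildNetwork(e)),
                           AbundanceTable(m2), "s3")
  expect_equal(igraph::ecount(networkGraph(full)), 2)

  # sample sharing no taxa -> empty subnetwork, flagged
  m3 <- rbind(m2, Z = c(0, 0, 1))
  netZ <- buildNetwork(edgeFrame("A", "B"))
  m4 <- m3[, "s1", drop = FALSE]; m4["A", ] <- 0; m4["B", ] <- 0
  m4["C", 1] <- 1
  expect_warning(sub <- sampleSubnetwork(netZ, AbundanceTable(m4), "s1"),
                 "no taxa")
  expect_equal(igraph::vcount(networkGraph(sub)), 0)

  expect_error(sampleSubnetwork(net, tab, "nope"), class = "mnKeyError")
})

test_that("graph export round-trips through GraphML and writes valid GEXF", {
  sim <- simulateCorrelatedCommunity(nTaxa = 20, samplesPerGroup = 5,
                                     loading = 0.9, noiseSd = 0.3,
                                     zeroInflation = 0, seed = 9)
  edges <- thresholdEdges(spearmanAssociation(sim$table),
                          edgeCriteria(0.6, 0.05))
  net <- detectModules(buildNetwork(edges))
  roles <- classifyRoles(ziPi(net))

  gml <- withr::local_tempfile(fileext = ".graphml")
  exportGraph(net, gml, roles = roles, format = "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(networkGraph(net))$name)
  expect_equal(igraph::ecount(back), igraph::ecount(networkGraph(net)))
  expect_equal(sort(igraph::E(back)$sign),
               sort(igraph::E(networkGraph(net))$sign))
  expect_setequal(igraph::V(back)$category, roles$category)

  gexf <- withr::local_tempfile(fileext = ".gexf")
  exportGraph(net, gexf, roles = roles, format = "gexf")
  doc <- xml2::read_xml(gexf)   # throws if malformed
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)),
               igraph::vcount(networkGraph(net)))
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)),
               igraph::ecount(networkGraph(net)))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  exportGraph(net, tsv, format = "edge-tsv")
  df <- read.delim(tsv)
  expect_equal(nrow(df), igraph::ecount(networkGraph(net)))
  expect_true(all(c("taxon_a", "taxon_b", "sign", "weight") %in% names(df)))

  # export with no roles still succeeds
  bare <- withr::local_tempfile(fileext = ".graphml")
  expect_silent(exportGraph(net, bare, format = "graphml"))
})
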