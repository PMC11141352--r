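## Co-occurrence graph construction, module detection, Zi-Pi node-role
## cartography (the keystone definition lives here), topology summaries,
## per-sample induced subnetworks and Gephi-compatible export.

#' Build a co-occurrence network from a signed edge list
#'
#' @param edges data.frame from \code{\link{thresholdEdges}} (columns
#'   taxon_a, taxon_b, sign, weight; rho/p/q carried along when
#'   present). Duplicate unordered pairs are collapsed to one edge.
#' @param allNodes node universe; edge endpoints must be a subset.
#' @param dropIsolated drop nodes with no retained edge (default, the
#'   usual co-occurrence practice); set \code{FALSE} to keep them as
#'   isolates.
#' @return A \code{\link{CoNetwork}} with modules unset. An empty
#'   result (no nodes) is allowed but flagged by a warning.
#' @export
buildNetwork <- function(edges, allNodes = NULL, dropIsolated = TRUE) {
  if (!is.data.frame(edges) ||
      !all(c("taxon_a", "taxon_b") %in% names(edges)))
    mnStop("mnInputError", "'edges' must have taxon_a/taxon_b columns")
  if (nrow(edges) && any(edges$taxon_a == edges$taxon_b))
    mnStop("mnInputError", "self-loops are not allowed in the edge input")
  if (is.null(allNodes))
    allNodes <- unique(c(edges$taxon_a, edges$taxon_b))
  if (nrow(edges) &&
      !all(c(edges$taxon_a, edges$taxon_b) %in% allNodes))
    mnStop("mnInputError", "edge endpoints outside 'allNodes'")
  ## collapse duplicate unordered pairs
  if (nrow(edges)) {
    key <- ifelse(edges$taxon_a < edges$taxon_b,
                  paste(edges$taxon_a, edges$taxon_b),
                  paste(edges$taxon_b, edges$taxon_a))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(allNodes), name = as.character(allNodes))
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$taxon_a, edges$taxon_b))
    igraph::E(g)$sign <- if ("sign" %in% names(edges)) edges$sign else 1L
    igraph::E(g)$weight <- if ("weight" %in% names(edges))
      edges$weight else 1
    if ("rho" %in% names(edges)) igraph::E(g)$rho <- edges$rho
  }
  if (dropIsolated) {
    iso <- igraph::V(g)[igraph::degree(g) == 0]
    g <- igraph::delete_vertices(g, iso)
  }
  if (igraph::vcount(g) == 0)
    warning("network is empty (no nodes after construction)")
  new("CoNetwork", graph = g, moduleOf = integer(), detection = list())
}

## igraph treats a 'weight' edge attribute as meaningful in several
## algorithms; strip it so clustering/topology run on the unweighted
## skeleton.
stripWeights <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g))
    igraph::delete_edge_attr(g, "weight") else g
}

#' Detect modules by modularity-based clustering
#'
#' Greedy modularity maximisation (deterministic; igraph's
#' \code{cluster_fast_greedy}) by default, or multi-level Louvain
#' behind a seed. Modularity assumes an edge signals affinity, so by
#' default clustering runs on the subgraph of positive
#' (co-occurrence) edges; negative (co-exclusion) edges stay in the
#' network but do not bind nodes into a module. Nodes left without a
#' positive edge, like isolated nodes, end up in singleton modules.
#' The result is deterministic given \code{(algorithm, seed)}.
#'
#' @param net a \code{\link{CoNetwork}}.
#' @param algorithm \code{"greedy"} or \code{"louvain"}.
#' @param seed RNG seed (only consulted by Louvain).
#' @param signAware cluster on positive edges only (default); set
#'   \code{FALSE} to cluster on the full unsigned skeleton.
#' @return The network with \code{moduleOf} filled in and the achieved
#'   modularity recorded in its \code{detection} slot.
#' @export
detectModules <- function(net, algorithm = c("greedy", "louvain"),
                          seed = 1L, signAware = TRUE) {
  stopifnot(is(net, "CoNetwork"))
  algorithm <- match.arg(algorithm)
  g <- net@graph
  if (igraph::vcount(g) == 0)
    mnStop("mnDegenerateResultError", "cannot detect modules in an empty graph")
  ## cluster on the unweighted skeleton; weights are attributes
  gs <- stripWeights(g)
  if (signAware && igraph::ecount(gs) &&
      "sign" %in% igraph::edge_attr_names(gs))
    gs <- igraph::delete_edges(gs, igraph::E(gs)[igraph::E(gs)$sign < 0])
  memb <- withSeed(seed, {
    if (algorithm == "greedy") {
      comm <- igraph::cluster_fast_greedy(gs)
      ## cut the merge tree at the maximum-modularity step explicitly:
      ## the default cut can stop one merge short on modularity ties
      igraph::cut_at(comm, steps = which.max(comm$modularity) - 1L)
    } else {
      igraph::membership(igraph::cluster_louvain(gs))
    }
  })
  moduleOf <- as.integer(memb)
  names(moduleOf) <- igraph::V(g)$name
  mod <- igraph::modularity(gs, memb)
  new("CoNetwork", graph = g, moduleOf = moduleOf,
      detection = list(algorithm = algorithm, seed = as.integer(seed),
                       modularity = mod))
}

#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' For node i in module s, \code{Zi = (k_is - mean(k_js)) / sd(k_js)}
#' where \code{k_js} is the within-module degree of each member j of s
#' and the standard deviation is the population sd over s's members
#' (\code{sd = 0} gives \code{Zi = 0}). \code{Pi = 1 - sum_t (k_it /
#' k_i)^2} over all modules t; isolated nodes get \code{Pi = 0}.
#'
#' @param net a \code{\link{CoNetwork}} with modules assigned.
#' @return A \code{data.frame}: node, module, degree, zi, pi.
#' @seealso \code{\link{classifyRoles}}
#' @export
ziPi <- function(net) {
  stopifnot(is(net, "CoNetwork"))
  if (!length(net@moduleOf))
    mnStop("mnStateError", "run detectModules() before ziPi()")
  g <- net@graph
  nodes <- igraph::V(g)$name
  memb <- net@moduleOf[nodes]
  k <- igraph::degree(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  ## k_it: edges from node i into module t, via adjacency x indicator
  modLevels <- sort(unique(memb))
  ind <- outer(memb, modLevels, "==") + 0
  kTo <- as.matrix(adj %*% ind)           # nodes x modules
  colnames(kTo) <- modLevels
  kIn <- kTo[cbind(seq_along(nodes), match(memb, modLevels))]
  zi <- numeric(length(nodes))
  for (m in modLevels) {
    members <- which(memb == m)
    mu <- mean(kIn[members])
    sdPop <- sqrt(mean((kIn[members] - mu)^2))
    zi[members] <- if (sdPop > 0) (kIn[members] - mu) / sdPop else 0
  }
  pi <- ifelse(k > 0, 1 - rowSums((kTo / pmax(k, 1))^2), 0)
  data.frame(node = nodes, module = as.integer(memb),
             degree = as.integer(k), zi = zi, pi = as.numeric(pi),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify node roles on the Zi-Pi plane
#'
#' Four categories: peripheral (low Zi, low Pi), connector (low Zi,
#' high Pi), module hub (high Zi, low Pi) and network hub (high Zi,
#' high Pi), at the conventional thresholds Zi 2.5 and Pi 0.62.
#' Boundary values count as the hub/connector side so the partition is
#' total. Keystone nodes are all non-peripheral nodes (connectors,
#' module hubs and network hubs).
#'
#' @param roles data.frame from \code{\link{ziPi}}.
#' @param ziThreshold,piThreshold classification thresholds.
#' @return The input with \code{category} (factor) and
#'   \code{is_keystone} columns added.
#' @export
classifyRoles <- function(roles, ziThreshold = 2.5, piThreshold = 0.62) {
  stopifnot(is.data.frame(roles), all(c("zi", "pi") %in% names(roles)))
  hub <- roles$zi >= ziThreshold
  conn <- roles$pi >= piThreshold
  cat <- ifelse(hub & conn, "network_hub",
         ifelse(hub, "module_hub",
         ifelse(conn, "connector", "peripheral")))
  roles$category <- factor(cat, levels = c("peripheral", "connector",
                                           "module_hub", "network_hub"))
  roles$is_keystone <- roles$category != "peripheral"
  roles
}

#' Topology summary of a co-occurrence network
#'
#' Node/edge counts split by sign, average degree, diameter and
#' average path length (unweighted, on the largest connected
#' component), global clustering coefficient, and the modularity and
#' module count of the stored partition (NA when modules are unset).
#'
#' @param net a \code{\link{CoNetwork}}.
#' @return One-row \code{data.frame}.
#' @export
topologySummary <- function(net) {
  stopifnot(is(net, "CoNetwork"))
  g <- net@graph
  if (igraph::vcount(g) == 0)
    mnStop("mnDegenerateResultError", "empty graph has no topology")
  gs <- stripWeights(g)  # unweighted skeleton
  s <- if (igraph::ecount(g)) igraph::E(g)$sign else integer()
  comps <- igraph::components(gs)
  lcc <- igraph::induced_subgraph(
    gs, which(comps$membership == which.max(comps$csize)))
  nE <- igraph::ecount(g)
  data.frame(
    n_nodes = as.integer(igraph::vcount(g)),
    n_edges = as.integer(nE),
    n_positive_edges = as.integer(sum(s > 0)),
    n_negative_edges = as.integer(sum(s < 0)),
    average_degree = 2 * nE / igraph::vcount(g),
    diameter = if (igraph::vcount(lcc) > 1)
      as.integer(igraph::diameter(lcc, weights = NA)) else 0L,
    average_path_length = if (igraph::vcount(lcc) > 1)
      igraph::mean_distance(lcc, weights = NA) else NA_real_,
    clustering_coefficient = {
      cc <- igraph::transitivity(gs, type = "global")
      if (is.nan(cc)) 0 else cc
    },
    modularity = if (length(net@moduleOf))
      igraph::modularity(gs, net@moduleOf[igraph::V(g)$name])
      else NA_real_,
    n_modules = if (length(net@moduleOf))
      length(unique(net@moduleOf)) else NA_integer_,
    stringsAsFactors = FALSE)
}

#' Induced subnetwork for one sample
#'
#' Restricts the network to the taxa detected (abundance > 0) in a
#' given sample; module labels are inherited from the full network.
#'
#' @param net a \code{\link{CoNetwork}}.
#' @param table the \code{AbundanceTable} the network was built from.
#' @param sampleId sample to extract.
#' @return A \code{\link{CoNetwork}} on the present taxa.
#' @export
sampleSubnetwork <- function(net, table, sampleId) {
  stopifnot(is(net, "CoNetwork"), is(table, "AbundanceTable"))
  if (!sampleId %in% sampleIds(table))
    mnStop("mnKeyError", sprintf("unknown sample '%s'", sampleId))
  present <- taxonIds(table)[abundances(table)[, sampleId] > 0]
  keep <- intersect(igraph::V(net@graph)$name, present)
  sub <- igraph::induced_subgraph(net@graph, keep)
  if (igraph::vcount(sub) == 0)
    warning(sprintf("sample '%s' shares no taxa with the network", sampleId))
  moduleOf <- if (length(net@moduleOf)) net@moduleOf[keep] else integer()
  if (length(moduleOf)) names(moduleOf) <- keep
  new("CoNetwork", graph = sub, moduleOf = moduleOf,
      detection = net@detection)
}

#' Export a network for Gephi or downstream tools
#'
#' Serialises nodes with module / Zi / Pi / category / taxonomy
#' attributes (when available) and edges with sign and weight, as
#' GraphML, GEXF, or a long-format edge TSV.
#'
#' @param net a \code{\link{CoNetwork}}.
#' @param path output file.
#' @param roles optional data.frame from \code{\link{classifyRoles}}.
#' @param format \code{"graphml"}, \code{"gexf"} or \code{"edge-tsv"}.
#' @param taxonomy optional named lineage vector to attach per node.
#' @return \code{path}, invisibly.
#' @export
exportGraph <- function(net, path, roles = NULL,
                        format = c("graphml", "gexf", "edge-tsv"),
                        taxonomy = NULL) {
  stopifnot(is(net, "CoNetwork"))
  format <- match.arg(format)
  g <- net@graph
  nodes <- igraph::V(g)$name
  if (length(net@moduleOf))
    igraph::V(g)$module <- as.integer(net@moduleOf[nodes])
  if (!is.null(roles)) {
    i <- match(nodes, roles$node)
    igraph::V(g)$zi <- roles$zi[i]
    igraph::V(g)$pi <- roles$pi[i]
    if ("category" %in% names(roles))
      igraph::V(g)$category <- as.character(roles$category[i])
  }
  if (!is.null(taxonomy) && length(taxonomy)) {
    tx <- taxonomy[nodes]
    tx[is.na(tx)] <- ""
    igraph::V(g)$taxonomy <- unname(tx)
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "gexf") {
    writeGexf(g, path)
  } else {
    el <- igraph::as_edgelist(g)
    df <- data.frame(taxon_a = el[, 1], taxon_b = el[, 2],
                     sign = if (igraph::ecount(g)) igraph::E(g)$sign
                            else integer(),
                     weight = if (igraph::ecount(g)) igraph::E(g)$weight
                              else numeric(),
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

## Minimal GEXF 1.2 writer: node attvalues for whatever vertex
## attributes are set, edge weight plus a 'sign' attvalue.
writeGexf <- function(g, path) {
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  vAttrs <- setdiff(igraph::vertex_attr_names(g), "name")
  if (length(vAttrs)) {
    attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
    for (i in seq_along(vAttrs)) {
      type <- if (is.numeric(igraph::vertex_attr(g, vAttrs[i])))
        "double" else "string"
      xml2::xml_add_child(attrs, "attribute", id = as.character(i - 1L),
                          title = vAttrs[i], type = type)
    }
  }
  eAttrs <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eAttrs, "attribute", id = "sign", title = "sign",
                      type = "integer")
  nodesEl <- xml2::xml_add_child(graph, "nodes")
  for (v in seq_len(igraph::vcount(g))) {
    nd <- xml2::xml_add_child(nodesEl, "node",
      id = igraph::V(g)$name[v], label = igraph::V(g)$name[v])
    if (length(vAttrs)) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (i in seq_along(vAttrs)) {
        val <- igraph::vertex_attr(g, vAttrs[i], v)
        if (!is.na(val))
          xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1L),
                              value = as.character(val))
      }
    }
  }
  edgesEl <- xml2::xml_add_child(graph, "edges")
  if (igraph::ecount(g)) {
    el <- igraph::as_edgelist(g)
    for (e in seq_len(nrow(el))) {
      ed <- xml2::xml_add_child(edgesEl, "edge", id = as.character(e - 1L),
        source = el[e, 1], target = el[e, 2],
        weight = as.character(igraph::E(g)$weight[e]))
      av <- xml2::xml_add_child(ed, "attvalues")
      xml2::xml_add_child(av, "attvalue", `for` = "sign",
                          value = as.character(igraph::E(g)$sign[e]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a node-role table as TSV
#'
#' @param roles data.frame from \code{\link{classifyRoles}}.
#' @param path output path.
#' @export
writeNodeRoles <- function(roles, path) {
  write.table(roles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
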