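## Config-driven orchestration: filter -> diversity -> association ->
## network -> roles -> topology -> multivariate, writing a structured
## results directory with a log, seeds and the resolved configuration.

#' Assemble and validate a pipeline run configuration
#'
#' Every tunable of the pipeline in one validated list. Per-kingdom
#' presets for the edge criteria are available through
#' \code{preset}; explicit \code{criteria} wins over \code{preset}.
#'
#' @param tablePath,metadataPath input TSV paths (must exist).
#' @param outDir results directory (created on run).
#' @param kingdom free-text label recorded in outputs.
#' @param preset optional \code{\link{edgeCriteriaPreset}} name.
#' @param criteria optional explicit \code{\link{EdgeCriteria}}.
#' @param minMeanRel mean relative-abundance filter threshold.
#' @param moduleAlgorithm \code{"greedy"} or \code{"louvain"}.
#' @param ziThreshold,piThreshold role-classification thresholds.
#' @param nPerm permutation count for PERMANOVA/Mantel.
#' @param seed master seed; all stage seeds derive from it.
#' @return A validated \code{RunConfig} list.
#' @export
makeRunConfig <- function(tablePath, metadataPath, outDir,
                          kingdom = "bacteria", preset = kingdom,
                          criteria = NULL, minMeanRel = 1e-4,
                          moduleAlgorithm = "greedy",
                          ziThreshold = 2.5, piThreshold = 0.62,
                          nPerm = 999, seed = 1L) {
  for (p in c(tablePath, metadataPath))
    if (!file.exists(p))
      mnStop("mnFormatError", sprintf("input file not found: %s", p))
  if (is.null(criteria)) {
    criteria <- if (!is.null(preset) &&
                    preset %in% c("bacteria", "fungi", "archaea"))
      edgeCriteriaPreset(preset) else edgeCriteria()
  }
  validObject(criteria)
  cfg <- list(tablePath = tablePath, metadataPath = metadataPath,
              outDir = outDir, kingdom = kingdom,
              rCutoff = criteria@rCutoff, sigCutoff = criteria@sigCutoff,
              useFdr = criteria@useFdr, minMeanRel = minMeanRel,
              moduleAlgorithm = match.arg(moduleAlgorithm,
                                          c("greedy", "louvain")),
              ziThreshold = ziThreshold, piThreshold = piThreshold,
              nPerm = as.integer(nPerm), seed = as.integer(seed))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

## Stage seeds derive deterministically from the master seed and are
## logged; kept well below 2^31.
stageSeed <- function(cfg, offset) (cfg$seed * 97L + offset) %% 1000000007L

#' Run the full co-occurrence pipeline
#'
#' Reads the table and metadata, filters low-abundance taxa, computes
#' alpha diversity, builds the Spearman/FDR network, detects modules,
#' classifies Zi-Pi roles, summarises topology, and runs the
#' Bray-Curtis multivariate stage (PERMANOVA; Mantel against the
#' Euclidean distance of scaled metadata covariates when covariates
#' are present; NMDS). All artifacts, a log and the resolved config are
#' written under \code{cfg$outDir}. With fixed seeds a rerun is
#' byte-identical. An empty network (e.g. a cutoff of 1 on noise) is a
#' logged degenerate outcome, not an error: roles and topology are
#' skipped.
#'
#' @param cfg a \code{RunConfig} from \code{\link{makeRunConfig}}.
#' @return Invisibly, a list with the in-memory stage results and
#'   \code{status} (\code{"ok"} or \code{"degenerate"}).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$outDir, "pipeline.log")
  logLines <- character()
  say <- function(fmt, ...) {
    logLines <<- c(logLines, sprintf(fmt, ...))
  }
  status <- "ok"

  say("stage=config kingdom=%s rCutoff=%g sigCutoff=%g useFdr=%s seed=%d",
      cfg$kingdom, cfg$rCutoff, cfg$sigCutoff, cfg$useFdr, cfg$seed)
  yaml::write_yaml(unclass(cfg), file.path(cfg$outDir, "run_config.yaml"))

  table <- readAbundanceTable(cfg$tablePath)
  metadata <- alignMetadata(readSampleMetadata(cfg$metadataPath), table)
  say("stage=input taxa=%d samples=%d relative=%s",
      nrow(abundances(table)), ncol(abundances(table)), isRelative(table))

  filt <- filterTaxa(table, minMeanRel = cfg$minMeanRel)
  say("stage=filter kept=%d dropped=%d threshold=%g",
      length(taxonIds(filt$table)), length(filt$dropped), cfg$minMeanRel)
  writeAbundanceTable(filt$table, file.path(cfg$outDir, "filtered_table.tsv"))
  writeLines(c("taxon_id", filt$dropped),
             file.path(cfg$outDir, "dropped_taxa.tsv"))

  alpha <- alphaDiversityTable(table, metadata)
  write.table(alpha, file.path(cfg$outDir, "alpha_diversity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say("stage=diversity samples=%d", nrow(alpha))

  assoc <- spearmanAssociation(filt$table)
  crit <- edgeCriteria(cfg$rCutoff, cfg$sigCutoff, cfg$useFdr)
  edges <- thresholdEdges(assoc, crit)
  say("stage=association pairs=%d edges=%d",
      length(upperTri(rhoMatrix(assoc))), nrow(edges))
  writeEdgeList(edges, file.path(cfg$outDir, "edges.tsv"))

  net <- suppressWarnings(
    buildNetwork(edges, allNodes = taxonIds(filt$table)))
  roles <- NULL
  topo <- NULL
  if (igraph::vcount(networkGraph(net)) == 0 || nrow(edges) == 0) {
    status <- "degenerate"
    say("stage=network status=empty reason=no-edges-survived-thresholds")
    say("stage=roles skipped=TRUE reason=empty-network")
    say("stage=topology skipped=TRUE reason=empty-network")
    ## still emit the role/topology files as headers so consumers see
    ## an explicit empty result rather than a missing file
    emptyRoles <- data.frame(node = character(), module = integer(),
                             degree = integer(), zi = numeric(),
                             pi = numeric(), category = character(),
                             is_keystone = logical(),
                             stringsAsFactors = FALSE)
    writeNodeRoles(emptyRoles, file.path(cfg$outDir, "node_roles.tsv"))
    write.table(topologyHeader(), file.path(cfg$outDir, "topology.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    net <- detectModules(net, algorithm = cfg$moduleAlgorithm,
                         seed = stageSeed(cfg, 1L))
    say("stage=modules n=%d modularity=%.4f algorithm=%s",
        length(unique(moduleMembership(net))), net@detection$modularity,
        cfg$moduleAlgorithm)
    roles <- classifyRoles(ziPi(net), cfg$ziThreshold, cfg$piThreshold)
    say("stage=roles keystones=%d of=%d", sum(roles$is_keystone),
        nrow(roles))
    writeNodeRoles(roles, file.path(cfg$outDir, "node_roles.tsv"))
    topo <- cbind(kingdom = cfg$kingdom, topologySummary(net))
    write.table(topo, file.path(cfg$outDir, "topology.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    exportGraph(net, file.path(cfg$outDir, "network.graphml"),
                roles = roles, format = "graphml",
                taxonomy = taxonomy(table))
  }

  ## multivariate stage on the unfiltered table (community-level view)
  bc <- brayCurtis(table)
  perm <- permanova(bc, metadata$group, nPerm = cfg$nPerm,
                    seed = stageSeed(cfg, 2L))
  say("stage=permanova F=%.4f R2=%.4f p=%.4g", perm@observed,
      perm@effectSize, perm@pValue)
  mv <- list(permanova = list(statistic = "pseudo-F",
                              observed = perm@observed,
                              R2 = perm@effectSize,
                              p_value = perm@pValue,
                              n_permutations = perm@nPermutations,
                              seed = perm@seed))
  cov <- metadataCovariates(metadata)
  if (!is.null(cov) && ncol(cov) >= 1) {
    dcov <- stats::dist(scale(cov))
    mant <- mantelTest(bc, dcov, nPerm = cfg$nPerm,
                       seed = stageSeed(cfg, 3L))
    say("stage=mantel r=%.4f p=%.4g", mant@observed, mant@pValue)
    mv$mantel <- list(statistic = mant@statisticName,
                      observed = mant@observed, p_value = mant@pValue,
                      n_permutations = mant@nPermutations,
                      seed = mant@seed)
  } else {
    say("stage=mantel skipped=TRUE reason=no-numeric-covariates")
  }
  jsonlite::write_json(mv, file.path(cfg$outDir, "multivariate.json"),
                       auto_unbox = TRUE, digits = NA)

  ord <- nmdsOrdination(bc, k = 2, seed = stageSeed(cfg, 4L))
  say("stage=nmds stress=%.5f converged=%s", ord@stress, ord@converged)
  coords <- data.frame(sample_id = rownames(ord@coordinates),
                       ord@coordinates, stringsAsFactors = FALSE)
  names(coords)[-1] <- sprintf("NMDS%d", seq_len(ncol(ord@coordinates)))
  write.table(coords, file.path(cfg$outDir, "nmds_coordinates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage=done status=%s", status)
  writeLines(logLines, logPath)
  invisible(list(status = status, table = table, filtered = filt,
                 alpha = alpha, association = assoc, edges = edges,
                 network = net, roles = roles, topology = topo,
                 brayCurtis = bc, permanova = perm, ordination = ord))
}

## Empty one-row-less topology frame used for degenerate runs.
topologyHeader <- function() {
  data.frame(kingdom = character(), n_nodes = integer(),
             n_edges = integer(), n_positive_edges = integer(),
             n_negative_edges = integer(), average_degree = numeric(),
             diameter = integer(), average_path_length = numeric(),
             clustering_coefficient = numeric(), modularity = numeric(),
             n_modules = integer(), stringsAsFactors = FALSE)
}

#' Compare topologies across completed pipeline runs
#'
#' Collects the topology summary and per-category keystone counts from
#' two or more results directories into one table, one row per
#' network, for cross-management comparison.
#'
#' @param resultsDirs character vector of completed run directories.
#' @return A \code{data.frame} with the topology fields plus
#'   n_peripheral / n_connector / n_module_hub / n_network_hub.
#' @export
compareNetworks <- function(resultsDirs) {
  if (length(resultsDirs) < 2)
    mnStop("mnInputError", "need at least 2 results directories")
  rows <- lapply(resultsDirs, function(dir) {
    topoPath <- file.path(dir, "topology.tsv")
    rolePath <- file.path(dir, "node_roles.tsv")
    if (!file.exists(topoPath))
      mnStop("mnInputError", sprintf("missing topology file in %s", dir))
    topo <- read.table(topoPath, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    if (nrow(topo) == 0) {
      topo <- topologyHeader()
      topo[1, ] <- NA          # degenerate (empty-network) run
    }
    topo$run <- basename(dir)
    counts <- c(peripheral = 0L, connector = 0L, module_hub = 0L,
                network_hub = 0L)
    if (file.exists(rolePath)) {
      roles <- read.table(rolePath, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      if (nrow(roles)) {
        tb <- table(factor(roles$category, levels = names(counts)))
        counts[names(tb)] <- as.integer(tb)
      }
    }
    cbind(topo, n_peripheral = counts[["peripheral"]],
          n_connector = counts[["connector"]],
          n_module_hub = counts[["module_hub"]],
          n_network_hub = counts[["network_hub"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[c("run", setdiff(names(out), "run"))]
}
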