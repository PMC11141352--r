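#' AbundanceTable: taxon-by-sample abundance matrix
#'
#' The package's universal input: a nonnegative numeric matrix with taxa
#' in rows and samples in columns, plus a flag recording whether the
#' values are relative abundances (each sample column sums to 1) and an
#' optional taxonomy lineage per taxon.
#'
#' @slot values numeric matrix, taxa x samples, with unique dimnames.
#' @slot isRelative logical; \code{TRUE} when each column sums to 1.
#' @slot taxonomy named character vector mapping taxon id to lineage
#'   string; may be empty.
#'
#' @seealso \code{\link{readAbundanceTable}}, \code{\link{filterTaxa}},
#'   \code{\link{toRelativeAbundance}}
#' @exportClass AbundanceTable
setClass("AbundanceTable",
  representation(
    values = "matrix",
    isRelative = "logical",
    taxonomy = "character"
  )
)

setValidity("AbundanceTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be numeric")
  if (nrow(v) < 1L || ncol(v) < 1L) return("empty abundance table")
  if (anyNA(v)) return("missing values are not allowed")
  if (any(v < 0)) return("negative abundances are not allowed")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("'values' must carry taxon (row) and sample (column) names")
  if (anyDuplicated(rownames(v))) return("duplicated taxon ids")
  if (anyDuplicated(colnames(v))) return("duplicated sample ids")
  if (length(object@isRelative) != 1L || is.na(object@isRelative))
    return("'isRelative' must be TRUE or FALSE")
  if (object@isRelative) {
    cs <- colSums(v)
    if (any(abs(cs - 1) > 1e-9))
      return("relative table has a column not summing to 1 (tolerance 1e-9)")
  }
  if (length(object@taxonomy) &&
      !all(names(object@taxonomy) %in% rownames(v)))
    return("taxonomy names must be a subset of taxon ids")
  TRUE
})

#' Construct an AbundanceTable
#'
#' @param values taxa x samples numeric matrix with dimnames.
#' @param isRelative \code{TRUE}, \code{FALSE}, or \code{NA} to
#'   auto-detect (all column sums within \code{1e-6} of 1).
#' @param taxonomy optional named character vector of lineages.
#' @return A validated \code{AbundanceTable}.
#' @examples
#' m <- matrix(c(5, 5, 0, 10), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' AbundanceTable(m)
#' @export
AbundanceTable <- function(values, isRelative = NA, taxonomy = character()) {
  if (!is.matrix(values))
    values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.na(isRelative)) {
    cs <- colSums(values)
    isRelative <- all(abs(cs - 1) < 1e-6)
  }
  if (isRelative) {
    ## snap near-1 column sums so the strict validity tolerance holds
    cs <- colSums(values)
    if (any(cs <= 0))
      mnStop("mnDegenerateSampleError", "all-zero sample column in relative table")
    values <- sweep(values, 2, cs, "/")
  }
  new("AbundanceTable", values = values, isRelative = isRelative,
      taxonomy = taxonomy)
}

#' @rdname AbundanceTable-accessors
#' @export
setGeneric("taxonIds", function(x) standardGeneric("taxonIds"))
#' @rdname AbundanceTable-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname AbundanceTable-accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname AbundanceTable-accessors
#' @export
setGeneric("isRelative", function(x) standardGeneric("isRelative"))
#' @rdname AbundanceTable-accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' Accessors for AbundanceTable
#'
#' \code{taxonIds}/\code{sampleIds} return the row/column identifiers,
#' \code{abundances} the numeric matrix, \code{isRelative} the
#' relative-abundance flag and \code{taxonomy} the lineage map.
#'
#' @param x an \code{AbundanceTable}.
#' @name AbundanceTable-accessors
#' @aliases taxonIds sampleIds abundances isRelative taxonomy
NULL

#' @rdname AbundanceTable-accessors
setMethod("taxonIds", "AbundanceTable", function(x) rownames(x@values))
#' @rdname AbundanceTable-accessors
setMethod("sampleIds", "AbundanceTable", function(x) colnames(x@values))
#' @rdname AbundanceTable-accessors
setMethod("abundances", "AbundanceTable", function(x) x@values)
#' @rdname AbundanceTable-accessors
setMethod("isRelative", "AbundanceTable", function(x) x@isRelative)
#' @rdname AbundanceTable-accessors
setMethod("taxonomy", "AbundanceTable", function(x) x@taxonomy)

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d taxa x %d samples (%s)\n",
              nrow(object@values), ncol(object@values),
              if (object@isRelative) "relative abundances" else "counts"))
  if (length(object@taxonomy))
    cat(sprintf("  taxonomy for %d taxa\n", length(object@taxonomy)))
})

#' @export
setMethod("dim", "AbundanceTable", function(x) dim(x@values))

#' AssociationResult: pairwise Spearman statistics over taxa
#'
#' Symmetric matrices of Spearman rho, raw two-sided p-values and
#' Benjamini-Hochberg adjusted q-values over the retained taxa, plus the
#' sample size used. Diagonal p/q entries are \code{NA} (not
#' applicable); \code{diag(rho) = 1}.
#'
#' @slot rho,pRaw,qFdr symmetric numeric matrices with identical
#'   taxon dimnames.
#' @slot nSamples integer, number of samples correlated.
#' @seealso \code{\link{spearmanAssociation}}, \code{\link{thresholdEdges}}
#' @exportClass AssociationResult
setClass("AssociationResult",
  representation(rho = "matrix", pRaw = "matrix", qFdr = "matrix",
                 nSamples = "integer"))

setValidity("AssociationResult", function(object) {
  r <- object@rho; p <- object@pRaw; q <- object@qFdr
  if (!identical(dim(r), dim(p)) || !identical(dim(r), dim(q)))
    return("matrix dimensions differ")
  if (is.null(rownames(r)) || !identical(rownames(r), colnames(r)))
    return("rho must carry matching taxon dimnames")
  if (max(abs(r - t(r))) > 1e-12) return("rho not symmetric")
  if (max(abs(diag(r) - 1)) > 1e-12) return("diag(rho) must be 1")
  if (any(r < -1 - 1e-12) || any(r > 1 + 1e-12)) return("rho outside [-1, 1]")
  off <- upper.tri(p)
  if (any(p[off] < 0 | p[off] > 1, na.rm = TRUE)) return("p outside [0, 1]")
  if (any(q[off] < p[off] - 1e-12, na.rm = TRUE))
    return("q must be >= p elementwise (BH never decreases a p-value)")
  if (object@nSamples < 4L) return("nSamples must be >= 4")
  TRUE
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult: %d taxa, n = %d samples\n",
              nrow(object@rho), object@nSamples))
  q <- upperTri(object@qFdr)
  cat(sprintf("  pairs: %d; q <= 0.05: %d\n", length(q), sum(q <= 0.05)))
})

#' @rdname AssociationResult-class
#' @param x an \code{AssociationResult}.
#' @export
rhoMatrix <- function(x) x@rho
#' @rdname AssociationResult-class
#' @export
pMatrix <- function(x) x@pRaw
#' @rdname AssociationResult-class
#' @export
qMatrix <- function(x) x@qFdr
#' @rdname AssociationResult-class
#' @export
nSamples <- function(x) x@nSamples

#' CoNetwork: signed co-occurrence graph with module membership
#'
#' A simple undirected igraph whose edges carry a \code{sign} (+1/-1)
#' and a \code{weight} (|rho|) attribute, together with a module
#' assignment per node once \code{\link{detectModules}} has run
#' (isolated nodes form singleton modules).
#'
#' @slot graph an \code{igraph} object (simple, undirected).
#' @slot moduleOf named integer vector node -> module index; zero
#'   length until modules are detected.
#' @slot detection list recording algorithm, seed and modularity.
#' @seealso \code{\link{buildNetwork}}, \code{\link{detectModules}},
#'   \code{\link{ziPi}}, \code{\link{topologySummary}}
#' @exportClass CoNetwork
setClass("CoNetwork",
  representation(graph = "ANY", moduleOf = "integer", detection = "list"))

setValidity("CoNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("'graph' must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (igraph::any_loop(g)) return("self-loops are not allowed")
  if (igraph::any_multiple(g)) return("parallel edges are not allowed")
  m <- object@moduleOf
  if (length(m)) {
    nm <- igraph::V(g)$name
    if (!setequal(names(m), nm) || length(m) != length(nm))
      return("moduleOf must assign every node exactly once")
    if (anyNA(m)) return("NA module assignment")
  }
  TRUE
})

setMethod("show", "CoNetwork", function(object) {
  g <- object@graph
  cat(sprintf("CoNetwork: %d nodes, %d edges", igraph::vcount(g),
              igraph::ecount(g)))
  if (igraph::ecount(g) > 0) {
    s <- igraph::E(g)$sign
    cat(sprintf(" (%d positive, %d negative)", sum(s > 0), sum(s < 0)))
  }
  cat("\n")
  if (length(object@moduleOf))
    cat(sprintf("  %d modules (%s)\n", length(unique(object@moduleOf)),
                object@detection$algorithm))
  else cat("  modules not yet detected\n")
})

#' @rdname CoNetwork-class
#' @param x a \code{CoNetwork}.
#' @export
networkGraph <- function(x) x@graph
#' @rdname CoNetwork-class
#' @export
moduleMembership <- function(x) x@moduleOf

#' PermutationResult: observed statistic and permutation p-value
#'
#' Shared container for PERMANOVA (pseudo-F, R-squared) and the Mantel
#' test (correlation). The p-value uses the \code{(1 + b) / (1 + m)}
#' estimator, so it is never exactly zero.
#'
#' @slot statisticName label, e.g. \code{"pseudo-F"} or
#'   \code{"Mantel r (spearman)"}.
#' @slot observed observed statistic.
#' @slot effectSize R-squared for PERMANOVA; \code{NA} for Mantel.
#' @slot nPermutations number of permutations drawn.
#' @slot pValue permutation p-value in \code{(0, 1]}.
#' @slot seed RNG seed used for the permutations.
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(statisticName = "character", observed = "numeric",
                 effectSize = "numeric", nPermutations = "integer",
                 pValue = "numeric", seed = "integer"))

setValidity("PermutationResult", function(object) {
  if (object@pValue < 1 / (object@nPermutations + 1) - 1e-12 ||
      object@pValue > 1)
    return("pValue outside (0, 1] or below 1/(nPerm+1)")
  if (!is.na(object@effectSize) &&
      (object@effectSize < -1e-12 || object@effectSize > 1 + 1e-12))
    return("effect size (R^2) outside [0, 1]")
  TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("%s = %.4f", object@statisticName, object@observed))
  if (!is.na(object@effectSize))
    cat(sprintf(", R^2 = %.3f", object@effectSize))
  cat(sprintf(", p = %.4g (%d permutations, seed %d)\n",
              object@pValue, object@nPermutations, object@seed))
})

#' @rdname PermutationResult-class
#' @param x a \code{PermutationResult}.
#' @export
observedStatistic <- function(x) x@observed
#' @rdname PermutationResult-class
#' @export
effectSize <- function(x) x@effectSize
#' @rdname PermutationResult-class
#' @export
pValue <- function(x) x@pValue
#' @rdname PermutationResult-class
#' @export
nPermutations <- function(x) x@nPermutations

#' Ordination: NMDS configuration with Kruskal stress-1
#'
#' @slot coordinates samples x k matrix of NMDS scores.
#' @slot stress Kruskal stress-1 of the best configuration.
#' @slot converged logical; \code{FALSE} when no restart descended
#'   before hitting the iteration cap.
#' @slot seed RNG seed used for the restarts.
#' @exportClass Ordination
setClass("Ordination",
  representation(coordinates = "matrix", stress = "numeric",
                 converged = "logical", seed = "integer"))

setMethod("show", "Ordination", function(object) {
  cat(sprintf("Ordination: %d samples in %d dimensions, stress-1 = %.4f%s\n",
              nrow(object@coordinates), ncol(object@coordinates),
              object@stress,
              if (object@converged) "" else " (not converged)"))
})

#' @rdname Ordination-class
#' @param x an \code{Ordination}.
#' @export
ordinationScores <- function(x) x@coordinates
#' @rdname Ordination-class
#' @export
ordinationStress <- function(x) x@stress

#' EdgeCriteria: thresholds deciding which correlations become edges
#'
#' An edge (i, j) is retained when \code{|rho| >= rCutoff} and the
#' significance value (BH-adjusted q when \code{useFdr}, raw p
#' otherwise) is \code{<= sigCutoff}. Comparisons are inclusive.
#'
#' @slot rCutoff correlation magnitude cutoff in (0, 1].
#' @slot sigCutoff significance cutoff in (0, 1].
#' @slot useFdr apply \code{sigCutoff} to BH-adjusted q (default) or to
#'   raw p.
#' @seealso \code{\link{edgeCriteria}}, \code{\link{edgeCriteriaPreset}}
#' @exportClass EdgeCriteria
setClass("EdgeCriteria",
  representation(rCutoff = "numeric", sigCutoff = "numeric",
                 useFdr = "logical"))

setValidity("EdgeCriteria", function(object) {
  if (object@rCutoff <= 0 || object@rCutoff > 1)
    return("rCutoff must be in (0, 1]")
  if (object@sigCutoff <= 0 || object@sigCutoff > 1)
    return("sigCutoff must be in (0, 1]")
  TRUE
})

#' @rdname EdgeCriteria-class
#' @param rCutoff,sigCutoff,useFdr see the class description.
#' @export
edgeCriteria <- function(rCutoff = 0.5, sigCutoff = 0.05, useFdr = TRUE) {
  new("EdgeCriteria", rCutoff = rCutoff, sigCutoff = sigCutoff,
      useFdr = useFdr)
}

#' Per-kingdom edge-criteria presets
#'
#' Named parameter sets commonly used for soil community networks:
#' bacteria (\code{|rho| >= 0.5}, significance 0.02), fungi (0.50,
#' 0.05) and archaea (0.68, 0.05), each applied to BH-adjusted
#' q-values.
#'
#' @param kingdom one of \code{"bacteria"}, \code{"fungi"},
#'   \code{"archaea"}.
#' @return An \code{\link{EdgeCriteria}} object.
#' @examples
#' edgeCriteriaPreset("archaea")
#' @export
edgeCriteriaPreset <- function(kingdom = c("bacteria", "fungi", "archaea")) {
  kingdom <- match.arg(kingdom)
  switch(kingdom,
    bacteria = edgeCriteria(0.5, 0.02, TRUE),
    fungi    = edgeCriteria(0.50, 0.05, TRUE),
    archaea  = edgeCriteria(0.68, 0.05, TRUE))
}

setMethod("show", "EdgeCriteria", function(object) {
  cat(sprintf("EdgeCriteria: |rho| >= %g and %s <= %g\n", object@rCutoff,
              if (object@useFdr) "q (BH)" else "p", object@sigCutoff))
})
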