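## Statistical core of the co-occurrence network: all-pairs Spearman
## correlation with two-sided p-values, Benjamini-Hochberg FDR over the
## upper triangle, and signed-edge thresholding.

#' All-pairs Spearman correlation with p-values and BH q-values
#'
#' Computes average-rank Spearman rho between every pair of taxon
#' profiles, a two-sided p-value from the t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on \code{n - 2}
#' degrees of freedom (\code{|rho| = 1} is assigned p = 0), and
#' BH-adjusted q-values computed once over the strictly-upper-triangle
#' p-values and mirrored. Taxa with constant profiles are dropped with
#' a warning before correlating, since rank correlation is undefined
#' for them.
#'
#' @param table an \code{AbundanceTable} with at least 4 samples and 2
#'   non-constant taxa.
#' @param exact use the exact permutation null distribution of rho
#'   instead of the t approximation; only allowed for \code{n <= 8}
#'   samples (the permutation space is enumerated).
#' @return An \code{\link{AssociationResult}}.
#' @examples
#' sim <- simulateCorrelatedCommunity(nTaxa = 9, samplesPerGroup = 4,
#'                                    nModules = 3, seed = 1)
#' spearmanAssociation(sim$table)
#' @export
spearmanAssociation <- function(table, exact = FALSE) {
  stopifnot(is(table, "AbundanceTable"))
  v <- abundances(table)
  n <- ncol(v)
  if (n < 4)
    mnStop("mnSampleSizeError",
           "at least 4 samples are required for the correlation step")
  constant <- apply(v, 1, function(x) max(x) == min(x))
  if (all(constant))
    mnStop("mnDegenerateResultError", "every taxon is constant across samples")
  if (any(constant)) {
    warning(sprintf("dropping %d constant taxa before correlation: %s",
                    sum(constant),
                    paste(utils::head(rownames(v)[constant], 5),
                          collapse = ", ")))
    v <- v[!constant, , drop = FALSE]
  }
  if (nrow(v) < 2)
    mnStop("mnDegenerateResultError", "fewer than 2 non-constant taxa")
  rho <- cor(t(v), method = "spearman")
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  diag(rho) <- 1
  p <- spearmanPValue(rho, n, exact = exact, profiles = v)
  diag(p) <- NA_real_
  q <- p
  ut <- upper.tri(p)
  q[ut] <- bhAdjust(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  new("AssociationResult", rho = rho, pRaw = p, qFdr = q,
      nSamples = as.integer(n))
}

## Two-sided p-values for a matrix of Spearman rho at sample size n.
## The exact route enumerates all n! rank permutations (n <= 8) and is
## intended for validating the t approximation on tiny fixtures.
spearmanPValue <- function(rho, n, exact = FALSE, profiles = NULL) {
  if (!exact) {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p[abs(rho) >= 1 - 1e-12] <- 0
    return(p)
  }
  if (n > 8)
    mnStop("mnParameterError",
           "exact permutation p-values are limited to n <= 8 samples")
  ## null distribution of rho for untied ranks, by full enumeration
  perms <- allPermutations(n)
  base <- seq_len(n)
  nullRho <- apply(perms, 1, function(pr) suppressWarnings(
    cor(base, pr, method = "spearman")))
  p <- matrix(NA_real_, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  for (i in seq_len(nrow(rho))) for (j in seq_len(ncol(rho))) {
    if (i == j) { p[i, j] <- 0; next }
    p[i, j] <- mean(abs(nullRho) >= abs(rho[i, j]) - 1e-12)
  }
  p
}

allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) for (k in seq_len(nrow(sub))) {
    r <- r + 1L
    out[r, ] <- append(sub[k, ], n, after = pos - 1L)
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort ascending, \code{q_(i) = min_{j >= i} p_(j) m / j}
#' capped at 1, mapped back to input order. Thin validated wrapper over
#' \code{p.adjust(method = "BH")}.
#'
#' @param p vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    mnStop("mnValueError", "p-values must be numeric in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Threshold correlations into a signed edge list
#'
#' Retains pair (i, j) when \code{|rho_ij| >= rCutoff} and the
#' significance value (q when \code{useFdr}, raw p otherwise) is
#' \code{<= sigCutoff}; both comparisons inclusive. Each edge carries
#' the sign of rho and weight |rho|; self-pairs are excluded.
#'
#' @param assoc an \code{\link{AssociationResult}}.
#' @param criteria an \code{\link{EdgeCriteria}} object.
#' @return A \code{data.frame} with columns taxon_a, taxon_b, rho, p,
#'   q, sign, weight; one row per retained unordered pair, taxon_a
#'   preceding taxon_b in the association's taxon order.
#' @export
thresholdEdges <- function(assoc, criteria = edgeCriteria()) {
  stopifnot(is(assoc, "AssociationResult"), is(criteria, "EdgeCriteria"))
  validObject(criteria)
  rho <- rhoMatrix(assoc); p <- pMatrix(assoc); q <- qMatrix(assoc)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  rv <- rho[ut]; pv <- p[ut]; qv <- q[ut]
  sig <- if (criteria@useFdr) qv else pv
  keep <- abs(rv) >= criteria@rCutoff & sig <= criteria@sigCutoff
  ids <- rownames(rho)
  data.frame(
    taxon_a = ids[ut[keep, 1L]],
    taxon_b = ids[ut[keep, 2L]],
    rho = rv[keep], p = pv[keep], q = qv[keep],
    sign = ifelse(rv[keep] >= 0, 1L, -1L),
    weight = abs(rv[keep]),
    stringsAsFactors = FALSE)
}

#' Write an edge list as TSV
#'
#' @param edges data.frame from \code{\link{thresholdEdges}}.
#' @param path output path.
#' @export
writeEdgeList <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
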