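## Distance-based community statistics: Bray-Curtis dissimilarity,
## one-factor PERMANOVA (Anderson's partition), the Mantel test, NMDS
## with Kruskal stress-1, and iterative VIF screening of covariates.

#' Bray-Curtis dissimilarity between samples
#'
#' \code{d_ij = sum |x_i - x_j| / sum (x_i + x_j)} over taxa, computed
#' between every pair of sample columns.
#'
#' @param table an \code{AbundanceTable} with no all-zero sample.
#' @return A \code{\link[stats]{dist}} object labelled by sample id;
#'   values in [0, 1].
#' @export
brayCurtis <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  v <- abundances(table)
  if (any(colSums(v) <= 0))
    mnStop("mnDegenerateSampleError",
           sprintf("all-zero sample: %s",
                   paste(colnames(v)[colSums(v) <= 0], collapse = ", ")))
  vegan::vegdist(t(v), method = "bray")
}

## Coerce a dist or labelled square matrix to a square matrix with ids.
asDistMatrix <- function(d, what = "distance matrix") {
  m <- as.matrix(d)
  if (is.null(rownames(m)))
    mnStop("mnAlignmentError", sprintf("%s must carry sample labels", what))
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    mnStop("mnAlignmentError", sprintf("%s must be square and symmetric", what))
  m
}

## Pseudo-F and R^2 for one labelling, from the squared-distance matrix.
## SS_total = sum_{i<j} d_ij^2 / N; SS_within = sum over groups of
## within-group pair sums / n_g; SS_between = SS_total - SS_within.
permanovaStatistic <- function(d2, groups) {
  n <- nrow(d2)
  idx <- split(seq_len(n), groups)
  ssW <- sum(vapply(idx, function(i) sum(d2[i, i]) / (2 * length(i)),
                    numeric(1)))
  ssT <- sum(d2[upper.tri(d2)]) / n
  ssB <- ssT - ssW
  g <- length(idx)
  list(F = (ssB / (g - 1)) / (ssW / (n - g)), R2 = ssB / ssT)
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance
#' matrix (Anderson's one-factor partition). Reports the pseudo-F
#' statistic, \code{R^2 = SS_between / SS_total}, and a permutation
#' p-value from random relabelings using the \code{(1 + b) / (1 + m)}
#' estimator.
#'
#' @param d a \code{dist} or labelled square distance matrix.
#' @param groups group labels aligned to the rows of \code{d} (at
#'   least 2 groups with 2 samples each).
#' @param nPerm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return A \code{\link{PermutationResult}}.
#' @examples
#' sim <- simulateCorrelatedCommunity(nTaxa = 30, samplesPerGroup = 5,
#'                                    groupEffectSd = 1, seed = 7)
#' permanova(brayCurtis(sim$table), sim$metadata$group, nPerm = 99, seed = 1)
#' @export
permanova <- function(d, groups, nPerm = 999, seed = 1L) {
  m <- asDistMatrix(d)
  n <- nrow(m)
  groups <- as.factor(groups)
  if (length(groups) != n)
    mnStop("mnAlignmentError", "'groups' length must match the matrix")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    mnStop("mnDesignError",
           "need at least 2 groups with at least 2 samples each")
  d2 <- m^2
  obs <- permanovaStatistic(d2, groups)
  exceed <- withSeed(seed, {
    sum(vapply(seq_len(nPerm), function(b) {
      permanovaStatistic(d2, sample(groups))$F >= obs$F
    }, logical(1)))
  })
  new("PermutationResult", statisticName = "pseudo-F",
      observed = obs$F, effectSize = obs$R2,
      nPermutations = as.integer(nPerm),
      pValue = (1 + exceed) / (1 + nPerm), seed = as.integer(seed))
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper triangles of two aligned distance matrices and
#' assesses significance by jointly permuting the rows and columns of
#' the second; two-sided on \code{|r|}, with the
#' \code{(1 + b) / (1 + m)} estimator.
#'
#' @param d1,d2 \code{dist} objects or labelled square matrices with
#'   identical ids in identical order.
#' @param method \code{"spearman"} (default, consistent with the
#'   rank-based network construction) or \code{"pearson"}.
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @return A \code{\link{PermutationResult}}.
#' @export
mantelTest <- function(d1, d2, method = c("spearman", "pearson"),
                       nPerm = 999, seed = 1L) {
  method <- match.arg(method)
  m1 <- asDistMatrix(d1, "d1"); m2 <- asDistMatrix(d2, "d2")
  if (!identical(rownames(m1), rownames(m2)))
    mnStop("mnAlignmentError", "d1 and d2 must share ids in the same order")
  n <- nrow(m1)
  ut <- upper.tri(m1)
  v1 <- m1[ut]; v2 <- m2[ut]
  if (sd(v1) == 0 || sd(v2) == 0)
    mnStop("mnDegenerateResultError",
           "constant distance matrix: Mantel r undefined")
  ## rank once; a permutation of ids permutes the pair vector, so the
  ## ranks can be permuted rather than recomputed (Spearman = Pearson
  ## on ranks)
  if (method == "spearman") {
    r1full <- matrix(0, n, n); r2full <- matrix(0, n, n)
    r1full[ut] <- rank(v1); r2full[ut] <- rank(v2)
    r1full <- r1full + t(r1full); r2full <- r2full + t(r2full)
  } else {
    r1full <- m1; r2full <- m2
  }
  x <- r1full[ut]
  rObs <- cor(r1full[ut], r2full[ut])
  exceed <- withSeed(seed, {
    sum(vapply(seq_len(nPerm), function(b) {
      p <- sample.int(n)
      abs(cor(x, r2full[p, p][ut])) >= abs(rObs) - 1e-12
    }, logical(1)))
  })
  new("PermutationResult",
      statisticName = sprintf("Mantel r (%s)", method),
      observed = rObs, effectSize = NA_real_,
      nPermutations = as.integer(nPerm),
      pValue = (1 + exceed) / (1 + nPerm), seed = as.integer(seed))
}

#' Non-metric multidimensional scaling with Kruskal stress-1
#'
#' Kruskal-style iterative NMDS (monotone regression of configuration
#' distances on the dissimilarity ranks, via \code{vegan::monoMDS}),
#' run from a principal-coordinates start plus seeded random restarts;
#' the lowest-stress configuration is kept. Stress-1 below ~0.1 is
#' conventionally a good fit.
#'
#' @param d a \code{dist} or labelled square distance matrix over at
#'   least \code{k + 2} samples.
#' @param k target dimensionality.
#' @param nRestarts number of random restarts besides the PCoA start.
#' @param seed RNG seed.
#' @return An \code{\link{Ordination}}; non-convergence is flagged,
#'   not an error.
#' @export
nmdsOrdination <- function(d, k = 2, nRestarts = 20, seed = 1L) {
  m <- asDistMatrix(d)
  n <- nrow(m)
  if (n < k + 2)
    mnStop("mnSampleSizeError", "need at least k + 2 samples for NMDS")
  dd <- stats::as.dist(m)
  fits <- withSeed(seed, {
    inits <- c(list(cmdscale(dd, k = k, add = TRUE)$points),
               replicate(nRestarts,
                         matrix(rnorm(n * k), n, k), simplify = FALSE))
    lapply(inits, function(y0)
      tryCatch(vegan::monoMDS(dd, y = y0, k = k, model = "global"),
               error = function(e) NULL))
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    mnStop("mnDegenerateResultError", "every NMDS start failed")
  stresses <- vapply(fits, function(f) f$stress, numeric(1))
  best <- fits[[which.min(stresses)]]
  coords <- best$points
  rownames(coords) <- rownames(m)
  ## monoMDS icause 1 = iteration cap hit without meeting either
  ## convergence criterion
  new("Ordination", coordinates = coords, stress = best$stress,
      converged = !identical(as.integer(best$icause), 1L),
      seed = as.integer(seed))
}

#' Iterative variance-inflation-factor screening
#'
#' Repeatedly drops the covariate with the largest VIF
#' (\code{1 / (1 - R^2)} from an OLS regression of that covariate on
#' the others) until all VIFs fall below the threshold. Exactly
#' collinear columns give infinite VIF; the later column (by input
#' order) is dropped first, with a warning.
#'
#' @param covariates samples x variables numeric matrix (more samples
#'   than variables).
#' @param threshold VIF threshold; 5 is the usual screen for soil
#'   covariates, 10 a laxer alternative.
#' @return Character vector of retained variable names.
#' @examples
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' x <- cbind(x, a2 = x[, "a"])   # duplicate column
#' vifScreen(x)
#' @export
vifScreen <- function(covariates, threshold = 5) {
  m <- as.matrix(covariates)
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("V%d", seq_len(ncol(m)))
  if (ncol(m) < 2)
    mnStop("mnParameterError", "need at least 2 covariates to screen")
  if (nrow(m) <= ncol(m))
    mnStop("mnParameterError",
           "need more samples than covariates for the OLS regressions")
  vifOf <- function(mm) {
    vapply(seq_len(ncol(mm)), function(j) {
      fit <- lm(mm[, j] ~ mm[, -j, drop = FALSE])
      ## summary() warns on essentially perfect fits; exact collinearity
      ## is an expected input here and handled below via Inf
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  keep <- colnames(m)
  while (length(keep) >= 2) {
    v <- vifOf(m[, keep, drop = FALSE])
    if (all(v < threshold)) break
    ## ties (incl. multiple Inf): drop the later column by input order
    worst <- max(which(v == max(v)))
    if (is.infinite(v[worst]))
      warning(sprintf("'%s' is exactly collinear with the others; dropped",
                      keep[worst]))
    keep <- keep[-worst]
  }
  keep
}
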