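## Per-sample alpha-diversity estimators: Chao1 richness, Shannon
## diversity (nats by default) and Pielou evenness.

#' Chao1 richness estimator
#'
#' \code{S_obs + F1^2 / (2 F2)} where F1/F2 are the singleton and
#' doubleton counts; when no doubletons exist the bias-corrected form
#' \code{S_obs + F1 (F1 - 1) / (2 (F2 + 1))} is used. Zeros are
#' ignored. Chao1 is undefined for relative abundances, so the input
#' must be integer counts.
#'
#' @param counts nonnegative integer vector of taxon counts in one
#'   sample.
#' @return The Chao1 estimate (always \code{>=} observed richness).
#' @examples
#' chao1(c(5, 3, 2, 1, 1))  # 5 + 2^2 / (2 * 1) = 7
#' @export
chao1 <- function(counts) {
  if (anyNA(counts) || any(counts < 0))
    mnStop("mnTypeError", "'counts' must be nonnegative and complete")
  if (any(abs(counts - round(counts)) > 1e-8))
    mnStop("mnTypeError",
           "Chao1 requires integer counts; undefined for relative abundances")
  counts <- round(counts[counts > 0])
  sObs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) sObs + f1^2 / (2 * f2)
  else sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' \code{H = -sum(p_i log p_i)} over positive entries, with abundances
#' normalised to proportions. Natural log (nats) by default, matching
#' common ecological practice.
#'
#' @param abund nonnegative abundance vector (counts or relative).
#' @param base logarithm base.
#' @return Shannon index, \code{>= 0}.
#' @export
shannonIndex <- function(abund, base = exp(1)) {
  if (anyNA(abund) || any(abund < 0))
    mnStop("mnTypeError", "'abund' must be nonnegative and complete")
  if (sum(abund) <= 0)
    mnStop("mnDegenerateSampleError", "all-zero abundance vector")
  as.numeric(vegan::diversity(abund, index = "shannon", base = base))
}

#' Pielou evenness
#'
#' \code{J = H / log(S_obs)}; requires at least two species with
#' positive abundance, and lies in [0, 1].
#'
#' @inheritParams shannonIndex
#' @return Evenness in [0, 1].
#' @export
pielouEvenness <- function(abund, base = exp(1)) {
  sObs <- sum(abund > 0, na.rm = FALSE)
  if (is.na(sObs) || sObs < 2)
    mnStop("mnDegenerateSampleError",
           "Pielou evenness undefined for fewer than 2 observed species")
  shannonIndex(abund, base = base) / log(sObs, base = base)
}

#' Per-sample alpha-diversity table
#'
#' Computes observed richness, Chao1 (counts tables only), Shannon and
#' Pielou for every sample. On relative tables Chao1 is reported as
#' \code{NA} since singleton/doubleton counts are undefined.
#'
#' @param table an \code{AbundanceTable}.
#' @param metadata optional metadata; when supplied, the group label is
#'   included in the output.
#' @return A \code{data.frame} with one row per sample: sample_id,
#'   (group,) observed_richness, chao1, shannon, pielou.
#' @export
alphaDiversityTable <- function(table, metadata = NULL) {
  stopifnot(is(table, "AbundanceTable"))
  v <- abundances(table)
  hasCounts <- !isRelative(table) &&
    all(abs(v - round(v)) < 1e-8)
  res <- data.frame(
    sample_id = colnames(v),
    observed_richness = apply(v, 2, function(x) sum(x > 0)),
    chao1 = if (hasCounts) apply(v, 2, chao1) else NA_real_,
    shannon = apply(v, 2, shannonIndex),
    pielou = apply(v, 2, function(x)
      if (sum(x > 0) < 2) NA_real_ else pielouEvenness(x)),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (!is.null(metadata)) {
    md <- alignMetadata(metadata, table)
    res <- data.frame(res[1L], group = md$group, res[-1L],
                      stringsAsFactors = FALSE)
  }
  res
}
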