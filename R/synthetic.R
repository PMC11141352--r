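## Synthetic community generator: latent-factor log-abundance model with
## planted correlation modules, known keystone taxa, group-level mean
## shifts, Poisson count sampling at a fixed library size, and cell-wise
## zero inflation. Everything downstream of table IO can be validated
## against the planted truth.

#' Simulate a community with planted correlation modules and keystones
#'
#' Each sample draws one latent value per module from a standard
#' normal; a taxon in module m has log-abundance
#' \code{mu_i + groupEffect + loading * z_m + eps} with
#' \code{eps ~ N(0, noiseSd)}. Keystone taxa additionally load (with
#' the same loading) on a second module's factor, so their abundance
#' correlates across module boundaries. Log-abundances are
#' exponentiated, scaled by one fixed factor chosen so a typical
#' sample totals \code{librarySize}, and Poisson-sampled to counts;
#' each cell is then zeroed with probability \code{zeroInflation}
#' (detection dropout). Sample sums therefore vary around
#' \code{librarySize}; per-sample closure is left to the downstream
#' relative-abundance transform, so the planted correlation structure
#' is not distorted by compositional coupling between modules.
#' The same seed reproduces the output bit-for-bit.
#'
#' @param nTaxa total number of taxa (must be at least
#'   \code{3 * nModules}).
#' @param samplesPerGroup samples per group (at least 3).
#' @param groups group labels; defaults to the three management regimes
#'   HY, TS, XY.
#' @param nModules number of planted modules.
#' @param loading within-module latent loading in (0, 1]; 0 disables
#'   the planted structure.
#' @param noiseSd standard deviation of the taxon-level log noise.
#' @param zeroInflation probability a count is zeroed after sampling.
#' @param nKeystones number of taxa wired across two modules.
#' @param groupEffectSd standard deviation of the per-taxon, per-group
#'   log-scale mean shift (0 for no group structure).
#' @param librarySize expected total count per sample.
#' @param seed master RNG seed.
#' @return A list with \code{table} (counts \code{AbundanceTable}),
#'   \code{metadata} (sample_id/group data.frame) and \code{truth}, a
#'   list holding \code{moduleOf} (named integer; 0 = background),
#'   \code{keystoneIds}, \code{groupEffect} (taxa x groups matrix of
#'   log-scale shifts) and \code{params}.
#' @examples
#' sim <- simulateCorrelatedCommunity(nTaxa = 12, samplesPerGroup = 4,
#'                                    nModules = 3, seed = 1)
#' sim$table
#' table(sim$truth$moduleOf)
#' @export
simulateCorrelatedCommunity <- function(nTaxa = 300,
                                        samplesPerGroup = 5,
                                        groups = c("HY", "TS", "XY"),
                                        nModules = 3,
                                        loading = 0.8,
                                        noiseSd = 0.3,
                                        zeroInflation = 0.1,
                                        nKeystones = 3,
                                        groupEffectSd = 0.5,
                                        librarySize = 1e5,
                                        seed = 1) {
  if (!isScalarNumber(loading) || loading < 0 || loading > 1)
    mnStop("mnParameterError", "'loading' must be in [0, 1]")
  checkProb(zeroInflation, "zeroInflation")
  if (noiseSd <= 0)
    mnStop("mnParameterError", "'noiseSd' must be positive")
  if (nTaxa < nModules * 3)
    mnStop("mnParameterError", "'nTaxa' must be at least 3 * nModules")
  if (samplesPerGroup < 3)
    mnStop("mnParameterError", "'samplesPerGroup' must be at least 3")
  if (nKeystones > nTaxa)
    mnStop("mnParameterError", "more keystones than taxa")
  groups <- as.character(groups)
  nSamples <- samplesPerGroup * length(groups)
  taxa <- sprintf("taxon_%03d", seq_len(nTaxa))
  samples <- sprintf("%s_%d", rep(groups, each = samplesPerGroup),
                     rep(seq_len(samplesPerGroup), length(groups)))
  groupOf <- rep(groups, each = samplesPerGroup)

  ## taxa are dealt round-robin into modules so every module has
  ## ceiling(nTaxa / nModules) or floor thereof members; no background
  ## block by default (module 0 is reserved for loading = 0 semantics)
  moduleOf <- rep(seq_len(nModules), length.out = nTaxa)
  if (loading == 0) moduleOf[] <- 0L
  names(moduleOf) <- taxa
  ## keystones: spread across modules, secondary loading on the next
  ## module (cyclically)
  keystoneIdx <- if (nKeystones > 0)
    round(seq(1, nTaxa, length.out = nKeystones)) else integer()
  keystoneIds <- taxa[keystoneIdx]

  withSeed(seed, {
    mu <- rnorm(nTaxa, mean = 0, sd = 1)                 # baseline log-abundance
    groupEffect <- matrix(rnorm(nTaxa * length(groups), 0, groupEffectSd),
                          nTaxa, length(groups),
                          dimnames = list(taxa, groups))
    z <- matrix(rnorm(max(nModules, 1) * nSamples), max(nModules, 1),
                nSamples)                                # latent module factors
    eps <- matrix(rnorm(nTaxa * nSamples, 0, noiseSd), nTaxa, nSamples)
    logAb <- matrix(mu, nTaxa, nSamples) +
      groupEffect[, match(groupOf, groups), drop = FALSE] + eps
    if (loading > 0) {
      for (i in seq_len(nTaxa)) {
        m <- moduleOf[i]
        logAb[i, ] <- logAb[i, ] + loading * z[m, ]
        if (i %in% keystoneIdx) {
          m2 <- (m %% nModules) + 1L                     # second module
          logAb[i, ] <- logAb[i, ] + loading * z[m2, ]
        }
      }
    }
    expAb <- exp(logAb)
    ## one fixed scale for the whole table (typical sample total ~
    ## librarySize); per-sample closure is NOT applied, so planted
    ## correlations survive on the count scale
    lambda <- expAb * (librarySize / mean(colSums(expAb)))
    counts <- matrix(rpois(nTaxa * nSamples, lambda),
                     nTaxa, nSamples, dimnames = list(taxa, samples))
    rel <- sweep(expAb, 2, colSums(expAb), "/")
    if (zeroInflation > 0) {
      drop <- matrix(runif(nTaxa * nSamples) < zeroInflation,
                     nTaxa, nSamples)
      counts[drop] <- 0L
    }
    ## a sample zeroed out entirely by dropout would violate the table
    ## invariants; restore its single largest expected taxon
    dead <- colSums(counts) == 0
    if (any(dead)) for (j in which(dead))
      counts[which.max(rel[, j]), j] <- 1
    storage.mode(counts) <- "double"
    list(
      table = AbundanceTable(counts, isRelative = FALSE),
      metadata = data.frame(sample_id = samples, group = factor(groupOf),
                            stringsAsFactors = FALSE),
      truth = list(
        moduleOf = moduleOf,
        keystoneIds = keystoneIds,
        groupEffect = groupEffect,
        params = list(nTaxa = nTaxa, samplesPerGroup = samplesPerGroup,
                      groups = groups, nModules = nModules,
                      loading = loading, noiseSd = noiseSd,
                      zeroInflation = zeroInflation,
                      nKeystones = nKeystones,
                      groupEffectSd = groupEffectSd,
                      librarySize = librarySize, seed = seed)))
  })
}

#' Simulate a structureless (null) community
#'
#' Independent log-normal counts with no group effects and no planted
#' correlation; group labels are assigned in equal blocks purely for
#' bookkeeping. Used to calibrate the type-I error of the permutation
#' tests.
#'
#' @param nTaxa,nSamples table dimensions (both at least 2).
#' @param nGroups number of (arbitrary) group labels.
#' @param librarySize expected total count per sample.
#' @param seed RNG seed.
#' @return A list with \code{table} and \code{metadata}.
#' @export
simulateNullCommunity <- function(nTaxa = 100, nSamples = 30, nGroups = 3,
                                  librarySize = 1e5, seed = 1) {
  if (nTaxa < 2 || nSamples < 2)
    mnStop("mnParameterError", "need at least 2 taxa and 2 samples")
  taxa <- sprintf("taxon_%03d", seq_len(nTaxa))
  samples <- sprintf("sample_%02d", seq_len(nSamples))
  groupOf <- sprintf("G%d", sort(rep(seq_len(nGroups),
                                     length.out = nSamples)))
  withSeed(seed, {
    expAb <- matrix(exp(rnorm(nTaxa * nSamples)), nTaxa, nSamples)
    lambda <- expAb * (librarySize / mean(colSums(expAb)))
    counts <- matrix(rpois(nTaxa * nSamples, lambda),
                     nTaxa, nSamples, dimnames = list(taxa, samples))
    rel <- sweep(expAb, 2, colSums(expAb), "/")
    dead <- colSums(counts) == 0
    if (any(dead)) for (j in which(dead))
      counts[which.max(rel[, j]), j] <- 1
    storage.mode(counts) <- "double"
    list(table = AbundanceTable(counts, isRelative = FALSE),
         metadata = data.frame(sample_id = samples,
                               group = factor(groupOf),
                               stringsAsFactors = FALSE))
  })
}
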