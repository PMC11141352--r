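test_that("bray-curtis matches the elementwise oracle and its bounds", {
  m <- cbind(s1 = c(2, 2), s2 = c(1, 3))
  rownames(m) <- c("a", "b")
  d <- brayCurtis(AbundanceTable(m))
  expect_equal(as.matrix(d)["s1", "s2"], 0.25)  # (1+1)/(3+5)

  ident <- cbind(s1 = c(1, 2), s2 = c(1, 2))
  rownames(ident) <- c("a", "b")
  expect_equal(as.matrix(brayCurtis(AbundanceTable(ident)))["s1", "s2"], 0)

  disjoint <- cbind(s1 = c(1, 0), s2 = c(0, 1))
  rownames(disjoint) <- c("a", "b")
  expect_equal(as.matrix(brayCurtis(AbundanceTable(disjoint)))["s1", "s2"], 1)

  set.seed(31)
  for (i in 1:10) {
    v <- matrix(rexp(8 * 6), 8, 6,
                dimnames = list(sprintf("t%d", 1:8), sprintf("s%d", 1:6)))
    got <- as.matrix(brayCurtis(AbundanceTable(v)))
    want <- bruteBray(v)
    expect_lt(max(abs(got - want)), 1e-12)
    expect_true(all(got >= 0 & got <= 1))
    expect_equal(got, t(got))
  }
  zero <- cbind(s1 = c(1, 1), s2 = c(0, 0))
  rownames(zero) <- c("a", "b")
  expect_error(brayCurtis(AbundanceTable(zero)),
               class = "mnDegenerateSampleError")
})

test_that("permanova on univariate euclidean distances equals one-way ANOVA F", {
  set.seed(32)
  y <- rnorm(18)
  g <- rep(c("A", "B", "C"), each = 6)
  d <- dist(y)
  attr(d, "Labels") <- sprintf("s%d", 1:18)
  res <- permanova(d, g, nPerm = 49, seed = 1)
  fAov <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_lt(abs(observedStatistic(res) - fAov), 1e-10)
})

test_that("permanova agrees with vegan::adonis2 and respects the design", {
  sim <- simulateCorrelatedCommunity(nTaxa = 40, samplesPerGroup = 5,
                                     groupEffectSd = 0.6, seed = 33)
  bc <- brayCurtis(sim$table)
  res <- permanova(bc, sim$metadata$group, nPerm = 199, seed = 2)
  grp <- sim$metadata$group
  ref <- vegan::adonis2(bc ~ grp, permutations = 199)
  expect_lt(abs(observedStatistic(res) - ref$F[1]), 1e-10)
  expect_lt(abs(effectSize(res) - ref$R2[1]), 1e-10)
  expect_true(pValue(res) >= 1 / 200 && pValue(res) <= 1)

  # statistic invariant to renaming the groups
  relabel <- factor(grp, levels = levels(grp), labels = c("x", "y", "z"))
  res2 <- permanova(bc, relabel, nPerm = 199, seed = 2)
  expect_equal(observedStatistic(res2), observedStatistic(res))

  expect_error(permanova(bc, rep("A", 15), nPerm = 99, seed = 1),
               class = "mnDesignError")
  expect_error(permanova(bc, c("A", rep("B", 14)), nPerm = 99, seed = 1),
               class = "mnDesignError")
})

test_that("well-separated groups reach the minimum attainable p-value", {
  sim <- simulateCorrelatedCommunity(nTaxa = 50, samplesPerGroup = 5,
                                     groupEffectSd = 3, seed = 34)
  res <- permanova(brayCurtis(sim$table), sim$metadata$group,
                   nPerm = 999, seed = 3)
  expect_equal(pValue(res), 0.001)
  expect_gt(effectSize(res), 0.3)
})

test_that("permutation results are reproducible bit-for-bit given a seed", {
  sim <- simulateNullCommunity(nTaxa = 30, nSamples = 12, seed = 35)
  bc <- brayCurtis(sim$table)
  p1 <- permanova(bc, sim$metadata$group, nPerm = 99, seed = 7)
  p2 <- permanova(bc, sim$metadata$group, nPerm = 99, seed = 7)
  expect_identical(pValue(p1), pValue(p2))
  m1 <- mantelTest(bc, bc, nPerm = 99, seed = 7)
  m2 <- mantelTest(bc, bc, nPerm = 99, seed = 7)
  expect_identical(pValue(m1), pValue(m2))
})

test_that("mantel test handles self-correlation, agreement, and degeneracy", {
  sim <- simulateNullCommunity(nTaxa = 30, nSamples = 10, seed = 36)
  bc <- brayCurtis(sim$table)
  self <- mantelTest(bc, bc, nPerm = 999, seed = 4)
  expect_equal(observedStatistic(self), 1)
  expect_equal(pValue(self), 1 / 1000)

  # cross-check r against vegan::mantel (spearman)
  other <- simulateNullCommunity(nTaxa = 30, nSamples = 10, seed = 37)
  bc2 <- brayCurtis(other$table)
  labs <- attr(bc, "Labels")
  attr(bc2, "Labels") <- labs
  got <- mantelTest(bc, bc2, nPerm = 99, seed = 4)
  ref <- vegan::mantel(bc, bc2, method = "spearman", permutations = 99)
  expect_lt(abs(observedStatistic(got) - ref$statistic), 1e-10)

  const <- matrix(1, 10, 10, dimnames = list(labs, labs))
  diag(const) <- 0
  expect_error(mantelTest(bc, const, nPerm = 99, seed = 1),
               class = "mnDegenerateResultError")
  bad <- as.matrix(bc2)
  rownames(bad) <- colnames(bad) <- rev(labs)
  expect_error(mantelTest(bc, bad, nPerm = 99, seed = 1),
               class = "mnAlignmentError")
})

test_that("nmds embeds exactly embeddable distances with near-zero stress", {
  set.seed(38)
  xy <- matrix(rnorm(20 * 2), 20, 2)
  rownames(xy) <- sprintf("s%d", 1:20)
  d <- dist(xy)
  ord <- nmdsOrdination(d, k = 2, nRestarts = 5, seed = 5)
  expect_lt(ordinationStress(ord), 0.01)
  expect_identical(rownames(ordinationScores(ord)), rownames(xy))

  # stress is invariant under orthogonal transformation of the input
  # configuration (rotation does not change the distances)
  theta <- pi / 5
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  ordRot <- nmdsOrdination(dist(xy %*% rot), k = 2, nRestarts = 5, seed = 5)
  expect_equal(ordinationStress(ordRot), ordinationStress(ord),
               tolerance = 1e-6)

  # planted group structure: separated groups and acceptable stress
  sim <- simulateCorrelatedCommunity(nTaxa = 40, samplesPerGroup = 5,
                                     groupEffectSd = 1.5, seed = 39)
  ordG <- nmdsOrdination(brayCurtis(sim$table), k = 2, seed = 6)
  expect_lt(ordinationStress(ordG), 0.2)
  sc <- ordinationScores(ordG)
  cent <- apply(sc, 2, tapply, sim$metadata$group, mean)
  within <- mean(sqrt(rowSums((sc - cent[sim$metadata$group, ])^2)))
  between <- mean(dist(cent))
  expect_lt(within, between)

  expect_error(nmdsOrdination(dist(xy[1:3, ]), k = 2, seed = 1),
               class = "mnSampleSizeError")
})

test_that("vif screening retains orthogonal sets and drops collinear columns", {
  set.seed(40)
  base <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3)))
  colnames(base) <- c("a", "b", "c")
  expect_setequal(vifScreen(base), c("a", "b", "c"))

  dupd <- cbind(base, a2 = base[, "a"])
  expect_warning(keep <- vifScreen(dupd), "collinear")
  expect_true("a" %in% keep && !"a2" %in% keep)

  # near-duplicate pair (r ~ 0.99): one of the pair leaves
  x <- rnorm(40)
  covs <- cbind(x1 = x, x2 = x + rnorm(40, sd = 0.05), x3 = rnorm(40))
  keep2 <- vifScreen(covs, threshold = 5)
  expect_identical(length(keep2), 2L)
  expect_true("x3" %in% keep2)
  expect_identical(sum(c("x1", "x2") %in% keep2), 1L)
  expect_error(vifScreen(covs[1:2, ]), class = "mnParameterError")
})
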