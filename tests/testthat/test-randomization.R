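test_that("anovaF matches hand decompositions, aov, and its sentinels", {
  # hand case: {1,2} vs {3,4} -> SSB = 4, SSW = 1, F = 4 / (1/2) = 8
  expect_equal(anovaF(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)), 8)
  # equal groups -> F = 0
  expect_equal(anovaF(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, FALSE), each = 3)), 0)
  # zero within-group variance, unequal means -> infinite sentinel
  expect_identical(anovaF(c(0, 0, 1, 1), c(TRUE, TRUE, FALSE, FALSE)), Inf)
  # agreement with R's own ANOVA on random data
  set.seed(42)
  for (i in 1:10) {
    v <- rnorm(15)
    lab <- sample(c(TRUE, FALSE), 15, replace = TRUE, prob = c(.3, .7))
    if (sum(lab) %in% c(0, 15)) next
    expect_equal(anovaF(v, lab), aovF(v, lab))
  }
  expect_error(anovaF(c(1, 2), c(TRUE, FALSE)), "n >= 3")
})

test_that("varDiffStat is symmetric in the group roles", {
  v <- c(1, 5, 2, 8, 3, 9)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(varDiffStat(v, lab), varDiffStat(v, !lab))
  expect_equal(varDiffStat(v, lab), abs(var(v[lab]) - var(v[!lab])))
})

test_that("the dyad universe is the paired birds, so n pairs give n^2 - n dyads", {
  co19 <- simPairedCohort(21, nPairs = 19, nLoci = 10)
  d19 <- buildDyadStatistic(co19, "sxy")
  expect_identical(nPairs(d19), 19L)
  expect_identical(nDyads(d19), 342L)
  co18 <- simPairedCohort(22, nPairs = 18, nLoci = 10)
  d18 <- buildDyadStatistic(co18, "sxy")
  expect_identical(nDyads(d18), 306L)
  # a single pair leaves no dyads: the test is undefined
  cfg <- cohortConfig(nMales = 1, nFemales = 1, propFemalePaired = 1, seed = 1)
  co1 <- simulatePairing(genCohort(cfg), cfg)
  expect_error(buildDyadStatistic(co1, "sxy"), "at least 2")
})

test_that("dyad matrices hold the same values the pairwise metrics return", {
  co <- setPairings(toyCohort(), toyPairings())
  for (met in c("sxy", "pdist_pbr", "pdist_pss", "relatedness_qg")) {
    d <- buildDyadStatistic(co, met)
    expect_identical(dim(d@values), c(3L, 3L))
    expect_identical(sum(d@pairMask), 3L)
    val <- function(f, m) switch(met,
      sxy = alleleSharing(co, f, m),
      pdist_pbr = dyadMeanPDistance(co, f, m, "pbr"),
      pdist_pss = dyadMeanPDistance(co, f, m, "pss"),
      relatedness_qg = relatednessQG(co, f, m))
    for (f in c("F1", "F3")) for (m in c("M1", "M2"))
      expect_equal(d@values[f, m], val(f, m))
  }
})

test_that("exhaustive enumeration covers exactly the admissible labelings", {
  co <- simPairedCohort(5, nPairs = 2, nLoci = 6)
  d <- buildDyadStatistic(co, "sxy")
  ex <- exhaustiveTest(d, "anova_f", "label_shuffle")
  expect_identical(ex@nPerm, 6L)            # C(4, 2)
  co3 <- simPairedCohort(6, nPairs = 3, nLoci = 6)
  d3 <- buildDyadStatistic(co3, "sxy")
  exm <- exhaustiveTest(d3, "anova_f", "matching_constrained")
  expect_identical(exm@nPerm, 6L)           # 3!
  expect_identical(exm@mode, "exhaustive")
  expect_error(exhaustiveTest(d3, maxLabelings = 10), "budget")
})

test_that("Monte-Carlo p converges to the exhaustive p (label shuffle)", {
  set.seed(7)
  worst <- 0
  for (i in 1:20) {
    vals <- matrix(rnorm(9), 3, 3)
    mask <- diag(3) == 1
    d <- new("DyadStatistic", femaleIds = paste0("f", 1:3),
             maleIds = paste0("m", 1:3), values = vals, pairMask = mask,
             metric = "synthetic")
    pEx <- pValue(exhaustiveTest(d, "anova_f", "label_shuffle"))
    pMc <- pValue(randomizationTest(d, "anova_f", nPerm = 10000,
                                    mode = "label_shuffle", seed = i))
    bound <- 3 * sqrt(pEx * (1 - pEx) / 10000)
    expect_lte(abs(pMc - pEx), max(bound, 3 / sqrt(10000) * 0.05))
    worst <- max(worst, abs(pMc - pEx))
  }
  expect_lt(worst, 0.05)
})

test_that("Monte-Carlo matches exhaustive enumeration under matching-constrained nulls", {
  co <- simPairedCohort(8, nPairs = 4, nLoci = 8)
  d <- buildDyadStatistic(co, "sxy")
  pEx <- pValue(exhaustiveTest(d, "anova_f", "matching_constrained"))
  pMc <- pValue(randomizationTest(d, "anova_f", nPerm = 20000,
                                  mode = "matching_constrained", seed = 2))
  expect_lte(abs(pMc - pEx), 3 * sqrt(pEx * (1 - pEx) / 20000) + 1e-9)
})

test_that("a maximal-F grouping attains the smallest achievable p", {
  # put the extreme values on the diagonal so the observed labeling maximizes F
  vals <- matrix(0.5, 3, 3) + matrix(rnorm(9, sd = 0.01), 3, 3)
  diag(vals) <- c(10, 10.1, 9.9)
  d <- new("DyadStatistic", femaleIds = paste0("f", 1:3),
           maleIds = paste0("m", 1:3), values = vals, pairMask = diag(3) == 1,
           metric = "synthetic")
  ex <- exhaustiveTest(d, "anova_f", "label_shuffle")
  allF <- apply(utils::combn(9, 3), 2, function(idx) {
    lab <- logical(9); lab[idx] <- TRUE
    anovaF(as.vector(vals), lab)
  })
  expect_equal(observedStat(ex), max(allF))
  expect_equal(pValue(ex), 1 / choose(9, 3))
})

test_that("constant cell values force p = 1 under both statistics", {
  vals <- matrix(0.4, 4, 4)
  d <- new("DyadStatistic", femaleIds = paste0("f", 1:4),
           maleIds = paste0("m", 1:4), values = vals, pairMask = diag(4) == 1,
           metric = "synthetic")
  expect_equal(pValue(randomizationTest(d, "anova_f", 500, seed = 1)), 1)
  expect_equal(observedStat(randomizationTest(d, "anova_f", 10, seed = 1)), 0)
  expect_equal(pValue(varianceRandomizationTest(d, 500, seed = 1)), 1)
})

test_that("variance test: pair group constant, dyads spread -> smallest attainable p", {
  vals <- matrix(c(0.5, -3, 3, 0.5), 2, 2)   # diagonal both 0.5
  d <- new("DyadStatistic", femaleIds = c("f1", "f2"), maleIds = c("m1", "m2"),
           values = vals, pairMask = diag(2) == 1, metric = "synthetic")
  ex <- exhaustiveTest(d, "var_diff", "label_shuffle")
  allS <- apply(utils::combn(4, 2), 2, function(idx) {
    lab <- logical(4); lab[idx] <- TRUE
    varDiffStat(as.vector(vals), lab)
  })
  expect_equal(observedStat(ex), max(allS))
  expect_equal(pValue(ex), mean(allS >= max(allS)))
})

test_that("p-values depend only on values and mask, not on cell ordering", {
  co <- simPairedCohort(9, nPairs = 4, nLoci = 8)
  d <- buildDyadStatistic(co, "sxy")
  set.seed(14)
  perm <- sample(4)
  d2 <- new("DyadStatistic", femaleIds = d@femaleIds[perm],
            maleIds = d@maleIds, values = d@values[perm, ],
            pairMask = d@pairMask[perm, ], metric = d@metric)
  # the exact test is order-invariant outright
  e1 <- exhaustiveTest(d, "anova_f", "label_shuffle")
  e2 <- exhaustiveTest(d2, "anova_f", "label_shuffle")
  expect_equal(observedStat(e1), observedStat(e2))
  expect_equal(pValue(e1), pValue(e2))
  # the Monte-Carlo estimate agrees to within sampling error
  r1 <- randomizationTest(d, "anova_f", 5000, seed = 11)
  r2 <- randomizationTest(d2, "anova_f", 5000, seed = 11)
  expect_equal(observedStat(r1), observedStat(r2))
  p <- pValue(e1)
  expect_lt(abs(pValue(r1) - pValue(r2)),
            6 * sqrt(p * (1 - p) / 5000) + 1e-12)
})

test_that("the same engine runs group comparisons (divorce design)", {
  v <- c(2, 3, 2.5, 9, 8, 10, 9.5)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  r <- groupRandomizationTest(v, lab, "anova_f", nPerm = 2000, seed = 5)
  # the observed split is the extreme one: p should be near 2 / C(7,3)
  expect_lt(pValue(r), 0.10)
  expect_equal(observedStat(r), anovaF(v, lab))
  expect_error(groupRandomizationTest(v, rep(TRUE, 7)), "non-empty")
})

test_that("randomization results are deterministic given the seed", {
  co <- simPairedCohort(13, nPairs = 8, nLoci = 8)
  d <- buildDyadStatistic(co, "sxy")
  r1 <- randomizationTest(d, "anova_f", 1000, seed = 77)
  r2 <- randomizationTest(d, "anova_f", 1000, seed = 77)
  expect_identical(pValue(r1), pValue(r2))
  expect_identical(r1@nExtreme, r2@nExtreme)
})
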