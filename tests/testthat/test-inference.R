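test_that("the pairing GLM recovers known logit coefficients at large n", {
  co <- glmRecoveryCohort(2000, b0 = -1.5, bAge = 1.2, bHs = 0.8, bDiv = 0.15,
                          seed = 41)
  fit <- fitPairingGLM(co)
  tab <- glmTable(fit)
  est <- setNames(tab$B, tab$term)
  expect_lt(abs(est[["ageClassold"]] - 1.2), 0.2)
  expect_lt(abs(est[["hs"]] - 0.8), 0.5)        # Hs has little spread, wider CI
  expect_lt(abs(est[["mhcDiv"]] - 0.15), 0.1)
  # internal consistency: odds-ratio column is exp(B), CI brackets it
  expect_equal(tab$oddsRatio, exp(tab$B))
  expect_true(all(tab$orLower <= tab$oddsRatio & tab$oddsRatio <= tab$orUpper))
})

test_that("under a null response the LR test is calibrated and R2 collapses", {
  ps <- c(); r2s <- c()
  for (s in 1:40) {
    co <- glmRecoveryCohort(300, b0 = 0, bAge = 0, bHs = 0, bDiv = 0,
                            seed = 900 + s)
    fit <- fitPairingGLM(co)
    ps <- c(ps, fit@lrP)
    r2s <- c(r2s, fit@nagelkerkeR2)
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(mean(r2s), 0.05)
})

test_that("Nagelkerke R2 matches a brute-force likelihood oracle on a 6-row toy", {
  co <- glmToy6()
  fit <- fitPairingGLM(co)
  # oracle: maximize the Bernoulli likelihood directly over the same design
  ind <- cohortIndividuals(co)
  males <- ind[ind$sex == "M", ]
  X <- cbind(1, as.numeric(mhcDiversity(co, males$id)),
             as.numeric(males$ageClass == "old"),
             as.numeric(standardizedHeterozygosity(co, males$id)))
  y <- as.numeric(males$paired)
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(b) -drop(t(X) %*% (y - plogis(drop(X %*% b))))
  opt <- optim(rep(0, 4), nll, grad, method = "BFGS",
               control = list(maxit = 10000, reltol = 1e-16))
  devModel <- 2 * opt$value
  # null MLE has the closed form logit(mean(y))
  devNull <- 2 * nll(c(qlogis(mean(y)), 0, 0, 0))
  r2Oracle <- (1 - exp((devModel - devNull) / 6)) / (1 - exp(-devNull / 6))
  expect_lt(abs(fit@nagelkerkeR2 - r2Oracle), 1e-6)
  expect_lt(abs(fit@deviance - devModel), 1e-6)
})

test_that("GLM refuses separated or incomplete designs", {
  co <- glmRecoveryCohort(40, b0 = -20, bAge = 60, bHs = 0, bDiv = 0, seed = 71)
  # paired iff old: complete separation on the age term
  ind <- cohortIndividuals(co)
  males <- ind$sex == "M"
  ind$paired[males] <- ind$ageClass[males] == "old"
  co2 <- Cohort(ind, genotypeMatrix(co), mhcMatrix(co))
  expect_error(fitPairingGLM(co2), "separation")
  ind$paired[males] <- NA
  co3 <- Cohort(ind, genotypeMatrix(co), mhcMatrix(co))
  expect_error(fitPairingGLM(co3), "status missing")
})

test_that("per-allele Fisher tests match enumeration and Bonferroni bookkeeping", {
  co <- glmRecoveryCohort(60, b0 = 0, bAge = 0, bHs = 0, bDiv = 0, seed = 83)
  res <- allelePairStatusTests(co, alpha = 0.05)
  expect_identical(nrow(res), 10L)
  expect_equal(unique(res$criticalP), 0.005)       # 0.05 / 10 variants
  expect_true(all(res$pairedCarrier + res$unpairedCarrier +
                  res$pairedNonCarrier + res$unpairedNonCarrier ==
                  sum(cohortIndividuals(co)$sex == "M")))
  # cross-check one variant against the hypergeometric enumeration
  r1 <- res[1, ]
  tab <- matrix(c(r1$pairedCarrier, r1$pairedNonCarrier,
                  r1$unpairedCarrier, r1$unpairedNonCarrier), 2)
  m <- sum(tab[, 1]); nn <- sum(tab[, 2]); k <- sum(tab[1, ])
  support <- max(0, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  pEnum <- sum(probs[probs <= dhyper(tab[1, 1], m, nn, k) * (1 + 1e-7)])
  expect_equal(r1$p, pEnum, tolerance = 1e-12)
  # proportional rows -> p = 1, OR = 1
  ind <- cohortIndividuals(co)
  males <- which(ind$sex == "M")
  m2 <- mhcMatrix(co)
  ind$paired[males] <- rep(c(TRUE, FALSE), 30)
  m2[males, "ua1"] <- rep(c(TRUE, TRUE, FALSE, FALSE), 15)
  m2[males, "ua2"] <- TRUE                        # fix rowSums > 0
  co4 <- Cohort(ind, genotypeMatrix(co), m2)
  res4 <- allelePairStatusTests(co4)
  expect_equal(res4$p[res4$variant == "ua1"], 1)
  expect_equal(res4$oddsRatio[res4$variant == "ua1"], 1)
})

test_that("two-sample tests match their base-R counterparts and conventions", {
  a <- c(1.2, 3.1, 2.2, 4.8)
  b <- c(2.0, 5.5, 6.1)
  w <- twoSampleTests(a, b, "welch_t")
  tt <- t.test(a, b)
  expect_equal(w$statistic, unname(tt$statistic))
  expect_equal(w$df, unname(tt$parameter))
  expect_equal(w$p, tt$p.value)
  r <- twoSampleTests(a, b, "rank_sum")
  wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(r$statistic, unname(wt$statistic))
  expect_equal(r$p, wt$p.value)
  # identical samples: t = 0, p = 1
  eq <- twoSampleTests(c(1, 2, 3), c(1, 2, 3), "welch_t")
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  # degenerate constant data flagged with p = 1
  cst <- twoSampleTests(c(2, 2), c(2, 2), "welch_t")
  expect_true(cst$degenerate)
  expect_equal(cst$p, 1)
  # a = {1,2}, b = {3,4}: rank-sum of a is minimal -> W (Mann-Whitney U) = 0
  lo <- twoSampleTests(c(1, 2), c(3, 4), "rank_sum")
  expect_equal(lo$statistic, 0)
})

test_that("divorce analysis wires the engine and refuses degenerate outcomes", {
  cfg <- cohortConfig(nMales = 30, nFemales = 30, propFemalePaired = 1,
                      effectDivorceMhcDiv = 2, seed = 19)
  co <- simulatePairing(genCohort(cfg), cfg)
  pr <- pairings(co)
  if (sum(pr$outcome == "divorced") < 2 || sum(pr$outcome == "stable") < 2) {
    cfg <- cohortConfig(nMales = 30, nFemales = 30, propFemalePaired = 1,
                        effectDivorceMhcDiv = 2, seed = 20)
    co <- simulatePairing(genCohort(cfg), cfg)
  }
  dv <- divorceAnalysis(co, nPerm = 1000, seed = 7)
  expect_s4_class(dv$maleDiversity, "RandTestResult")
  expect_identical(sort(dv$similarity$metric),
                   sort(c("sxy", "pdist_pbr", "pdist_pss")))
  expect_true(all(dv$similarity$p >= 0 & dv$similarity$p <= 1))
  # all pairs stable -> refuse
  pr$outcome <- "stable"
  co2 <- setPairings(co, pr)
  expect_error(divorceAnalysis(co2), "outcome group")
})

test_that("divorce diversity effect is detected in males more than females", {
  rejM <- 0; rejF <- 0; done <- 0
  for (s in 1:25) {
    cfg <- cohortConfig(nMales = 35, nFemales = 35, propFemalePaired = 1,
                        effectDivorceMhcDiv = 2.5, seed = 500 + s)
    co <- simulatePairing(genCohort(cfg), cfg)
    dv <- tryCatch(divorceAnalysis(co, nPerm = 400, seed = s),
                   error = function(e) NULL)
    if (is.null(dv)) next
    done <- done + 1
    rejM <- rejM + (pValue(dv$maleDiversity) <= 0.05)
    rejF <- rejF + (pValue(dv$femaleDiversity) <= 0.05)
  }
  expect_gt(done, 15)
  expect_gt(rejM, rejF)
})
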