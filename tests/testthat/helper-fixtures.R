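# Shared fixtures and independent brute-force oracles.  The oracles use
# naive loops and base-R primitives only, never the package's own code path.

# -- hand-built toy panel: 4 variants x 10 codons, masks chosen by hand ------
toyPanel <- function() {
  AllelePanel(c(
    ua1 = "ARNDCQEGHI",
    ua2 = "ARNECQEGHI",   # differs from ua1 at codon 4
    ua3 = "VRNDCQEGHW",   # differs from ua1 at codons 1, 10
    ua4 = "VRNECQEGHW"),  # differs from ua1 at codons 1, 4, 10
    masks = list(pbr = c(1L, 4L, 5L), pss = c(4L, 10L)))
}

# -- hand-built cohort: 3 females, 3 males, 2 loci, known repertoires --------
toyCohort <- function(panel = toyPanel()) {
  ids <- c("F1", "F2", "F3", "M1", "M2", "M3")
  ind <- data.frame(
    id = ids, sex = rep(c("F", "M"), each = 3),
    island = "toy",
    ageClass = c("young", "old", "young", "old", "young", "old"),
    stringsAsFactors = FALSE)
  g <- matrix(c(
    1, 2, 3, 3,
    1, 1, 3, 4,
    2, 2, 4, 4,
    1, 2, 3, 3,
    2, 2, 3, 3,
    1, 1, 4, 4), nrow = 6, byrow = TRUE,
    dimnames = list(ids, c("L01.1", "L01.2", "L02.1", "L02.2")))
  m <- matrix(FALSE, 6, 4, dimnames = list(ids, c("ua1", "ua2", "ua3", "ua4")))
  m["F1", c("ua1", "ua2")] <- TRUE
  m["F2", c("ua1", "ua2", "ua3", "ua4")] <- TRUE
  m["F3", c("ua3", "ua4")] <- TRUE
  m["M1", c("ua1", "ua2")] <- TRUE
  m["M2", c("ua2", "ua3")] <- TRUE
  m["M3", c("ua1", "ua2", "ua3")] <- TRUE
  Cohort(ind, g, m, panel = panel)
}

toyPairings <- function() {
  data.frame(femaleId = c("F1", "F2", "F3"), maleId = c("M1", "M2", "M3"),
             observed = TRUE, outcome = c("stable", "divorced", "stable"),
             stringsAsFactors = FALSE)
}

# -- independent oracles -----------------------------------------------------

naiveSxy <- function(repX, repY) {
  shared <- 0
  for (a in repX) for (b in repY) if (a == b) shared <- shared + 1
  2 * shared / (length(repX) + length(repY))
}

naivePDist <- function(sa, sb, mask) {
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  diff <- 0
  for (i in mask) if (ca[i] != cb[i]) diff <- diff + 1
  diff / length(mask)
}

naiveDyadMeanP <- function(repX, repY, seqs, mask) {
  tot <- 0; n <- 0
  for (a in repX) for (b in repY) {
    tot <- tot + naivePDist(seqs[[a]], seqs[[b]], mask)
    n <- n + 1
  }
  tot / n
}

# Queller-Goodnight by naive per-locus loops (genotype vectors, 2 per locus);
# same degenerate-denominator convention as the package: pool the two
# directions when one summed denominator vanishes
naiveQG <- function(gx, gy, freqs) {
  oneWay <- function(gx, gy) {
    num <- 0; den <- 0
    for (k in seq_along(freqs)) {
      a <- gx[2 * k - 1]; b <- gx[2 * k]
      c_ <- gy[2 * k - 1]; d <- gy[2 * k]
      if (anyNA(c(a, b, c_, d)) || length(freqs[[k]]) < 2) next
      pa <- freqs[[k]][as.character(a)]
      pb <- freqs[[k]][as.character(b)]
      if (anyNA(c(pa, pb))) next
      num <- num + 0.5 * ((a == c_) + (a == d) + (b == c_) + (b == d)) - pa - pb
      den <- den + 1 + (a == b) - pa - pb
    }
    c(num = unname(num), den = unname(den))
  }
  fx <- oneWay(gx, gy)
  fy <- oneWay(gy, gx)
  if (abs(fx["den"]) < 1e-12 || abs(fy["den"]) < 1e-12)
    return(unname((fx["num"] + fy["num"]) / (fx["den"] + fy["den"])))
  unname((fx["num"] / fx["den"] + fy["num"] / fy["den"]) / 2)
}

naiveHs <- function(g, locusHet) {
  L <- length(locusHet)
  hets <- c(); dens <- c()
  for (k in seq_len(L)) {
    a <- g[2 * k - 1]; b <- g[2 * k]
    if (is.na(a) || is.na(b)) next
    hets <- c(hets, as.numeric(a != b))
    dens <- c(dens, locusHet[k])
  }
  mean(hets) / mean(dens)
}

# ANOVA F via R's own linear-model machinery (independent of anovaF)
aovF <- function(values, labels) {
  fit <- stats::anova(stats::lm(values ~ factor(labels)))
  fit[["F value"]][1]
}

# cohort of males whose pairing status follows a known logit model;
# covariate effects are injected directly, bypassing the matching process
glmRecoveryCohort <- function(n, b0, bAge, bHs, bDiv, seed) {
  cfg <- cohortConfig(nMales = n, nFemales = 1, nMsatLoci = 20, seed = seed)
  co <- genCohort(cfg)
  ind <- cohortIndividuals(co)
  males <- ind$id[ind$sex == "M"]
  hs <- standardizedHeterozygosity(co, males)
  div <- mhcDiversity(co, males)
  old <- as.numeric(ind$ageClass[match(males, ind$id)] == "old")
  set.seed(seed + 1)
  eta <- b0 + bAge * old + bHs * hs + bDiv * div
  ind$paired <- FALSE
  ind$paired[match(males, ind$id)] <- runif(length(males)) < plogis(eta)
  Cohort(ind, genotypeMatrix(co), mhcMatrix(co), panel = cohortPanel(co))
}

# handcrafted 6-male cohort whose pairing pattern overlaps in every
# covariate, so the logit fit is identifiable (no separation)
glmToy6 <- function() {
  y <- c(0, 1, 0, 1, 1, 0)
  ids <- c(sprintf("M%d", 1:6), "F1")
  ind <- data.frame(id = ids, sex = c(rep("M", 6), "F"), island = "t",
    ageClass = c("young", "young", "young", "old", "old", "old", "young"),
    paired = c(y == 1, FALSE), stringsAsFactors = FALSE)
  g <- matrix(c(
    1, 2, 3, 4,
    1, 1, 3, 4,
    1, 2, 3, 3,
    1, 1, 4, 4,
    1, 2, 3, 4,
    2, 2, 3, 3,
    1, 2, 3, 4), nrow = 7, byrow = TRUE,
    dimnames = list(ids, c("L01.1", "L01.2", "L02.1", "L02.2")))
  m <- matrix(FALSE, 7, 8, dimnames = list(ids, paste0("ua", 1:8)))
  sizes <- c(2, 3, 4, 5, 6, 7, 3)
  for (i in 1:7) m[i, 1:sizes[i]] <- TRUE
  Cohort(ind, g, m)
}

# small simulated cohort with pairings attached, for engine-level tests
simPairedCohort <- function(seed, nPairs = 20L, effectCompat = 0,
                            nLoci = 30L) {
  cfg <- cohortConfig(nMales = nPairs, nFemales = nPairs,
                      nMsatLoci = nLoci, propFemalePaired = 1,
                      effectCompat = effectCompat, seed = seed)
  simulatePairing(genCohort(cfg), cfg)
}
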