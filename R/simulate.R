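#' Derive a deterministic sub-stream seed from a master seed
#'
#' All simulator stages draw from sub-streams derived from one master seed,
#' so that stages can be re-run independently yet the whole pipeline is
#' byte-reproducible.  The derivation is a fixed multiplicative hash of the
#' master seed and the stream label, reduced modulo 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param stream character label of the sub-stream.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
  as.integer((abs(as.numeric(seed)) %% 1048576 * 2654435 + h * 97) %% 2147483647)
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Generate a synthetic MHC allele panel
#'
#' Builds \code{mhcPoolSize} distinct amino-acid sequences of
#' \code{nCodons} residues around a random consensus, with elevated
#' substitution diversity at the masked (PBR/PSS) codons relative to the
#' unmasked background -- mimicking the footprint of balancing selection on
#' antigen-binding sites.  The PBR and PSS masks themselves are drawn once,
#' with \code{maskOverlap} PSS codons placed inside the PBR.
#'
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @return an \code{\linkS4class{AllelePanel}} with masks "pbr" and "pss".
#' @export
genAllelePanel <- function(config) {
  validObject(config)
  nc <- config@nCodons
  if (max(config@maskSizes) > nc)
    stop("mask position exceeds nCodons")
  set.seed(deriveSeed(config@seed, "panel"))
  pbr <- sort(sample.int(nc, config@maskSizes[["pbr"]]))
  nOut <- config@maskSizes[["pss"]] - config@maskOverlap
  outside <- setdiff(seq_len(nc), pbr)
  if (nOut > length(outside))
    stop("PSS mask does not fit outside the PBR with this overlap")
  pss <- sort(c(sample(pbr, config@maskOverlap),
                if (nOut > 0L) sample(outside, nOut)))
  consensus <- sample(.AA20, nc, replace = TRUE)
  masked <- union(pbr, pss)
  # per-site residue repertoires at masked codons (3 alternatives + consensus)
  alts <- lapply(masked, function(i) sample(setdiff(.AA20, consensus[i]), 3L))
  drawVariant <- function() {
    s <- consensus
    sub <- runif(length(masked)) < 0.5
    if (any(sub))
      s[masked[sub]] <- vapply(which(sub), function(j) sample(alts[[j]], 1L),
                               character(1))
    bg <- runif(nc) < 0.02
    bg[masked] <- FALSE
    if (any(bg))
      s[bg] <- vapply(which(bg), function(i) sample(setdiff(.AA20, consensus[i]), 1L),
                      character(1))
    paste(s, collapse = "")
  }
  seqs <- character(config@mhcPoolSize)
  for (v in seq_along(seqs)) {
    for (try in 1:1000) {
      cand <- drawVariant()
      if (!cand %in% seqs[seq_len(v - 1L)]) break
    }
    if (cand %in% seqs[seq_len(v - 1L)])
      stop("could not generate distinct variant sequences; enlarge masks")
    seqs[v] <- cand
  }
  names(seqs) <- sprintf("ua%d", seq_along(seqs))
  AllelePanel(seqs, masks = list(pbr = pbr, pss = pss))
}

.rdirichlet1 <- function(k, alpha = 1) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

#' Generate a synthetic cohort under Hardy-Weinberg proportions
#'
#' Simulates \code{nMales + nFemales} individuals: microsatellite genotypes
#' drawn locus-wise under Hardy-Weinberg proportions from per-locus allele
#' frequency spectra (symmetric Dirichlet(1)), MHC repertoire sizes uniform
#' on [mhcMin, mhcMax] with variant identities drawn without replacement
#' from the pool (uniform or Dirichlet pool frequencies), and age class
#' Bernoulli(propOld).  Deterministic given the config seed.
#'
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @param island island label stored on every individual.
#' @param panel optionally a pre-built \code{\linkS4class{AllelePanel}}
#'   (default: generated from the same config).
#' @return a \code{\linkS4class{Cohort}}; the simulated ("true") per-locus
#'   allele frequencies are retrievable with \code{\link{msatFreqs}}.
#' @export
genCohort <- function(config, island = "simisland", panel = genAllelePanel(config)) {
  validObject(config)
  if (config@nMales < 1L || config@nFemales < 1L)
    stop("need at least one male and one female")
  set.seed(deriveSeed(config@seed, paste0("cohort:", island)))
  n <- config@nMales + config@nFemales
  L <- config@nMsatLoci
  loci <- sprintf("L%02d", seq_len(L))
  freqs <- vector("list", L)
  names(freqs) <- loci
  g <- matrix(NA_real_, n, 2L * L)
  colnames(g) <- paste0(rep(loci, each = 2L), c(".1", ".2"))
  for (k in seq_len(L)) {
    nal <- config@msatAllelesPerLocus
    f <- .rdirichlet1(nal)
    labels <- 100 + 2 * seq_len(nal)   # fragment-size-style allele labels
    names(f) <- labels
    freqs[[k]] <- f
    g[, 2L * k - 1L] <- sample(labels, n, replace = TRUE, prob = f)
    g[, 2L * k]      <- sample(labels, n, replace = TRUE, prob = f)
  }
  poolFreqs <- if (config@poolDirichletAlpha > 0)
    .rdirichlet1(config@mhcPoolSize, config@poolDirichletAlpha)
  else rep(1 / config@mhcPoolSize, config@mhcPoolSize)
  vnames <- variantNames(panel)
  mhc <- matrix(FALSE, n, config@mhcPoolSize,
                dimnames = list(NULL, vnames))
  sizes <- config@mhcMin +
    sample.int(config@mhcMax - config@mhcMin + 1L, n, replace = TRUE) - 1L
  for (i in seq_len(n))
    mhc[i, sample(vnames, sizes[i], prob = poolFreqs)] <- TRUE
  ids <- c(sprintf("M%03d", seq_len(config@nMales)),
           sprintf("F%03d", seq_len(config@nFemales)))
  ind <- data.frame(
    id = ids,
    sex = rep(c("M", "F"), c(config@nMales, config@nFemales)),
    island = island,
    ageClass = ifelse(stats::rbinom(n, 1, config@propOld) == 1, "old", "young"),
    paired = NA, mateId = NA_character_, divorceStatus = NA_character_,
    hasMHC = TRUE, stringsAsFactors = FALSE)
  rownames(g) <- ids
  rownames(mhc) <- ids
  attr(g, "msatFreqs") <- freqs
  Cohort(ind, g, mhc, panel = panel)
}

#' True simulated allele frequencies of a synthetic cohort
#'
#' @param cohort a cohort produced by \code{\link{genCohort}}.
#' @return named list of per-locus frequency vectors, or NULL for cohorts
#'   read from disk (use \code{\link{populationReference}} then).
#' @export
msatFreqs <- function(cohort) attr(genotypeMatrix(cohort), "msatFreqs")

# PopulationReference from known (true) frequencies; obsHet = HWE expectation
.refFromFreqs <- function(freqs) {
  new("PopulationReference", loci = names(freqs), freqs = freqs,
      obsHet = vapply(freqs, function(f) 1 - sum(f^2), numeric(1)))
}

.sampleGenotypes <- function(freqs, n) {
  L <- length(freqs)
  g <- matrix(NA_real_, n, 2L * L)
  colnames(g) <- paste0(rep(names(freqs), each = 2L), c(".1", ".2"))
  for (k in seq_len(L)) {
    lab <- as.numeric(names(freqs[[k]]))
    g[, 2L * k - 1L] <- sample(lab, n, replace = TRUE, prob = freqs[[k]])
    g[, 2L * k]      <- sample(lab, n, replace = TRUE, prob = freqs[[k]])
  }
  g
}

# one gamete per row from a parental genotype matrix
.gamete <- function(g) {
  L <- ncol(g) / 2L
  pick <- matrix(sample(c(0L, 1L), nrow(g) * L, replace = TRUE), nrow(g), L)
  out <- matrix(NA_real_, nrow(g), L)
  for (k in seq_len(L))
    out[, k] <- ifelse(pick[, k] == 0L, g[, 2L * k - 1L], g[, 2L * k])
  out
}

.combineGametes <- function(ga, gb, loci) {
  L <- ncol(ga)
  g <- matrix(NA_real_, nrow(ga), 2L * L)
  colnames(g) <- paste0(rep(loci, each = 2L), c(".1", ".2"))
  g[, 2L * seq_len(L) - 1L] <- ga
  g[, 2L * seq_len(L)]      <- gb
  g
}

#' Simulate dyads of known pedigree relationship
#'
#' Constructs genotype pairs by Mendelian transmission from parents drawn
#' under Hardy-Weinberg proportions at the cohort's (true) allele
#' frequencies.  Expected Queller-Goodnight relatedness is 0.5 for
#' parent-offspring and full-sib dyads, 0.25 for half-sibs, 0 for unrelated
#' dyads.
#'
#' @param cohort a cohort carrying simulated frequencies
#'   (\code{\link{msatFreqs}}).
#' @param relationship one of "parent_offspring", "full_sib", "half_sib",
#'   "unrelated".
#' @param n number of dyads (>= 1).
#' @param seed RNG seed.
#' @return list with genotype matrices \code{x} and \code{y} (one dyad per
#'   row), the \code{relationship}, and \code{ref}, the
#'   \code{\linkS4class{PopulationReference}} built from the true
#'   frequencies (HWE expected heterozygosities).
#' @export
genRelatedDyads <- function(cohort,
                            relationship = c("parent_offspring", "full_sib",
                                             "half_sib", "unrelated"),
                            n, seed = 1L) {
  relationship <- match.arg(relationship)
  if (n < 1L) stop("n must be >= 1")
  freqs <- msatFreqs(cohort)
  if (is.null(freqs))
    stop("cohort carries no simulated allele frequencies")
  set.seed(deriveSeed(seed, paste0("dyads:", relationship)))
  loci <- names(freqs)
  if (relationship == "unrelated") {
    x <- .sampleGenotypes(freqs, n)
    y <- .sampleGenotypes(freqs, n)
  } else if (relationship == "parent_offspring") {
    x <- .sampleGenotypes(freqs, n)                 # the parent
    mate <- .sampleGenotypes(freqs, n)
    y <- .combineGametes(.gamete(x), .gamete(mate), loci)
  } else if (relationship == "full_sib") {
    p1 <- .sampleGenotypes(freqs, n)
    p2 <- .sampleGenotypes(freqs, n)
    x <- .combineGametes(.gamete(p1), .gamete(p2), loci)
    y <- .combineGametes(.gamete(p1), .gamete(p2), loci)
  } else {                                          # half_sib: shared father
    dad <- .sampleGenotypes(freqs, n)
    m1 <- .sampleGenotypes(freqs, n)
    m2 <- .sampleGenotypes(freqs, n)
    x <- .combineGametes(.gamete(dad), .gamete(m1), loci)
    y <- .combineGametes(.gamete(dad), .gamete(m2), loci)
  }
  list(x = x, y = y, relationship = relationship, ref = .refFromFreqs(freqs))
}

#' Simulate the social pairing and divorce process
#'
#' Females, taken in uniform random order, each pair with probability
#' \code{propFemalePaired}.  A pairing female chooses among the currently
#' unpaired males with probability proportional to
#' \code{exp(effectAge * old + effectHs * Hs + effectMhcDiv * diversity +
#' effectCompat * (1 - Sxy with her))}, yielding a one-to-one matching.
#' Each realised pair then divorces with log-odds
#' \code{qlogis(divorceBaseRate) - effectDivorceMhcDiv * (male diversity -
#' pool-expected diversity)}.  With all effects zero this is a uniform
#' random matching -- the null hypothesis of every downstream test.
#'
#' @param cohort a \code{\linkS4class{Cohort}}.
#' @param config the \code{\linkS4class{CohortConfig}} providing effects,
#'   \code{propFemalePaired} and the master seed.
#' @return the cohort with pairing records attached (see
#'   \code{\link{pairings}}); unpaired birds are retained with
#'   \code{paired = FALSE}.
#' @export
simulatePairing <- function(cohort, config) {
  ind <- cohortIndividuals(cohort)
  females <- ind$id[ind$sex == "F"]
  males <- ind$id[ind$sex == "M"]
  if (length(females) < 1L || length(males) < 1L)
    stop("cohort must contain at least one male and one female")
  set.seed(deriveSeed(config@seed, "pairing"))
  hs <- standardizedHeterozygosity(cohort, males)
  div <- mhcDiversity(cohort, males)
  old <- as.numeric(ind$ageClass[match(males, ind$id)] == "old")
  m <- mhcMatrix(cohort)
  fIdx <- match(females, ind$id)
  mIdx <- match(males, ind$id)
  available <- rep(TRUE, length(males))
  recF <- character(); recM <- character()
  for (f in sample(females)) {
    if (stats::runif(1) > config@propFemalePaired) next
    if (!any(available)) {
      warning(sprintf("female %s must pair but no male is available", f))
      next
    }
    rx <- m[match(f, ind$id), ]
    sxy <- apply(m[mIdx, , drop = FALSE], 1L, function(ry) .sxy(rx, ry))
    score <- config@effectAge * old + config@effectHs * hs +
      config@effectMhcDiv * div + config@effectCompat * (1 - sxy)
    w <- exp(score - max(score[available]))       # softmax-stable weights
    w[!available] <- 0
    chosen <- sample(males, 1L, prob = w)
    available[match(chosen, males)] <- FALSE
    recF <- c(recF, f); recM <- c(recM, chosen)
  }
  expDiv <- (config@mhcMin + config@mhcMax) / 2
  outcome <- character(length(recM))
  if (length(recM)) {
    lo <- stats::qlogis(config@divorceBaseRate) -
      config@effectDivorceMhcDiv * (div[recM] - expDiv)
    outcome <- ifelse(stats::runif(length(recM)) < stats::plogis(lo),
                      "divorced", "stable")
  }
  tab <- data.frame(femaleId = recF, maleId = recM,
                    observed = rep(TRUE, length(recF)),
                    outcome = outcome, stringsAsFactors = FALSE)
  setPairings(cohort, tab)
}
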