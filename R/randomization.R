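#' DyadStatistic: a female x male metric matrix with the observed pairs marked
#'
#' The universe of the pair-versus-dyad comparison: every combination of the
#' paired females with the paired males, each cell holding the value of one
#' genetic metric, and a logical mask marking the n observed social pairs.
#' With n pairs the universe has n^2 cells, so n^2 - n "dyads" (all other
#' possible combinations).
#'
#' @slot femaleIds,maleIds row/column identities.
#' @slot values numeric matrix (females x males) of the metric.
#' @slot pairMask logical matrix of the same shape; exactly one TRUE per row
#'   and per column (the observed one-to-one matching).
#' @slot metric label of the metric ("sxy", "pdist_pbr", "pdist_pss",
#'   "relatedness_qg", ...).
#' @seealso \code{\link{buildDyadStatistic}}, \code{\link{randomizationTest}}
#' @export
setClass("DyadStatistic",
  representation(femaleIds = "character", maleIds = "character",
                 values = "matrix", pairMask = "matrix", metric = "character"))

setValidity("DyadStatistic", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (!identical(dim(object@pairMask), d))
    msg <- c(msg, "values and pairMask must have identical dimensions")
  if (length(object@femaleIds) != d[1L] || length(object@maleIds) != d[2L])
    msg <- c(msg, "id vectors must match matrix dimensions")
  if (!is.logical(object@pairMask))
    msg <- c(msg, "pairMask must be logical")
  else {
    if (any(rowSums(object@pairMask) > 1L) || any(colSums(object@pairMask) > 1L))
      msg <- c(msg, "pairMask must mark at most one pair per female and per male")
  }
  if (anyNA(object@values))
    msg <- c(msg, "metric values must not be NA")
  if (length(msg)) msg else TRUE
})

#' @describeIn DyadStatistic number of observed pairs.
#' @param d,object a \code{DyadStatistic}.
#' @export
nPairs <- function(d) sum(d@pairMask)

#' @describeIn DyadStatistic number of non-pair combinations (dyads).
#' @export
nDyads <- function(d) length(d@values) - sum(d@pairMask)

#' @describeIn DyadStatistic metric values of the observed pairs.
#' @export
pairValues <- function(d) d@values[d@pairMask]

#' @describeIn DyadStatistic metric values of the dyads.
#' @export
dyadValues <- function(d) d@values[!d@pairMask]

setMethod("show", "DyadStatistic", function(object) {
  cat(sprintf("DyadStatistic '%s': %d pairs vs %d dyads (%d F x %d M)\n",
              object@metric, nPairs(object), nDyads(object),
              nrow(object@values), ncol(object@values)))
  cat(sprintf("  pair mean %.4g, dyad mean %.4g\n",
              mean(pairValues(object)), mean(dyadValues(object))))
})

#' Build the pair-versus-dyad metric matrix
#'
#' Computes the chosen metric for every combination of the paired females
#' with the paired males and marks the observed pairs.  The universe is the
#' paired birds only, so n pairs yield n^2 - n dyads (19 pairs -> 342
#' dyads; 18 -> 306).  At least two pairs are required for the comparison to
#' be defined.
#'
#' @param cohort a \code{\linkS4class{Cohort}} with pairing records.
#' @param metric one of "sxy", "pdist_pbr", "pdist_pss", "relatedness_qg".
#' @param pairs optional pairing table (default: the cohort's observed
#'   pairings).
#' @param ref \code{\linkS4class{PopulationReference}} for
#'   "relatedness_qg" (default: computed from the cohort).
#' @return a \code{\linkS4class{DyadStatistic}}.
#' @export
buildDyadStatistic <- function(cohort,
                               metric = c("sxy", "pdist_pbr", "pdist_pss",
                                          "relatedness_qg"),
                               pairs = NULL, ref = NULL) {
  metric <- match.arg(metric)
  if (is.null(pairs)) pairs <- pairings(cohort)
  pairs <- pairs[pairs$observed, , drop = FALSE]
  np <- nrow(pairs)
  if (np < 2L)
    stop("need at least 2 observed pairs (1 pair gives 0 dyads: test undefined)")
  fem <- pairs$femaleId
  mal <- pairs$maleId
  ind <- cohortIndividuals(cohort)
  i <- match(c(fem, mal), ind$id)
  if (anyNA(i)) stop("pairing table names individuals absent from the cohort")
  vals <- matrix(NA_real_, np, np, dimnames = list(fem, mal))
  if (metric == "sxy") {
    m <- mhcMatrix(cohort)
    if (any(!ind$hasMHC[i]))
      stop(sprintf("missing MHC data for: %s",
                   paste(ind$id[i][!ind$hasMHC[i]], collapse = ", ")))
    for (a in seq_len(np))
      for (b in seq_len(np))
        vals[a, b] <- .sxy(m[match(fem[a], ind$id), ], m[match(mal[b], ind$id), ])
  } else if (metric %in% c("pdist_pbr", "pdist_pss")) {
    panel <- cohortPanel(cohort)
    if (is.null(panel)) stop("cohort has no allele panel attached")
    D <- panelPDistMatrix(panel, sub("^pdist_", "", metric))
    for (a in seq_len(np))
      for (b in seq_len(np))
        vals[a, b] <- dyadMeanPDistance(cohort, fem[a], mal[b], pdistMatrix = D)
  } else {
    if (is.null(ref)) ref <- populationReference(cohort)
    g <- genotypeMatrix(cohort)
    for (a in seq_len(np))
      for (b in seq_len(np))
        vals[a, b] <- qgFromGenotypes(g[match(fem[a], ind$id), ],
                                      g[match(mal[b], ind$id), ], ref)
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("metric '%s' undefined for dyad %s x %s",
                 metric, fem[bad[1L]], mal[bad[2L]]))
  }
  mask <- matrix(FALSE, np, np, dimnames = dimnames(vals))
  mask[cbind(seq_len(np), seq_len(np))] <- TRUE    # pairs are the diagonal
  new("DyadStatistic", femaleIds = fem, maleIds = mal,
      values = vals, pairMask = mask, metric = metric)
}

#' One-way two-group ANOVA F statistic
#'
#' F = between-group mean square / within-group mean square for the
#' two-group case (1 and n - 2 degrees of freedom).  When the within-group
#' variance is zero, F is 0 if the group means are also equal and +Inf
#' otherwise (the infinite sentinel ranks above every finite F in the
#' permutation tail count).
#'
#' @param values numeric vector.
#' @param labels logical vector: TRUE = pair group, FALSE = dyad group.
#' @return a nonnegative number (possibly Inf).
#' @export
anovaF <- function(values, labels) {
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  n1 <- sum(labels); n2 <- sum(!labels); n <- n1 + n2
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  if (n < 3L) stop("need total n >= 3")
  g1 <- values[labels]; g2 <- values[!labels]
  m1 <- mean(g1); m2 <- mean(g2); gm <- mean(values)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- sum((g1 - m1)^2) + sum((g2 - m2)^2)
  tol <- 1e-12 * max(1, sum(values^2))
  if (ssw <= tol) {
    if (ssb <= tol) return(0)
    return(Inf)
  }
  (ssb / 1) / (ssw / (n - 2))
}

#' Absolute difference of group variances
#'
#' The statistic of the variance randomization test:
#' |var(pair group) - var(dyad group)| (sample variances).  Symmetric in the
#' two groups.
#'
#' @inheritParams anovaF
#' @return a nonnegative number.
#' @export
varDiffStat <- function(values, labels) {
  n1 <- sum(labels); n2 <- sum(!labels)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 values for a variance")
  abs(stats::var(values[labels]) - stats::var(values[!labels]))
}

#' RandTestResult: one randomization test
#'
#' @slot observedStat observed statistic on the real grouping.
#' @slot nPerm number of resamples (or enumerated labelings).
#' @slot pValue proportion of resamples with statistic >= observed (ties
#'   count as extreme).
#' @slot mode "label_shuffle", "matching_constrained" or "exhaustive".
#' @slot statistic "anova_f" or "var_diff".
#' @slot seed RNG seed used (NA for exhaustive).
#' @slot nExtreme resamples at least as extreme as observed.
#' @export
setClass("RandTestResult",
  representation(observedStat = "numeric", nPerm = "integer",
                 pValue = "numeric", mode = "character",
                 statistic = "character", seed = "integer",
                 nExtreme = "integer"))

setValidity("RandTestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("pValue outside [0,1]")
  TRUE
})

setMethod("show", "RandTestResult", function(object) {
  cat(sprintf("RandTestResult (%s, %s): observed = %.4g, p = %.4g (%d/%d)\n",
              object@statistic, object@mode, object@observedStat,
              object@pValue, object@nExtreme, object@nPerm))
})

#' @describeIn RandTestResult the permutation p-value.
#' @param r a \code{RandTestResult}.
#' @export
pValue <- function(r) r@pValue

#' @describeIn RandTestResult the observed statistic.
#' @export
observedStat <- function(r) r@observedStat

.statFun <- function(statistic) {
  switch(statistic, anova_f = anovaF, var_diff = varDiffStat,
         stop(sprintf("unknown statistic '%s'", statistic)))
}

# shared tail rule: ties (to within numeric tolerance) count as extreme
.countExtreme <- function(permStats, obs) {
  tol <- 1e-9 * max(1, abs(obs[is.finite(obs)]), 0)
  sum(permStats >= obs - tol)
}

.makeResult <- function(obs, permStats, nPerm, mode, statistic, seed) {
  nExtreme <- .countExtreme(permStats, obs)
  new("RandTestResult", observedStat = obs, nPerm = as.integer(nPerm),
      pValue = nExtreme / nPerm, mode = mode, statistic = statistic,
      seed = as.integer(seed), nExtreme = as.integer(nExtreme))
}

# core Monte-Carlo engine on a flat value vector + logical labels
.permEngine <- function(values, labels, statistic, nPerm, mode, seed,
                        dim = NULL) {
  stat <- .statFun(statistic)
  obs <- stat(values, labels)
  set.seed(deriveSeed(seed, paste0("permtest:", statistic)))
  nCells <- length(values)
  k <- sum(labels)
  permStats <- numeric(nPerm)
  if (mode == "label_shuffle") {
    lab <- logical(nCells)
    for (b in seq_len(nPerm)) {
      lab[] <- FALSE
      lab[sample.int(nCells, k)] <- TRUE
      permStats[b] <- stat(values, lab)
    }
  } else if (mode == "matching_constrained") {
    if (is.null(dim) || dim[1L] != dim[2L])
      stop("matching_constrained requires a square female x male universe")
    np <- dim[1L]
    vmat <- matrix(values, np, np)
    lab <- matrix(FALSE, np, np)
    for (b in seq_len(nPerm)) {
      perm <- sample.int(np)
      lab[] <- FALSE
      lab[cbind(seq_len(np), perm)] <- TRUE
      permStats[b] <- stat(as.vector(vmat), as.vector(lab))
    }
  } else stop(sprintf("unknown mode '%s'", mode))
  .makeResult(obs, permStats, nPerm, mode, statistic, seed)
}

#' Pair-versus-dyad randomization test
#'
#' Computes the observed statistic (ANOVA F on group means, or the absolute
#' variance difference) between the observed pairs and all other dyads,
#' then re-labels which cells are "pairs" \code{nPerm} times and reports
#' the proportion of resamples whose statistic equals or exceeds the
#' observed one.  Two null universes are available: \code{label_shuffle}
#' draws a uniform n-subset of all cells (values shuffled without
#' replacement between the groups), while \code{matching_constrained} draws
#' a uniform random perfect matching (each female re-paired to one male) --
#' the biologically faithful re-pairing null.  Deterministic given
#' \code{seed}.
#'
#' @param d a \code{\linkS4class{DyadStatistic}}.
#' @param statistic "anova_f" (means) or "var_diff" (variances).
#' @param nPerm number of resamples (default 1e5).
#' @param mode "label_shuffle" (default) or "matching_constrained".
#' @param seed RNG seed.
#' @return a \code{\linkS4class{RandTestResult}}.
#' @seealso \code{\link{exhaustiveTest}} for the exact small-sample oracle.
#' @export
randomizationTest <- function(d, statistic = c("anova_f", "var_diff"),
                              nPerm = 100000L,
                              mode = c("label_shuffle", "matching_constrained"),
                              seed = 1L) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  if (nPairs(d) < 1L || nDyads(d) < 1L)
    stop("need at least one pair and one dyad")
  .permEngine(as.vector(d@values), as.vector(d@pairMask), statistic,
              nPerm, mode, seed, dim = dim(d@values))
}

#' Variance randomization test
#'
#' Convenience wrapper for \code{\link{randomizationTest}} with
#' \code{statistic = "var_diff"}: tests whether observed pairs are more (or
#' less) variable in the metric than random dyads, the signature of an
#' optimal-similarity preference hiding under an unshifted mean.
#'
#' @inheritParams randomizationTest
#' @export
varianceRandomizationTest <- function(d, nPerm = 100000L,
                                      mode = c("label_shuffle",
                                               "matching_constrained"),
                                      seed = 1L) {
  if (nPairs(d) < 2L) stop("variance test needs >= 2 pairs")
  randomizationTest(d, statistic = "var_diff", nPerm = nPerm,
                    mode = match.arg(mode), seed = seed)
}

#' Exact permutation test by full enumeration
#'
#' Enumerates every admissible relabeling -- all C(n^2, n) cell subsets for
#' \code{label_shuffle}, all n! perfect matchings for
#' \code{matching_constrained} -- and returns the exact p-value.  Refuses
#' designs whose enumeration exceeds \code{maxLabelings}; use
#' \code{\link{randomizationTest}} then.
#'
#' @inheritParams randomizationTest
#' @param maxLabelings enumeration budget (default 1e6).
#' @return a \code{\linkS4class{RandTestResult}} with mode "exhaustive".
#' @export
exhaustiveTest <- function(d, statistic = c("anova_f", "var_diff"),
                           mode = c("label_shuffle", "matching_constrained"),
                           maxLabelings = 1e6) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  stat <- .statFun(statistic)
  values <- as.vector(d@values)
  obs <- stat(values, as.vector(d@pairMask))
  np <- nPairs(d)
  nCells <- length(values)
  if (mode == "label_shuffle") {
    total <- choose(nCells, np)
    if (total > maxLabelings)
      stop(sprintf("C(%d, %d) = %g labelings exceeds the enumeration budget; use randomizationTest()",
                   nCells, np, total))
    combos <- utils::combn(nCells, np)
    permStats <- apply(combos, 2L, function(idx) {
      lab <- logical(nCells); lab[idx] <- TRUE
      stat(values, lab)
    })
  } else {
    total <- factorial(np)
    if (total > maxLabelings)
      stop(sprintf("%d! = %g matchings exceeds the enumeration budget; use randomizationTest()",
                   np, total))
    perms <- .allPermutations(np)
    vmat <- d@values
    permStats <- vapply(perms, function(perm) {
      lab <- matrix(FALSE, np, np)
      lab[cbind(seq_len(np), perm)] <- TRUE
      stat(as.vector(vmat), as.vector(lab))
    }, numeric(1))
  }
  .makeResult(obs, permStats, length(permStats), "exhaustive", statistic,
              NA_integer_)
}

# all permutations of 1..n as a list (n small; guarded by caller's budget)
.allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Two-group randomization test on a plain value vector
#'
#' The same engine as \code{\link{randomizationTest}} for groupings that are
#' not female x male universes -- e.g. divorced versus stable males compared
#' on MHC diversity.  Group labels are shuffled uniformly.
#'
#' @param values numeric vector.
#' @param groupLabels logical vector (TRUE = focal group).
#' @param statistic "anova_f" or "var_diff".
#' @param nPerm resample count.
#' @param seed RNG seed.
#' @return a \code{\linkS4class{RandTestResult}}.
#' @export
groupRandomizationTest <- function(values, groupLabels,
                                   statistic = c("anova_f", "var_diff"),
                                   nPerm = 10000L, seed = 1L) {
  statistic <- match.arg(statistic)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  if (sum(groupLabels) < 1L || sum(!groupLabels) < 1L)
    stop("both groups must be non-empty")
  .permEngine(values, groupLabels, statistic, nPerm, "label_shuffle", seed)
}
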