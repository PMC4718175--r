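#' GlmResult: binomial logit model of male pairing status
#'
#' @slot table data.frame, one row per model term: coefficient \code{B},
#'   \code{SE}, Wald \code{z}, two-sided \code{p}, odds ratio
#'   \code{exp(B)} and its Wald 95% CI \code{exp(B +/- 1.96 SE)}.
#' @slot deviance,nullDeviance residual deviances of the fitted and
#'   intercept-only models.
#' @slot lrChisq,lrDf,lrP likelihood-ratio test of the full model against
#'   the intercept-only model.
#' @slot nagelkerkeR2 rescaled likelihood-ratio pseudo R-squared in [0, 1].
#' @slot n number of males modelled.
#' @export
setClass("GlmResult",
  representation(table = "data.frame", deviance = "numeric",
                 nullDeviance = "numeric", lrChisq = "numeric",
                 lrDf = "integer", lrP = "numeric",
                 nagelkerkeR2 = "numeric", n = "integer"))

setValidity("GlmResult", function(object) {
  msg <- character()
  if (object@lrChisq < -1e-8)
    msg <- c(msg, "LR chi-square must be nonnegative")
  if (object@nagelkerkeR2 < -1e-8 || object@nagelkerkeR2 > 1 + 1e-8)
    msg <- c(msg, "Nagelkerke R2 must lie in [0,1]")
  tab <- object@table
  if (nrow(tab) &&
      any(tab$oddsRatio < tab$orLower - 1e-8 | tab$oddsRatio > tab$orUpper + 1e-8))
    msg <- c(msg, "odds-ratio CI must bracket the odds ratio")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GlmResult", function(object) {
  cat(sprintf("Binomial logit model of male pairing status (n = %d)\n", object@n))
  print(format(object@table, digits = 3))
  cat(sprintf("Model chi2 = %.2f, df = %d, P = %.3g; R2 = %.2f (Nagelkerke)\n",
              object@lrChisq, object@lrDf, object@lrP, object@nagelkerkeR2))
})

#' @describeIn GlmResult the per-term coefficient table.
#' @param x a \code{GlmResult}.
#' @export
glmTable <- function(x) x@table

#' Nagelkerke's rescaled pseudo R-squared
#'
#' R2 = [1 - exp((D_model - D_null) / n)] / [1 - exp(-D_null / n)], where D
#' are the residual deviances.  Equals 0 when the model explains nothing
#' and 1 at perfect prediction.
#'
#' @param devModel,devNull residual deviances of the fitted and
#'   intercept-only models.
#' @param n number of observations.
#' @return a value in [0, 1].
#' @export
nagelkerkeR2 <- function(devModel, devNull, n) {
  (1 - exp((devModel - devNull) / n)) / (1 - exp(-devNull / n))
}

#' Binomial GLM of male pairing status
#'
#' Fits \code{paired ~ mhcDiv + ageClass + hs + island} with binomial errors
#' and logit link over all MHC-typed males: MHC diversity and standardized
#' heterozygosity (Hs) as covariates, age class and island as treatment-coded
#' factors (reference: young, alphabetically first island).  Reports Wald
#' inference per term, the likelihood-ratio test against the intercept-only
#' model, and Nagelkerke's R2.  \code{quadratic = TRUE} adds an
#' MHC-diversity squared term to probe an intermediate-optimum effect.
#'
#' @param cohort a \code{\linkS4class{Cohort}} whose males have known
#'   pairing status.
#' @param ref a \code{\linkS4class{PopulationReference}} for Hs (default:
#'   whole cohort).
#' @param quadratic add \code{I(mhcDiv^2)}?
#' @return a \code{\linkS4class{GlmResult}}.
#' @export
fitPairingGLM <- function(cohort, ref = populationReference(cohort),
                          quadratic = FALSE) {
  ind <- cohortIndividuals(cohort)
  males <- ind[ind$sex == "M" & ind$hasMHC, , drop = FALSE]
  if (any(is.na(males$paired)))
    stop(sprintf("pairing status missing for males: %s",
                 paste(males$id[is.na(males$paired)], collapse = ", ")))
  if (any(is.na(males$ageClass)))
    stop(sprintf("age class missing for males: %s",
                 paste(males$id[is.na(males$ageClass)], collapse = ", ")))
  dat <- data.frame(
    paired = as.numeric(males$paired),
    mhcDiv = as.numeric(mhcDiversity(cohort, males$id)),
    ageClass = factor(males$ageClass, levels = c("young", "old")),
    hs = as.numeric(standardizedHeterozygosity(cohort, males$id, ref)),
    island = factor(males$island))
  terms <- c("mhcDiv", if (quadratic) "I(mhcDiv^2)", "ageClass", "hs",
             if (nlevels(dat$island) > 1L) "island")
  form <- stats::as.formula(paste("paired ~", paste(terms, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = dat)
  if (!fit$converged || any(abs(stats::coef(fit)[-1L]) > 15, na.rm = TRUE)) {
    worst <- names(which.max(abs(stats::coef(fit)[-1L])))
    stop(sprintf("apparent complete separation (term '%s'); model not identifiable",
                 worst))
  }
  sm <- summary(fit)$coefficients
  tab <- data.frame(
    term = rownames(sm), B = sm[, 1L], SE = sm[, 2L], z = sm[, 3L],
    p = sm[, 4L], oddsRatio = exp(sm[, 1L]),
    orLower = exp(sm[, 1L] - 1.96 * sm[, 2L]),
    orUpper = exp(sm[, 1L] + 1.96 * sm[, 2L]),
    row.names = NULL)
  lr <- fit$null.deviance - fit$deviance
  lrDf <- fit$df.null - fit$df.residual
  new("GlmResult", table = tab, deviance = fit$deviance,
      nullDeviance = fit$null.deviance, lrChisq = lr, lrDf = as.integer(lrDf),
      lrP = stats::pchisq(lr, lrDf, lower.tail = FALSE),
      nagelkerkeR2 = nagelkerkeR2(fit$deviance, fit$null.deviance, nrow(dat)),
      n = nrow(dat))
}

#' Per-allele Fisher exact tests of pairing status
#'
#' For each MHC variant present in at least one male, tests independence of
#' carrying the variant and being paired with a two-sided Fisher exact test
#' (summation of hypergeometric point probabilities at most that of the
#' observed table).  Reports the sample odds ratio (with the 0.5 continuity
#' substitute, flagged, when any cell is zero) and applies a Bonferroni
#' critical p of \code{alpha / number of variants tested}.
#'
#' @param cohort a \code{\linkS4class{Cohort}} whose males have known
#'   pairing status.
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with one row per variant: the 2x2 counts
#'   (carrier/non-carrier x paired/unpaired), \code{p}, \code{oddsRatio},
#'   \code{continuity} flag, \code{criticalP} and \code{significant}.
#' @export
allelePairStatusTests <- function(cohort, alpha = 0.05) {
  ind <- cohortIndividuals(cohort)
  males <- ind$sex == "M" & ind$hasMHC
  if (!any(males)) stop("no MHC-typed males")
  paired <- ind$paired[males]
  if (any(is.na(paired))) stop("pairing status missing for some males")
  m <- mhcMatrix(cohort)[males, , drop = FALSE]
  present <- colSums(m) > 0L
  if (any(!present))
    warning(sprintf("variants absent from all males, skipped: %s",
                    paste(colnames(m)[!present], collapse = ", ")))
  vars <- colnames(m)[present]
  crit <- alpha / length(vars)
  rows <- lapply(vars, function(v) {
    carrier <- m[, v]
    a <- sum(carrier & paired);  b <- sum(carrier & !paired)
    cc <- sum(!carrier & paired); dd <- sum(!carrier & !paired)
    p <- stats::fisher.test(matrix(c(a, cc, b, dd), 2L))$p.value
    cont <- any(c(a, b, cc, dd) == 0L)
    if (cont) { a2 <- a + 0.5; b2 <- b + 0.5; c2 <- cc + 0.5; d2 <- dd + 0.5 }
    else { a2 <- a; b2 <- b; c2 <- cc; d2 <- dd }
    or <- (a2 * d2) / (b2 * c2)
    data.frame(variant = v, pairedCarrier = a, unpairedCarrier = b,
               pairedNonCarrier = cc, unpairedNonCarrier = dd,
               p = p, oddsRatio = or, continuity = cont,
               criticalP = crit, significant = p < crit)
  })
  do.call(rbind, rows)
}

#' Welch t and rank-sum two-sample tests
#'
#' \code{welch_t}: unequal-variance t with Welch-Satterthwaite degrees of
#' freedom.  \code{rank_sum}: Wilcoxon-Mann-Whitney rank-sum with midranks
#' for ties and the continuity- and tie-corrected normal approximation.
#' When both samples are constant and equal, p is 1 by convention and the
#' result is flagged degenerate.
#'
#' @param a,b numeric samples.
#' @param kind "welch_t" or "rank_sum".
#' @return list with \code{statistic}, \code{df} (Welch only), \code{p},
#'   \code{kind}, \code{degenerate}.
#' @export
twoSampleTests <- function(a, b, kind = c("welch_t", "rank_sum")) {
  kind <- match.arg(kind)
  if (kind == "welch_t") {
    if (length(a) < 2L || length(b) < 2L)
      stop("welch_t needs >= 2 values per sample")
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b))
        return(list(statistic = 0, df = NA_real_, p = 1, kind = kind,
                    degenerate = TRUE))
      return(list(statistic = Inf * sign(mean(a) - mean(b)), df = NA_real_,
                  p = 0, kind = kind, degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, kind = kind, degenerate = FALSE)
  } else {
    if (length(a) < 1L || length(b) < 1L)
      stop("rank_sum needs >= 1 value per sample")
    if (length(unique(c(a, b))) == 1L)
      return(list(statistic = length(a) * length(b) / 2, df = NA_real_,
                  p = 1, kind = kind, degenerate = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    list(statistic = unname(wt$statistic), df = NA_real_, p = wt$p.value,
         kind = kind, degenerate = FALSE)
  }
}

#' Divorce analyses
#'
#' Compares pairs that divorced with pairs that remained stable (censored
#' pairings -- one member unresighted -- are excluded): (i) randomization
#' tests (shared engine, ANOVA-F statistic, label shuffling) of male and of
#' female MHC diversity between divorced and stable individuals; (ii)
#' rank-sum tests of pair Sxy, PBR p-distance and PSS p-distance between
#' divorced and stable pairs.
#'
#' @param cohort a \code{\linkS4class{Cohort}} whose pairings carry
#'   outcomes.
#' @param nPerm resamples for the diversity randomizations.
#' @param seed RNG seed.
#' @return list: \code{maleDiversity} and \code{femaleDiversity}
#'   (\code{\linkS4class{RandTestResult}}), \code{similarity} (data.frame of
#'   rank-sum results per metric), \code{nDivorced}, \code{nStable}.
#' @export
divorceAnalysis <- function(cohort, nPerm = 10000L, seed = 1L) {
  pr <- pairings(cohort)
  pr <- pr[pr$observed & !is.na(pr$outcome) & pr$outcome != "censored", ,
           drop = FALSE]
  div <- pr$outcome == "divorced"
  if (sum(div) < 2L || sum(!div) < 2L)
    stop(sprintf("need >= 2 pairs per outcome group (divorced = %d, stable = %d)",
                 sum(div), sum(!div)))
  maleDiv <- as.numeric(mhcDiversity(cohort, pr$maleId))
  femDiv <- as.numeric(mhcDiversity(cohort, pr$femaleId))
  maleTest <- groupRandomizationTest(maleDiv, div, "anova_f", nPerm,
                                     deriveSeed(seed, "divorce:male"))
  femTest <- groupRandomizationTest(femDiv, div, "anova_f", nPerm,
                                    deriveSeed(seed, "divorce:female"))
  panel <- cohortPanel(cohort)
  metrics <- list(
    sxy = vapply(seq_len(nrow(pr)), function(i)
      alleleSharing(cohort, pr$femaleId[i], pr$maleId[i]), numeric(1)))
  if (!is.null(panel)) {
    for (mk in c("pbr", "pss")) {
      D <- panelPDistMatrix(panel, mk)
      metrics[[paste0("pdist_", mk)]] <- vapply(seq_len(nrow(pr)), function(i)
        dyadMeanPDistance(cohort, pr$femaleId[i], pr$maleId[i],
                          pdistMatrix = D), numeric(1))
    }
  }
  sim <- do.call(rbind, lapply(names(metrics), function(mn) {
    v <- metrics[[mn]]
    res <- twoSampleTests(v[div], v[!div], "rank_sum")
    data.frame(metric = mn, meanDivorced = mean(v[div]),
               meanStable = mean(v[!div]), W = res$statistic, p = res$p)
  }))
  list(maleDiversity = maleTest, femaleDiversity = femTest, similarity = sim,
       nDivorced = sum(div), nStable = sum(!div))
}
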