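#' Assemble an analysis configuration
#'
#' One object drives \code{\link{runPipeline}}: either a simulator
#' configuration (one \code{\linkS4class{CohortConfig}} per island to
#' simulate) or paths to on-disk tables, plus the test settings.
#'
#' @param outDir output directory.
#' @param seed master seed (mandatory; every random draw derives from it).
#' @param simConfigs named list of \code{\linkS4class{CohortConfig}}s, one
#'   per simulated island; NULL to load data from disk instead.
#' @param indPath,genotypePath,mhcPath,fastaPath,maskPaths input files
#'   (used when \code{simConfigs} is NULL).
#' @param metrics dyad metrics to test.
#' @param nPerm resamples per randomization test (default 1e5).
#' @param mode permutation universe, "label_shuffle" or
#'   "matching_constrained".
#' @param alpha significance level.
#' @param stages analysis stages to run, a subset of
#'   \code{c("randomization", "glm", "allele_tests", "divorce")}.
#' @return a validated config list of class \code{"pairmhc_analysis_config"}.
#' @export
analysisConfig <- function(outDir, seed, simConfigs = NULL,
                           indPath = NULL, genotypePath = NULL,
                           mhcPath = NULL, fastaPath = NULL,
                           maskPaths = NULL,
                           metrics = c("relatedness_qg", "sxy", "pdist_pbr",
                                       "pdist_pss"),
                           nPerm = 100000L,
                           mode = c("label_shuffle", "matching_constrained"),
                           alpha = 0.05,
                           stages = c("randomization", "glm", "allele_tests",
                                      "divorce")) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (nPerm < 1L) stop("nPerm must be >= 1")
  stages <- match.arg(stages, several.ok = TRUE)
  if (length(stages) == 0L) stop("at least one analysis stage must be enabled")
  if (is.null(simConfigs)) {
    for (p in c(indPath, genotypePath, mhcPath))
      if (is.null(p) || !file.exists(p))
        stop(sprintf("input file missing: %s",
                     if (is.null(p)) "(not given)" else p))
  }
  structure(list(outDir = outDir, seed = as.integer(seed),
                 simConfigs = simConfigs, indPath = indPath,
                 genotypePath = genotypePath, mhcPath = mhcPath,
                 fastaPath = fastaPath, maskPaths = maskPaths,
                 metrics = metrics, nPerm = as.integer(nPerm),
                 mode = match.arg(mode), alpha = alpha, stages = stages),
            class = "pairmhc_analysis_config")
}

.loadOrSimulate <- function(config) {
  if (!is.null(config$simConfigs)) {
    cohorts <- lapply(names(config$simConfigs), function(isl) {
      cc <- config$simConfigs[[isl]]
      simulatePairing(genCohort(cc, island = isl), cc)
    })
    names(cohorts) <- names(config$simConfigs)
    return(cohorts)
  }
  panel <- if (!is.null(config$fastaPath))
    readAllelePanel(config$fastaPath, config$maskPaths) else NULL
  cohort <- readIndividuals(config$indPath, config$genotypePath,
                            config$mhcPath, panel = panel)
  ind <- cohortIndividuals(cohort)
  # rebuild pairing records from the reciprocal mate links
  fem <- ind[ind$sex == "F" & !is.na(ind$mateId), , drop = FALSE]
  tab <- data.frame(femaleId = fem$id, maleId = fem$mateId,
                    observed = TRUE, outcome = fem$divorceStatus,
                    stringsAsFactors = FALSE)
  cohort <- setPairings(cohort, tab)
  split <- lapply(unique(ind$island), function(isl) subsetIsland(cohort, isl))
  names(split) <- unique(ind$island)
  split
}

#' Run the full analysis pipeline
#'
#' Simulates or loads the cohorts, excludes MHC-untyped birds (with their
#' mates), then runs per island the pair-versus-dyad randomization battery
#' (mean via ANOVA F for each metric; variance for the similarity metrics),
#' and on the pooled cohort the binomial GLM of male pairing status, the
#' per-allele Fisher tests and the divorce analyses.  Every result is
#' written as delimited text together with a combined summary, a markdown
#' report and a reproducibility manifest.  A stage failure aborts with the
#' stage name; results of completed stages are retained on disk.
#'
#' @param config an \code{\link{analysisConfig}}.
#' @return the result bundle (named list), invisibly.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  cohorts <- stage("load", .loadOrSimulate(config))
  cohorts <- stage("exclusions", lapply(cohorts, function(co)
    excludeMissingMHC(co)$cohort))
  bundle$cohorts <- cohorts
  results <- list()
  summary <- list()
  if ("randomization" %in% config$stages) {
    for (isl in names(cohorts)) {
      co <- cohorts[[isl]]
      if (sum(pairings(co)$observed) < 2L) next
      for (met in config$metrics) {
        d <- stage(sprintf("dyads:%s:%s", isl, met),
                   buildDyadStatistic(co, met))
        r <- stage(sprintf("randtest:%s:%s", isl, met),
                   randomizationTest(d, "anova_f", config$nPerm, config$mode,
                                     deriveSeed(config$seed,
                                                paste("rt", isl, met))))
        key <- sprintf("randtest_mean_%s_%s", isl, met)
        results[[key]] <- r
        summary[[key]] <- data.frame(
          island = isl, metric = met, test = "mean_anova_f",
          n_pairs = nPairs(d), n_dyads = nDyads(d),
          pair_mean = mean(pairValues(d)), pair_sd = stats::sd(pairValues(d)),
          dyad_mean = mean(dyadValues(d)), dyad_sd = stats::sd(dyadValues(d)),
          observed_stat = observedStat(r), p = pValue(r))
        if (met != "relatedness_qg") {
          rv <- stage(sprintf("vartest:%s:%s", isl, met),
                      varianceRandomizationTest(d, config$nPerm, config$mode,
                                                deriveSeed(config$seed,
                                                           paste("vt", isl, met))))
          key <- sprintf("randtest_var_%s_%s", isl, met)
          results[[key]] <- rv
          summary[[key]] <- data.frame(
            island = isl, metric = met, test = "variance_diff",
            n_pairs = nPairs(d), n_dyads = nDyads(d),
            pair_mean = stats::var(pairValues(d)), pair_sd = NA,
            dyad_mean = stats::var(dyadValues(d)), dyad_sd = NA,
            observed_stat = observedStat(rv), p = pValue(rv))
        }
      }
    }
  }
  pooled <- stage("pool", .poolCohorts(cohorts))
  if ("glm" %in% config$stages)
    results$pairing_glm <- stage("glm", fitPairingGLM(pooled))
  if ("allele_tests" %in% config$stages)
    results$allele_tests <- stage("allele_tests",
                                  allelePairStatusTests(pooled, config$alpha))
  if ("divorce" %in% config$stages) {
    dv <- stage("divorce",
                tryCatch(divorceAnalysis(pooled, config$nPerm,
                                         deriveSeed(config$seed, "divorce")),
                         error = function(e) e))
    if (inherits(dv, "error")) {
      bundle$divorceSkipped <- conditionMessage(dv)
    } else {
      results$divorce_male_diversity <- dv$maleDiversity
      results$divorce_female_diversity <- dv$femaleDiversity
      results$divorce_similarity <- dv$similarity
      bundle$divorce <- dv
    }
  }
  bundle$results <- results
  bundle$summary <- if (length(summary)) do.call(rbind, c(summary, list(make.row.names = FALSE))) else NULL
  if (!is.null(bundle$summary))
    results$summary <- bundle$summary
  writeResults(results, config$outDir, seed = config$seed,
               nPerm = config$nPerm)
  writeLines(.manifest(config), file.path(config$outDir, "manifest.txt"))
  writeLines(makeReport(bundle), file.path(config$outDir, "report.md"))
  invisible(bundle)
}

.poolCohorts <- function(cohorts) {
  if (length(cohorts) == 1L) return(cohorts[[1L]])
  ind <- do.call(rbind, lapply(cohorts, cohortIndividuals))
  rownames(ind) <- NULL
  if (anyDuplicated(ind$id)) {
    # prefix island to keep ids unique across simulated islands
    for (i in seq_along(cohorts)) {
      co <- cohorts[[i]]
      pre <- paste0(names(cohorts)[i], ".")
      idmap <- function(x) ifelse(is.na(x), x, paste0(pre, x))
      ci <- cohortIndividuals(co)
      ci$id <- idmap(ci$id); ci$mateId <- idmap(ci$mateId)
      g <- genotypeMatrix(co); rownames(g) <- ci$id
      m <- mhcMatrix(co); rownames(m) <- ci$id
      pr <- pairings(co)
      pr$femaleId <- idmap(pr$femaleId); pr$maleId <- idmap(pr$maleId)
      cohorts[[i]] <- new("Cohort", individuals = ci, genotypes = g, mhc = m,
                          panel = cohortPanel(co), pairings = pr)
    }
    ind <- do.call(rbind, lapply(cohorts, cohortIndividuals))
    rownames(ind) <- NULL
  }
  g <- do.call(rbind, lapply(cohorts, genotypeMatrix))
  m <- do.call(rbind, lapply(cohorts, mhcMatrix))
  pr <- do.call(rbind, c(lapply(cohorts, pairings), list(make.row.names = FALSE)))
  new("Cohort", individuals = ind, genotypes = g, mhc = m,
      panel = cohortPanel(cohorts[[1L]]), pairings = pr)
}

.manifest <- function(config) {
  lines <- c("pairMHC run manifest",
             sprintf("package version: %s",
                     as.character(utils::packageVersion("pairMHC"))),
             sprintf("seed: %d", config$seed),
             sprintf("n_perm: %d", config$nPerm),
             sprintf("mode: %s", config$mode),
             sprintf("alpha: %g", config$alpha),
             sprintf("stages: %s", paste(config$stages, collapse = ", ")))
  if (!is.null(config$simConfigs)) {
    lines <- c(lines, "inputs: simulated")
    for (isl in names(config$simConfigs)) {
      cc <- config$simConfigs[[isl]]
      lines <- c(lines, sprintf("  island %s: %dM/%dF seed %d", isl,
                                cc@nMales, cc@nFemales, cc@seed))
    }
  } else {
    paths <- c(config$indPath, config$genotypePath, config$mhcPath,
               config$fastaPath, unlist(config$maskPaths))
    sums <- tools::md5sum(paths)
    lines <- c(lines, "inputs:",
               sprintf("  %s  %s", sums, names(sums)))
  }
  lines
}

#' Render a result bundle as a markdown report
#'
#' Produces pairs-versus-dyads summary tables (mean, spread, randomization
#' p per island and metric), the GLM coefficient table, the per-allele
#' Fisher table and the divorce comparisons.
#'
#' @param bundle the list returned by \code{\link{runPipeline}}.
#' @return character vector of markdown lines.
#' @export
makeReport <- function(bundle) {
  out <- c("# Social mate choice analysis report", "")
  fmtRow <- function(...) paste(..., sep = " | ")
  if (!is.null(bundle$summary)) {
    s <- bundle$summary
    out <- c(out, "## Pair-versus-dyad randomization tests", "",
             fmtRow("island", "metric", "test", "pairs", "dyads",
                    "pair mean", "dyad mean", "p"),
             fmtRow("---", "---", "---", "---", "---", "---", "---", "---"))
    for (i in seq_len(nrow(s)))
      out <- c(out, fmtRow(s$island[i], s$metric[i], s$test[i],
                           s$n_pairs[i], s$n_dyads[i],
                           sprintf("%.3f", s$pair_mean[i]),
                           sprintf("%.3f", s$dyad_mean[i]),
                           sprintf("%.4f", s$p[i])))
    out <- c(out, "")
  }
  glm <- bundle$results$pairing_glm
  if (!is.null(glm)) {
    tab <- glmTable(glm)
    out <- c(out, "## Male pairing status (binomial GLM)", "",
             fmtRow("term", "B (SE)", "z", "odds ratio", "95% CI", "p"),
             fmtRow("---", "---", "---", "---", "---", "---"))
    for (i in seq_len(nrow(tab)))
      out <- c(out, fmtRow(tab$term[i],
                           sprintf("%.2f (%.2f)", tab$B[i], tab$SE[i]),
                           sprintf("%.2f", tab$z[i]),
                           sprintf("%.2f", tab$oddsRatio[i]),
                           sprintf("%.2f-%.2f", tab$orLower[i], tab$orUpper[i]),
                           sprintf("%.3f", tab$p[i])))
    out <- c(out, "",
             sprintf("Model chi2 = %.2f, df = %d, P = %.3g, R2 = %.2f (Nagelkerke), n = %d",
                     glm@lrChisq, glm@lrDf, glm@lrP, glm@nagelkerkeR2, glm@n), "")
  }
  at <- bundle$results$allele_tests
  if (!is.null(at)) {
    out <- c(out, "## Per-allele Fisher exact tests", "",
             fmtRow("variant", "paired carriers", "unpaired carriers", "p",
                    "odds ratio", "significant"),
             fmtRow("---", "---", "---", "---", "---", "---"))
    for (i in seq_len(nrow(at)))
      out <- c(out, fmtRow(at$variant[i], at$pairedCarrier[i],
                           at$unpairedCarrier[i], sprintf("%.4f", at$p[i]),
                           sprintf("%.2f", at$oddsRatio[i]),
                           at$significant[i]))
    out <- c(out, "",
             sprintf("Bonferroni critical p = %.4g", at$criticalP[1L]), "")
  }
  dv <- bundle$divorce
  if (!is.null(dv)) {
    out <- c(out, "## Divorce analyses", "",
             sprintf("Divorced pairs: %d, stable pairs: %d", dv$nDivorced,
                     dv$nStable),
             sprintf("Male MHC diversity randomization: p = %.4f",
                     pValue(dv$maleDiversity)),
             sprintf("Female MHC diversity randomization: p = %.4f",
                     pValue(dv$femaleDiversity)), "",
             fmtRow("metric", "mean divorced", "mean stable", "W", "p"),
             fmtRow("---", "---", "---", "---", "---"))
    for (i in seq_len(nrow(dv$similarity)))
      out <- c(out, fmtRow(dv$similarity$metric[i],
                           sprintf("%.3f", dv$similarity$meanDivorced[i]),
                           sprintf("%.3f", dv$similarity$meanStable[i]),
                           sprintf("%.1f", dv$similarity$W[i]),
                           sprintf("%.4f", dv$similarity$p[i])))
    out <- c(out, "")
  }
  if (!is.null(bundle$divorceSkipped))
    out <- c(out, sprintf("Divorce analyses skipped: %s",
                          bundle$divorceSkipped), "")
  out
}
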