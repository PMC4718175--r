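#' @keywords internal
#' @noRd
.readDelim <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
}

.requireCols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
}

#' Read individuals, genotypes and MHC tables into a Cohort
#'
#' Merges three delimited tables (comma default, tab accepted) keyed by
#' individual id:
#' \describe{
#'   \item{individual table}{columns \code{id,sex,island,age_class} and
#'     optionally \code{paired,mate_id,divorce_status}.}
#'   \item{genotype table}{\code{id} plus two columns per locus named
#'     \code{<locus>.1}/\code{<locus>.2}; missing alleles coded \code{NA}.}
#'   \item{MHC table}{\code{id} plus one 0/1 column per variant.}
#' }
#' Birds absent from the MHC table are retained and flagged
#' \code{hasMHC = FALSE}; the analysis convention is to exclude them (with
#' their social mates) via \code{\link{excludeMissingMHC}}.  Birds typed at
#' fewer than \code{minTypedFrac} of loci are flagged with a warning.
#'
#' @param indPath,genotypePath,mhcPath file paths.
#' @param panel optional \code{\linkS4class{AllelePanel}}; when given,
#'   variant columns in the MHC table must all exist in the panel.
#' @param minTypedFrac completeness threshold for the warning flag
#'   (default 0.5).
#' @return a \code{\linkS4class{Cohort}}.
#' @export
readIndividuals <- function(indPath, genotypePath, mhcPath, panel = NULL,
                            minTypedFrac = 0.5) {
  ind <- .readDelim(indPath)
  .requireCols(ind, c("id", "sex", "island", "age_class"), indPath)
  if (anyDuplicated(ind$id)) {
    dups <- ind$id[duplicated(ind$id)]
    stop(sprintf("%s: duplicate id '%s' (line %d)", indPath, dups[1L],
                 which(ind$id == dups[1L])[2L] + 1L))
  }
  bad <- which(!ind$sex %in% c("F", "M"))
  if (length(bad))
    stop(sprintf("%s: line %d: field 'sex' must be F or M, got '%s'",
                 indPath, bad[1L] + 1L, ind$sex[bad[1L]]))
  bad <- which(!is.na(ind$age_class) & !ind$age_class %in% c("young", "old"))
  if (length(bad))
    stop(sprintf("%s: line %d: field 'age_class' must be young/old, got '%s'",
                 indPath, bad[1L] + 1L, ind$age_class[bad[1L]]))

  gt <- .readDelim(genotypePath)
  .requireCols(gt, "id", genotypePath)
  if (anyDuplicated(gt$id))
    stop(sprintf("%s: duplicate id '%s'", genotypePath,
                 gt$id[duplicated(gt$id)][1L]))
  gcols <- setdiff(names(gt), "id")
  if (length(gcols) %% 2L != 0L ||
      !all(grepl("\\.[12]$", gcols)))
    stop(sprintf("%s: genotype columns must come in <locus>.1/<locus>.2 pairs",
                 genotypePath))
  unknown <- setdiff(ind$id, gt$id)
  if (length(unknown))
    stop(sprintf("%s: no genotype row for id(s): %s", genotypePath,
                 paste(unknown, collapse = ", ")))
  g <- as.matrix(gt[match(ind$id, gt$id), gcols, drop = FALSE])
  suppressWarnings(storage.mode(g) <- "double")
  rownames(g) <- ind$id

  mh <- .readDelim(mhcPath)
  .requireCols(mh, "id", mhcPath)
  if (anyDuplicated(mh$id))
    stop(sprintf("%s: duplicate id '%s'", mhcPath, mh$id[duplicated(mh$id)][1L]))
  vcols <- setdiff(names(mh), "id")
  if (!is.null(panel)) {
    unknownV <- setdiff(vcols, variantNames(panel))
    if (length(unknownV))
      stop(sprintf("%s: variant(s) not in panel: %s", mhcPath,
                   paste(unknownV, collapse = ", ")))
  }
  mhm <- matrix(FALSE, nrow(ind), length(vcols),
                dimnames = list(ind$id, vcols))
  hit <- match(ind$id, mh$id)
  hasMHC <- !is.na(hit)
  if (any(hasMHC))
    mhm[hasMHC, ] <- as.matrix(mh[hit[hasMHC], vcols, drop = FALSE]) != 0
  emptyTyped <- hasMHC & rowSums(mhm) == 0L
  if (any(emptyTyped))
    stop(sprintf("%s: empty MHC repertoire for typed bird(s): %s", mhcPath,
                 paste(ind$id[emptyTyped], collapse = ", ")))

  typedFrac <- rowMeans(!is.na(g[, seq(1, ncol(g), by = 2), drop = FALSE]) &
                        !is.na(g[, seq(2, ncol(g), by = 2), drop = FALSE]))
  low <- typedFrac < minTypedFrac
  if (any(low))
    warning(sprintf("individual(s) typed at < %d%% of loci: %s",
                    round(100 * minTypedFrac),
                    paste(ind$id[low], collapse = ", ")))

  indDf <- data.frame(
    id = as.character(ind$id), sex = ind$sex, island = as.character(ind$island),
    ageClass = ind$age_class,
    paired = if ("paired" %in% names(ind)) as.logical(ind$paired) else NA,
    mateId = if ("mate_id" %in% names(ind)) as.character(ind$mate_id)
             else NA_character_,
    divorceStatus = if ("divorce_status" %in% names(ind))
      as.character(ind$divorce_status) else NA_character_,
    hasMHC = hasMHC, stringsAsFactors = FALSE)
  Cohort(indDf, g, mhm, panel = panel)
}

#' Read an allele panel from FASTA plus codon-mask files
#'
#' The FASTA holds the amino-acid sequence of each variant (unique headers,
#' equal lengths).  Each mask file lists 1-based codon indices separated by
#' whitespace and/or commas; lines beginning with \code{#} are ignored.
#'
#' @param fastaPath amino-acid FASTA.
#' @param maskPaths named character vector of mask files, e.g.
#'   \code{c(pbr = "pbr.txt", pss = "pss.txt")}.
#' @return an \code{\linkS4class{AllelePanel}}.
#' @export
readAllelePanel <- function(fastaPath, maskPaths = character()) {
  seqs <- Biostrings::readAAStringSet(fastaPath)
  if (length(seqs) == 0L) stop(sprintf("%s: no sequences", fastaPath))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop(sprintf("%s: duplicate FASTA header '%s'", fastaPath,
                 names(seqs)[duplicated(names(seqs))][1L]))
  w <- Biostrings::width(seqs)
  if (length(unique(w)) > 1L)
    stop(sprintf("%s: unequal sequence lengths (%s)", fastaPath,
                 paste(unique(w), collapse = ", ")))
  masks <- lapply(maskPaths, readCodonMask)
  names(masks) <- names(maskPaths)
  for (mn in names(masks))
    if (any(masks[[mn]] > w[1L]))
      stop(sprintf("mask '%s': codon index %d exceeds sequence length %d",
                   mn, max(masks[[mn]]), w[1L]))
  AllelePanel(seqs, masks)
}

#' @rdname readAllelePanel
#' @param path a single mask file.
#' @return \code{readCodonMask}: sorted integer vector of codon indices.
#' @export
readCodonMask <- function(path) {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tokens <- unlist(strsplit(paste(lines, collapse = " "), "[,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L)
    stop(sprintf("%s: mask file contains no codon indices", path))
  idx <- suppressWarnings(as.integer(tokens))
  if (anyNA(idx) || any(idx < 1L))
    stop(sprintf("%s: mask entries must be positive integers", path))
  if (anyDuplicated(idx))
    stop(sprintf("%s: duplicated codon index %d", path, idx[duplicated(idx)][1L]))
  sort(idx)
}

#' Write a cohort to delimited text (plus FASTA panel and mask files)
#'
#' Produces \code{individuals.csv}, \code{genotypes.csv} (alleles in sorted
#' canonical order per locus), \code{mhc.csv}, \code{pairings.csv} and --
#' when a panel is attached -- \code{panel.fasta} with one
#' \code{mask_<name>.txt} per mask.  Files round-trip through
#' \code{\link{readIndividuals}} / \code{\link{readAllelePanel}}.
#'
#' @param cohort a \code{\linkS4class{Cohort}}.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ind <- cohortIndividuals(cohort)
  out <- c()
  f <- file.path(dir, "individuals.csv")
  utils::write.csv(data.frame(
    id = ind$id, sex = ind$sex, island = ind$island, age_class = ind$ageClass,
    paired = ind$paired, mate_id = ind$mateId,
    divorce_status = ind$divorceStatus), f, row.names = FALSE, quote = FALSE)
  out["individuals"] <- f
  g <- genotypeMatrix(cohort)
  L <- ncol(g) / 2L
  for (k in seq_len(L)) {                       # canonical sorted allele order
    pair <- g[, c(2L * k - 1L, 2L * k), drop = FALSE]
    swap <- !is.na(pair[, 1L]) & !is.na(pair[, 2L]) & pair[, 1L] > pair[, 2L]
    g[swap, c(2L * k - 1L, 2L * k)] <- pair[swap, 2L:1L]
  }
  f <- file.path(dir, "genotypes.csv")
  utils::write.csv(data.frame(id = ind$id, g, check.names = FALSE),
                   f, row.names = FALSE, quote = FALSE)
  out["genotypes"] <- f
  m <- mhcMatrix(cohort)
  typed <- ind$hasMHC
  f <- file.path(dir, "mhc.csv")
  utils::write.csv(data.frame(id = ind$id[typed],
                              m[typed, , drop = FALSE] * 1L,
                              check.names = FALSE),
                   f, row.names = FALSE, quote = FALSE)
  out["mhc"] <- f
  pr <- pairings(cohort)
  f <- file.path(dir, "pairings.csv")
  utils::write.csv(data.frame(female_id = pr$femaleId, male_id = pr$maleId,
                              observed = pr$observed, outcome = pr$outcome),
                   f, row.names = FALSE, quote = FALSE)
  out["pairings"] <- f
  panel <- cohortPanel(cohort)
  if (!is.null(panel)) {
    f <- file.path(dir, "panel.fasta")
    Biostrings::writeXStringSet(panelSequences(panel), f)
    out["panel"] <- f
    for (mn in names(panelMasks(panel))) {
      f <- file.path(dir, sprintf("mask_%s.txt", mn))
      writeLines(c(sprintf("# 1-based codon indices of mask '%s'", mn),
                   paste(maskCodons(panel, mn), collapse = " ")), f)
      out[paste0("mask_", mn)] <- f
    }
  }
  invisible(out)
}

#' Serialize analysis results to delimited tables plus a run log
#'
#' Writes one CSV per result object and a plain-text run log recording the
#' seed, permutation settings and package version.  Accepted result types:
#' \code{\linkS4class{RandTestResult}} (one row: observed statistic,
#' permutations, p, seed), \code{\linkS4class{GlmResult}} (per-term table
#' plus a model-summary footer row set), plain data.frames (written as-is),
#' and lists of these.
#'
#' @param results named list of result objects.
#' @param outDir output directory.
#' @param seed,nPerm run metadata for the log.
#' @return character vector of files written, invisibly.
#' @export
writeResults <- function(results, outDir, seed = NA_integer_,
                         nPerm = NA_integer_) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(results)) {
    obj <- results[[nm]]
    f <- file.path(outDir, paste0(nm, ".csv"))
    utils::write.csv(resultAsTable(obj), f, row.names = FALSE)
    files <- c(files, f)
  }
  log <- file.path(outDir, "run_log.txt")
  writeLines(c(
    sprintf("pairMHC version: %s", as.character(utils::packageVersion("pairMHC"))),
    sprintf("R version: %s", R.version.string),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %s", seed),
    sprintf("n_perm: %s", nPerm),
    sprintf("results: %s", paste(names(results), collapse = ", "))), log)
  invisible(c(files, log))
}

#' Flatten a result object to a writable data.frame
#'
#' @param obj a result object (see \code{\link{writeResults}}).
#' @return a data.frame.
#' @export
resultAsTable <- function(obj) {
  if (is(obj, "RandTestResult"))
    return(data.frame(observed_stat = obj@observedStat, n_perm = obj@nPerm,
                      n_extreme = obj@nExtreme, p_value = obj@pValue,
                      mode = obj@mode, statistic = obj@statistic,
                      seed = obj@seed))
  if (is(obj, "GlmResult")) {
    tab <- obj@table
    names(tab) <- c("term", "B", "SE", "z", "p", "odds_ratio",
                    "or_ci_lower", "or_ci_upper")
    tab$model_chisq <- obj@lrChisq
    tab$model_df <- obj@lrDf
    tab$model_p <- obj@lrP
    tab$nagelkerke_r2 <- obj@nagelkerkeR2
    tab$n <- obj@n
    return(tab)
  }
  if (is.data.frame(obj)) return(obj)
  stop(sprintf("cannot serialize object of class '%s'", class(obj)[1L]))
}
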