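#' CohortConfig: parameters of the synthetic translocated-cohort generator
#'
#' Describes one simulated translocation: cohort composition, marker
#' architecture, MHC pool, and the log-odds effect sizes that drive the
#' pairing and divorce processes.  Defaults mirror a male-biased island
#' release cohort (34 males, 24 females) carrying 2-8 MHC variants from a
#' 10-variant pool typed at 30 microsatellite loci.
#'
#' @slot nMales,nFemales cohort composition (counts > 0).
#' @slot propOld probability an individual is in the "old" age class.
#' @slot nMsatLoci,msatAllelesPerLocus microsatellite architecture; allele
#'   frequencies per locus are drawn from a symmetric Dirichlet(1).
#' @slot mhcPoolSize number of named MHC variants in the pool.
#' @slot mhcMin,mhcMax per-individual repertoire-size bounds (uniform draw).
#' @slot nCodons amino-acid length of each variant sequence (85 = 255 bp).
#' @slot maskSizes named integer vector \code{c(pbr=, pss=)}: codon counts of
#'   the two masks.
#' @slot maskOverlap number of PSS codons falling inside the PBR.
#' @slot effectAge,effectHs,effectMhcDiv,effectCompat log-scale weights in a
#'   female's male-choice kernel (see \code{\link{simulatePairing}}).
#' @slot effectDivorceMhcDiv decrease in divorce log-odds per unit of male
#'   MHC diversity above the pool expectation.
#' @slot divorceBaseRate divorce probability at average male MHC diversity.
#' @slot propFemalePaired probability a female pairs at all.
#' @slot poolDirichletAlpha 0 = uniform MHC variant frequencies; > 0 draws
#'   pool frequencies from a symmetric Dirichlet with this concentration.
#' @slot seed master RNG seed; all sub-streams derive from it.
#' @seealso \code{\link{cohortConfig}}, \code{\link{genCohort}}
#' @export
setClass("CohortConfig",
  representation(nMales = "integer", nFemales = "integer", propOld = "numeric",
                 nMsatLoci = "integer", msatAllelesPerLocus = "integer",
                 mhcPoolSize = "integer", mhcMin = "integer", mhcMax = "integer",
                 nCodons = "integer", maskSizes = "integer",
                 maskOverlap = "integer",
                 effectAge = "numeric", effectHs = "numeric",
                 effectMhcDiv = "numeric", effectCompat = "numeric",
                 effectDivorceMhcDiv = "numeric", divorceBaseRate = "numeric",
                 propFemalePaired = "numeric", poolDirichletAlpha = "numeric",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  cnt <- c(nMales = object@nMales, nFemales = object@nFemales,
           nMsatLoci = object@nMsatLoci, mhcPoolSize = object@mhcPoolSize,
           nCodons = object@nCodons)
  if (any(cnt < 1L))
    msg <- c(msg, sprintf("counts must be positive (%s)",
                          paste(names(cnt)[cnt < 1L], collapse = ", ")))
  if (object@msatAllelesPerLocus < 2L)
    msg <- c(msg, "msatAllelesPerLocus must be >= 2")
  if (!(2L <= object@mhcMin && object@mhcMin <= object@mhcMax &&
        object@mhcMax <= object@mhcPoolSize))
    msg <- c(msg, "need 2 <= mhcMin <= mhcMax <= mhcPoolSize")
  if (length(object@maskSizes) != 2L ||
      !identical(sort(names(object@maskSizes)), c("pbr", "pss")))
    msg <- c(msg, "maskSizes must be a named vector c(pbr=, pss=)")
  else {
    if (any(object@maskSizes < 1L) || any(object@maskSizes > object@nCodons))
      msg <- c(msg, "mask sizes must lie in [1, nCodons]")
    if (object@maskOverlap > min(object@maskSizes))
      msg <- c(msg, "maskOverlap cannot exceed either mask size")
  }
  for (p in c("propOld", "propFemalePaired", "divorceBaseRate")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0,1]", p))
  }
  if (length(msg)) msg else TRUE
})

#' Create a simulator configuration
#'
#' All arguments have defaults describing a male-biased translocated cohort;
#' see \code{\linkS4class{CohortConfig}} for their meaning.
#'
#' @param nMales,nFemales,propOld,nMsatLoci,msatAllelesPerLocus,mhcPoolSize
#'   cohort and marker architecture.
#' @param mhcMin,mhcMax,nCodons,maskSizes,maskOverlap MHC pool geometry.
#' @param effectAge,effectHs,effectMhcDiv,effectCompat,effectDivorceMhcDiv
#'   effect sizes (log scale), all 0 by default (null pairing process).
#' @param divorceBaseRate,propFemalePaired,poolDirichletAlpha,seed see class
#'   documentation.
#' @return a validated \code{\linkS4class{CohortConfig}}.
#' @examples
#' cfg <- cohortConfig(nMales = 6, nFemales = 3, seed = 42)
#' @export
cohortConfig <- function(nMales = 34L, nFemales = 24L, propOld = 0.5,
                         nMsatLoci = 30L, msatAllelesPerLocus = 6L,
                         mhcPoolSize = 10L, mhcMin = 2L, mhcMax = 8L,
                         nCodons = 85L, maskSizes = c(pbr = 16L, pss = 7L),
                         maskOverlap = 3L,
                         effectAge = 0, effectHs = 0, effectMhcDiv = 0,
                         effectCompat = 0, effectDivorceMhcDiv = 0,
                         divorceBaseRate = 8 / 37, propFemalePaired = 0.85,
                         poolDirichletAlpha = 0, seed = 1L) {
  maskSizes <- setNames(as.integer(maskSizes), names(maskSizes))
  new("CohortConfig",
      nMales = as.integer(nMales), nFemales = as.integer(nFemales),
      propOld = propOld, nMsatLoci = as.integer(nMsatLoci),
      msatAllelesPerLocus = as.integer(msatAllelesPerLocus),
      mhcPoolSize = as.integer(mhcPoolSize), mhcMin = as.integer(mhcMin),
      mhcMax = as.integer(mhcMax), nCodons = as.integer(nCodons),
      maskSizes = maskSizes, maskOverlap = as.integer(maskOverlap),
      effectAge = effectAge, effectHs = effectHs, effectMhcDiv = effectMhcDiv,
      effectCompat = effectCompat, effectDivorceMhcDiv = effectDivorceMhcDiv,
      divorceBaseRate = divorceBaseRate, propFemalePaired = propFemalePaired,
      poolDirichletAlpha = poolDirichletAlpha, seed = as.integer(seed))
}

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(paste0("CohortConfig: %dM/%dF, %d msat loci (<=%d alleles), ",
                     "MHC pool %d (repertoire %d-%d), seed %d\n"),
              object@nMales, object@nFemales, object@nMsatLoci,
              object@msatAllelesPerLocus, object@mhcPoolSize,
              object@mhcMin, object@mhcMax, object@seed))
  eff <- c(age = object@effectAge, hs = object@effectHs,
           mhcdiv = object@effectMhcDiv, compat = object@effectCompat,
           divorce_mhcdiv = object@effectDivorceMhcDiv)
  cat("  effects:", paste(sprintf("%s=%g", names(eff), eff), collapse = " "), "\n")
})

# key:value text representation (snake_case keys, one per line)
.configKeyMap <- c(
  n_males = "nMales", n_females = "nFemales", prop_old = "propOld",
  n_msat_loci = "nMsatLoci", msat_alleles_per_locus = "msatAllelesPerLocus",
  mhc_pool_size = "mhcPoolSize", mhc_min = "mhcMin", mhc_max = "mhcMax",
  n_codons = "nCodons", mask_size_pbr = "__pbr", mask_size_pss = "__pss",
  mask_overlap = "maskOverlap",
  effect_age = "effectAge", effect_hs = "effectHs",
  effect_mhcdiv = "effectMhcDiv", effect_compat = "effectCompat",
  effect_divorce_mhcdiv = "effectDivorceMhcDiv",
  divorce_base_rate = "divorceBaseRate",
  prop_female_paired = "propFemalePaired",
  pool_dirichlet_alpha = "poolDirichletAlpha", seed = "seed")

#' Read / write a CohortConfig as plain key:value text
#'
#' One \code{key: value} pair per line, snake_case keys (e.g.
#' \code{n_males: 34}); lines starting with \code{#} and blank lines are
#' ignored.  Keys not supplied keep their defaults.
#'
#' @param path file to read or write.
#' @param config a \code{\linkS4class{CohortConfig}} (write only).
#' @return \code{readCohortConfig}: a \code{CohortConfig};
#'   \code{writeCohortConfig}: \code{path}, invisibly.
#' @export
readCohortConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  masks <- c(pbr = 16L, pss = 7L)
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], ":", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop(sprintf("%s: line %d is not 'key: value'", path, i))
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    tgt <- unname(.configKeyMap[key])
    if (is.na(tgt))
      stop(sprintf("%s: line %d: unknown config key '%s'", path, i, key))
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num))
      stop(sprintf("%s: line %d: value of '%s' is not numeric", path, i, key))
    if (tgt == "__pbr") masks[["pbr"]] <- as.integer(num)
    else if (tgt == "__pss") masks[["pss"]] <- as.integer(num)
    else args[[tgt]] <- num
  }
  args$maskSizes <- masks
  do.call(cohortConfig, args)
}

#' @rdname readCohortConfig
#' @export
writeCohortConfig <- function(config, path) {
  out <- character()
  for (key in names(.configKeyMap)) {
    tgt <- .configKeyMap[[key]]
    val <- switch(tgt,
                  "__pbr" = config@maskSizes[["pbr"]],
                  "__pss" = config@maskSizes[["pss"]],
                  slot(config, tgt))
    out <- c(out, sprintf("%s: %s", key, format(val, digits = 15)))
  }
  writeLines(out, path)
  invisible(path)
}
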