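#' Cohort: individuals, genotypes, MHC repertoires and pairings
#'
#' The central data container.  A \code{Cohort} stores one row per bird
#' together with its microsatellite genotype, its MHC class I repertoire
#' (presence/absence over the variant pool), the variant panel, and the
#' social pairing records once pairing has been observed or simulated.
#'
#' @slot individuals \code{data.frame} with columns \code{id} (unique),
#'   \code{sex} ("F"/"M"), \code{island}, \code{ageClass} ("young"/"old" or
#'   NA), \code{paired} (logical, NA = unknown), \code{mateId} (NA when
#'   unpaired), \code{divorceStatus} ("stable"/"divorced"/"censored"/NA),
#'   \code{hasMHC} (logical: MHC typing available).
#' @slot genotypes numeric matrix, one row per individual (rownames = id),
#'   two columns per locus named \code{<locus>.1}/\code{<locus>.2}; alleles
#'   are integer size labels, \code{NA} = untyped.
#' @slot mhc logical matrix, one row per individual (rownames = id), one
#'   column per panel variant; all-\code{FALSE} rows only for birds with
#'   \code{hasMHC = FALSE}.
#' @slot panel an \code{\linkS4class{AllelePanel}} or \code{NULL}.
#' @slot pairings \code{data.frame} of pairing records: \code{femaleId},
#'   \code{maleId}, \code{observed} (logical), \code{outcome}
#'   ("stable"/"divorced"/"censored"/NA).  Zero rows until pairing is set.
#'
#' @seealso \code{\link{genCohort}}, \code{\link{readIndividuals}},
#'   \code{\link{simulatePairing}}
#' @export
setClass("Cohort",
  representation(individuals = "data.frame", genotypes = "matrix",
                 mhc = "matrix", panel = "ANY", pairings = "data.frame"))

.emptyPairings <- function() {
  data.frame(femaleId = character(), maleId = character(),
             observed = logical(), outcome = character(),
             stringsAsFactors = FALSE)
}

setValidity("Cohort", function(object) {
  msg <- character()
  ind <- object@individuals
  need <- c("id", "sex", "island", "ageClass", "paired", "mateId",
            "divorceStatus", "hasMHC")
  miss <- setdiff(need, names(ind))
  if (length(miss))
    return(sprintf("individuals lacks columns: %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(ind$id))
    msg <- c(msg, "duplicate individual ids")
  if (!all(ind$sex %in% c("F", "M")))
    msg <- c(msg, "sex must be 'F' or 'M'")
  if (!all(is.na(ind$ageClass) | ind$ageClass %in% c("young", "old")))
    msg <- c(msg, "ageClass must be 'young', 'old' or NA")
  if (!identical(rownames(object@genotypes), ind$id))
    msg <- c(msg, "genotype rownames must equal individuals$id, in order")
  if (ncol(object@genotypes) %% 2L != 0L)
    msg <- c(msg, "genotype matrix must have two columns per locus")
  if (!identical(rownames(object@mhc), ind$id))
    msg <- c(msg, "mhc rownames must equal individuals$id, in order")
  if (any(rowSums(object@mhc) == 0L & ind$hasMHC))
    msg <- c(msg, "individual flagged hasMHC but repertoire empty")
  if (!is.null(object@panel)) {
    if (!is(object@panel, "AllelePanel"))
      msg <- c(msg, "panel must be an AllelePanel or NULL")
    else if (!all(colnames(object@mhc) %in% variantNames(object@panel)))
      msg <- c(msg, "mhc matrix names variants absent from the panel")
  }
  # reciprocal mates
  m <- ind$mateId
  has <- !is.na(m)
  if (any(has)) {
    back <- ind$mateId[match(m[has], ind$id)]
    if (any(is.na(back)) || any(back != ind$id[has]))
      msg <- c(msg, "mateId links are not reciprocal")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Cohort
#'
#' @param individuals data.frame as described for
#'   \code{\linkS4class{Cohort}}; missing optional columns (\code{paired},
#'   \code{mateId}, \code{divorceStatus}, \code{hasMHC}) are filled in.
#' @param genotypes numeric matrix, 2 columns per locus, rownames = ids.
#' @param mhc logical matrix of variant presence, rownames = ids.
#' @param panel optional \code{\linkS4class{AllelePanel}}.
#' @param pairings optional pairing-record data.frame.
#' @return a \code{\linkS4class{Cohort}}.
#' @export
Cohort <- function(individuals, genotypes, mhc, panel = NULL,
                   pairings = .emptyPairings()) {
  individuals$id <- as.character(individuals$id)
  for (col in c("paired", "mateId", "divorceStatus"))
    if (is.null(individuals[[col]])) individuals[[col]] <- NA
  individuals$mateId <- as.character(individuals$mateId)
  individuals$divorceStatus <- as.character(individuals$divorceStatus)
  if (is.null(individuals$hasMHC))
    individuals$hasMHC <- rowSums(mhc) > 0L
  rownames(individuals) <- NULL
  new("Cohort", individuals = individuals, genotypes = genotypes,
      mhc = mhc, panel = panel, pairings = pairings)
}

#' Accessors for Cohort objects
#'
#' @param cohort a \code{\linkS4class{Cohort}}.
#' @param id individual id (single string) for \code{mhcRepertoire}.
#' @return \code{cohortIndividuals}: the individual table;
#'   \code{genotypeMatrix}: the allele matrix; \code{mhcMatrix}: the logical
#'   presence matrix; \code{cohortPanel}: the \code{AllelePanel} (or NULL);
#'   \code{pairings}: the pairing records; \code{lociNames}: locus names;
#'   \code{mhcRepertoire}: character vector of variants carried by one bird.
#' @export
cohortIndividuals <- function(cohort) cohort@individuals

#' @rdname cohortIndividuals
#' @export
genotypeMatrix <- function(cohort) cohort@genotypes

#' @rdname cohortIndividuals
#' @export
mhcMatrix <- function(cohort) cohort@mhc

#' @rdname cohortIndividuals
#' @export
cohortPanel <- function(cohort) cohort@panel

#' @rdname cohortIndividuals
#' @export
pairings <- function(cohort) cohort@pairings

#' @rdname cohortIndividuals
#' @export
lociNames <- function(cohort) {
  cn <- colnames(cohort@genotypes)
  unique(sub("\\.[12]$", "", cn))
}

#' @rdname cohortIndividuals
#' @export
mhcRepertoire <- function(cohort, id) {
  i <- match(id, cohort@individuals$id)
  if (is.na(i)) stop(sprintf("no individual with id '%s'", id))
  colnames(cohort@mhc)[cohort@mhc[i, ]]
}

setMethod("show", "Cohort", function(object) {
  ind <- object@individuals
  cat(sprintf("Cohort: %d individuals (%d M, %d F) on %s\n",
              nrow(ind), sum(ind$sex == "M"), sum(ind$sex == "F"),
              paste(unique(ind$island), collapse = "+")))
  cat(sprintf("  %d microsatellite loci; %d MHC variants; %d birds MHC-typed\n",
              ncol(object@genotypes) / 2L, ncol(object@mhc), sum(ind$hasMHC)))
  if (nrow(object@pairings))
    cat(sprintf("  %d pairing records (%d observed pairs)\n",
                nrow(object@pairings), sum(object@pairings$observed)))
})

#' Attach pairing records to a cohort
#'
#' Sets the \code{pairings} slot and synchronises the per-individual
#' \code{paired}, \code{mateId} and \code{divorceStatus} columns.  Every
#' individual not named in an observed pairing is marked unpaired.
#'
#' @param cohort a \code{\linkS4class{Cohort}}.
#' @param pairingTable data.frame with \code{femaleId}, \code{maleId},
#'   \code{observed} and optionally \code{outcome}.
#' @return the updated \code{Cohort}.
#' @export
setPairings <- function(cohort, pairingTable) {
  if (is.null(pairingTable$outcome)) pairingTable$outcome <- NA_character_
  ind <- cohort@individuals
  ind$paired <- FALSE
  ind$mateId <- NA_character_
  ind$divorceStatus <- NA_character_
  obs <- pairingTable[pairingTable$observed, , drop = FALSE]
  if (anyDuplicated(obs$femaleId) || anyDuplicated(obs$maleId))
    stop("an individual appears in more than one observed pairing")
  fi <- match(obs$femaleId, ind$id)
  mi <- match(obs$maleId, ind$id)
  if (anyNA(fi) || anyNA(mi))
    stop("pairing table names individuals absent from the cohort")
  if (any(ind$sex[fi] != "F") || any(ind$sex[mi] != "M"))
    stop("pairing table violates female x male orientation")
  ind$paired[c(fi, mi)] <- TRUE
  ind$mateId[fi] <- obs$maleId
  ind$mateId[mi] <- obs$femaleId
  ind$divorceStatus[fi] <- obs$outcome
  ind$divorceStatus[mi] <- obs$outcome
  cohort@individuals <- ind
  cohort@pairings <- pairingTable
  validObject(cohort)
  cohort
}

#' Drop birds without MHC typing, together with their social mates
#'
#' Pairings where either member lacks MHC data cannot enter the
#' MHC analyses; the convention is to exclude both members of such a
#' pairing.  Unpaired birds without MHC data are dropped as well.
#'
#' @param cohort a \code{\linkS4class{Cohort}} with pairings set.
#' @return a list: \code{cohort} (the filtered cohort), \code{nExcluded}
#'   (birds removed), \code{nPairingsBefore}, \code{nPairingsAfter}.
#' @export
excludeMissingMHC <- function(cohort) {
  ind <- cohort@individuals
  noMHC <- ind$id[!ind$hasMHC]
  pr <- cohort@pairings
  before <- sum(pr$observed)
  dropPair <- pr$observed & (pr$femaleId %in% noMHC | pr$maleId %in% noMHC)
  dropIds <- unique(c(noMHC, pr$femaleId[dropPair], pr$maleId[dropPair]))
  keep <- !(ind$id %in% dropIds)
  pr2 <- pr[!(pr$femaleId %in% dropIds | pr$maleId %in% dropIds), , drop = FALSE]
  out <- new("Cohort",
             individuals = `rownames<-`(ind[keep, , drop = FALSE], NULL),
             genotypes = cohort@genotypes[keep, , drop = FALSE],
             mhc = cohort@mhc[keep, , drop = FALSE],
             panel = cohort@panel, pairings = pr2)
  validObject(out)
  list(cohort = out, nExcluded = sum(!keep),
       nPairingsBefore = before, nPairingsAfter = sum(pr2$observed))
}

#' Restrict a cohort to one island
#'
#' @param cohort a \code{\linkS4class{Cohort}}.
#' @param island island label to keep.
#' @return the subset \code{Cohort}; pairings are filtered to members kept.
#' @export
subsetIsland <- function(cohort, island) {
  ind <- cohort@individuals
  keep <- ind$island == island
  if (!any(keep)) stop(sprintf("no individuals on island '%s'", island))
  ids <- ind$id[keep]
  pr <- cohort@pairings
  pr <- pr[pr$femaleId %in% ids & pr$maleId %in% ids, , drop = FALSE]
  out <- new("Cohort",
             individuals = `rownames<-`(ind[keep, , drop = FALSE], NULL),
             genotypes = cohort@genotypes[keep, , drop = FALSE],
             mhc = cohort@mhc[keep, , drop = FALSE],
             panel = cohort@panel, pairings = pr)
  validObject(out)
  out
}
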