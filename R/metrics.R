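#' PopulationReference: allele frequencies and locus heterozygosities
#'
#' Reference quantities that individual-level metrics are standardized
#' against: per-locus microsatellite allele frequencies (used by the
#' Queller-Goodnight relatedness estimator) and per-locus observed
#' heterozygosity (used to standardize individual heterozygosity Hs).
#'
#' @slot loci character vector of locus names.
#' @slot freqs named list, one named numeric vector of allele frequencies
#'   per locus; each sums to 1.
#' @slot obsHet numeric vector of observed heterozygosity per locus, in
#'   [0, 1], NA where no individual is typed.
#' @export
setClass("PopulationReference",
  representation(loci = "character", freqs = "list", obsHet = "numeric"))

setValidity("PopulationReference", function(object) {
  msg <- character()
  if (length(object@freqs) != length(object@loci) ||
      length(object@obsHet) != length(object@loci))
    msg <- c(msg, "freqs and obsHet must have one entry per locus")
  sums <- vapply(object@freqs, sum, numeric(1))
  ok <- vapply(object@freqs, length, integer(1)) == 0L | abs(sums - 1) < 1e-9
  if (!all(ok))
    msg <- c(msg, "allele frequencies must sum to 1 at every typed locus")
  h <- object@obsHet
  if (any(!is.na(h) & (h < 0 | h > 1)))
    msg <- c(msg, "observed heterozygosities must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Build a population reference from a cohort's genotypes
#'
#' Frequencies and observed heterozygosities are computed from all genotyped
#' individuals; \code{excludeIds} supports leave-out references (e.g.
#' leave-pair-out relatedness).
#'
#' @param x a \code{\linkS4class{Cohort}} or a genotype matrix (two columns
#'   per locus, rownames = ids).
#' @param excludeIds ids to drop before computing frequencies.
#' @return a \code{\linkS4class{PopulationReference}}.
#' @export
populationReference <- function(x, excludeIds = NULL) {
  g <- if (is(x, "Cohort")) genotypeMatrix(x) else x
  if (!is.null(excludeIds)) {
    keep <- !(rownames(g) %in% excludeIds)
    if (!any(keep)) stop("excludeIds removes every individual")
    g <- g[keep, , drop = FALSE]
  }
  loci <- unique(sub("\\.[12]$", "", colnames(g)))
  freqs <- vector("list", length(loci))
  names(freqs) <- loci
  obsHet <- rep(NA_real_, length(loci))
  names(obsHet) <- loci
  for (k in seq_along(loci)) {
    a1 <- g[, 2L * k - 1L]
    a2 <- g[, 2L * k]
    typed <- !is.na(a1) & !is.na(a2)
    if (any(typed)) {
      tab <- table(c(a1[typed], a2[typed]))
      freqs[[k]] <- setNames(as.numeric(tab) / sum(tab), names(tab))
      obsHet[k] <- mean(a1[typed] != a2[typed])
    } else {
      freqs[[k]] <- numeric(0)
    }
  }
  new("PopulationReference", loci = loci, freqs = freqs, obsHet = obsHet)
}

setMethod("show", "PopulationReference", function(object) {
  cat(sprintf("PopulationReference: %d loci, mean observed het %.3f\n",
              length(object@loci), mean(object@obsHet, na.rm = TRUE)))
})

#' MHC diversity: the number of variants an individual carries
#'
#' @param cohort a \code{\linkS4class{Cohort}}.
#' @param ids individuals to evaluate (default: all MHC-typed birds).
#' @return named integer vector of repertoire sizes.
#' @examples
#' # a bird carrying 8 variants must be amplified from >= ceiling(8/2)
#' # diploid loci; see impliedMinLoci()
#' @export
mhcDiversity <- function(cohort, ids = NULL) {
  ind <- cohortIndividuals(cohort)
  if (is.null(ids)) ids <- ind$id[ind$hasMHC]
  i <- match(ids, ind$id)
  if (anyNA(i))
    stop(sprintf("unknown ids: %s", paste(ids[is.na(i)], collapse = ", ")))
  bad <- !ind$hasMHC[i]
  if (any(bad))
    stop(sprintf("missing MHC data for: %s (exclude these individuals)",
                 paste(ids[bad], collapse = ", ")))
  setNames(as.integer(rowSums(mhcMatrix(cohort)[i, , drop = FALSE])), ids)
}

#' Minimum number of diploid loci implied by a repertoire size
#'
#' A diploid individual can carry at most two distinct alleles per locus, so
#' observing k variants in one bird implies at least ceiling(k/2) amplified
#' loci.
#'
#' @param k repertoire size(s).
#' @return integer vector.
#' @export
impliedMinLoci <- function(k) as.integer(ceiling(k / 2))

.sxy <- function(rx, ry) {
  nx <- sum(rx); ny <- sum(ry)
  2 * sum(rx & ry) / (nx + ny)
}

#' MHC allele sharing Sxy between two individuals
#'
#' Sxy = 2 Nxy / (Nx + Ny), where Nxy is the number of variants shared and
#' Nx, Ny the repertoire sizes.  Symmetric, in [0, 1], and 1 exactly when
#' the two repertoires are identical as sets.
#'
#' @param cohort a \code{\linkS4class{Cohort}}.
#' @param idX,idY individual ids (any sex).
#' @return a number in [0, 1].
#' @export
alleleSharing <- function(cohort, idX, idY) {
  ind <- cohortIndividuals(cohort)
  i <- match(c(idX, idY), ind$id)
  if (anyNA(i)) stop("unknown individual id")
  if (any(!ind$hasMHC[i]))
    stop(sprintf("missing MHC data for: %s",
                 paste(c(idX, idY)[!ind$hasMHC[i]], collapse = ", ")))
  m <- mhcMatrix(cohort)
  .sxy(m[i[1L], ], m[i[2L], ])
}

#' Amino-acid p-distance between two sequences over a codon mask
#'
#' The proportion of masked codon positions at which the residues differ.
#' With \code{mask = NULL} all positions are used.
#'
#' @param seqA,seqB equal-length amino-acid strings.
#' @param mask 1-based positions to compare (default: all).
#' @return a fraction in [0, 1].
#' @export
pDistance <- function(seqA, seqB, mask = NULL) {
  a <- strsplit(as.character(seqA), "")[[1L]]
  b <- strsplit(as.character(seqB), "")[[1L]]
  if (length(a) != length(b))
    stop(sprintf("sequence length mismatch: %d vs %d", length(a), length(b)))
  if (is.null(mask)) mask <- seq_along(a)
  if (any(mask < 1L) || any(mask > length(a)))
    stop("mask index outside sequence")
  mean(a[mask] != b[mask])
}

#' Pairwise p-distance matrix among panel variants
#'
#' @param panel an \code{\linkS4class{AllelePanel}}.
#' @param mask a mask name in the panel (e.g. "pbr", "pss"), an integer
#'   vector of codon positions, or NULL for the full sequence.
#' @return symmetric numeric matrix with variant names as dimnames.
#' @export
panelPDistMatrix <- function(panel, mask = NULL) {
  if (is.character(mask) && length(mask) == 1L)
    mask <- maskCodons(panel, mask)
  seqs <- as.character(panelSequences(panel))
  nv <- length(seqs)
  D <- matrix(0, nv, nv, dimnames = list(names(seqs), names(seqs)))
  if (nv > 1L) {
    for (i in seq_len(nv - 1L)) {
      for (j in seq((i + 1L), nv)) {
        D[i, j] <- D[j, i] <- pDistance(seqs[i], seqs[j], mask)
      }
    }
  }
  D
}

#' Mean cross-repertoire amino-acid divergence between two individuals
#'
#' The mean p-distance over all variant pairs (a, b) with a in x's
#' repertoire and b in y's, including shared variants (which contribute 0).
#' Symmetric in its arguments.
#'
#' @param cohort a \code{\linkS4class{Cohort}} whose panel is set.
#' @param idX,idY individual ids.
#' @param mask mask name or codon positions passed to
#'   \code{\link{panelPDistMatrix}}.
#' @param pdistMatrix optionally a precomputed panel p-distance matrix (used
#'   by the dyad builder to avoid recomputation).
#' @return a fraction in [0, 1].
#' @export
dyadMeanPDistance <- function(cohort, idX, idY, mask = NULL,
                              pdistMatrix = NULL) {
  if (is.null(pdistMatrix)) {
    panel <- cohortPanel(cohort)
    if (is.null(panel)) stop("cohort has no allele panel attached")
    pdistMatrix <- panelPDistMatrix(panel, mask)
  }
  rx <- mhcRepertoire(cohort, idX)
  ry <- mhcRepertoire(cohort, idY)
  if (length(rx) == 0L || length(ry) == 0L)
    stop(sprintf("empty MHC repertoire for %s",
                 paste(c(idX, idY)[c(length(rx), length(ry)) == 0L],
                       collapse = ", ")))
  missing <- setdiff(c(rx, ry), rownames(pdistMatrix))
  if (length(missing))
    stop(sprintf("variants absent from panel: %s",
                 paste(missing, collapse = ", ")))
  mean(pdistMatrix[rx, ry])
}

.hsFromGenotype <- function(g, ref) {
  nl <- length(ref@loci)
  a1 <- g[2L * seq_len(nl) - 1L]
  a2 <- g[2L * seq_len(nl)]
  typed <- !is.na(a1) & !is.na(a2)
  if (!any(typed)) return(NA_real_)
  mean(a1[typed] != a2[typed]) / mean(ref@obsHet[typed])
}

#' Standardized individual heterozygosity (Hs)
#'
#' The proportion of typed loci at which an individual is heterozygous,
#' divided by the mean population observed heterozygosity over the loci at
#' which that individual was typed.  With complete typing the cohort mean is
#' 1 by construction.
#'
#' @param cohort a \code{\linkS4class{Cohort}}.
#' @param ids individuals to evaluate (default all).
#' @param ref a \code{\linkS4class{PopulationReference}}; default computed
#'   from the whole cohort.
#' @return named numeric vector of Hs values.
#' @export
standardizedHeterozygosity <- function(cohort, ids = NULL,
                                       ref = populationReference(cohort)) {
  ind <- cohortIndividuals(cohort)
  if (is.null(ids)) ids <- ind$id
  i <- match(ids, ind$id)
  if (anyNA(i)) stop("unknown individual id")
  g <- genotypeMatrix(cohort)
  out <- vapply(i, function(k) .hsFromGenotype(g[k, ], ref), numeric(1))
  if (anyNA(out))
    stop(sprintf("no typed locus for: %s", paste(ids[is.na(out)], collapse = ", ")))
  setNames(out, ids)
}

# Queller-Goodnight focal-locus components for one direction (x focal).
# gx, gy: numeric genotype vectors (2 entries per locus); returns summed
# numerator and denominator over usable loci.
.qgOneDirection <- function(gx, gy, ref) {
  num <- 0; den <- 0; used <- 0L
  for (k in seq_along(ref@loci)) {
    a <- gx[2L * k - 1L]; b <- gx[2L * k]
    c_ <- gy[2L * k - 1L]; d <- gy[2L * k]
    if (is.na(a) || is.na(b) || is.na(c_) || is.na(d)) next
    f <- ref@freqs[[k]]
    if (length(f) < 2L) next                       # monomorphic in reference
    pa <- f[as.character(a)]; pb <- f[as.character(b)]
    if (is.na(pa) || is.na(pb)) next               # allele unseen in reference
    num <- num + 0.5 * ((a == c_) + (a == d) + (b == c_) + (b == d)) - pa - pb
    den <- den + 1 + (a == b) - pa - pb
    used <- used + 1L
  }
  c(num = unname(num), den = unname(den), used = used)
}

#' Queller-Goodnight pairwise relatedness
#'
#' The allele-frequency-weighted relatedness estimator: per locus, with
#' focal individual x carrying alleles (a, b) and partner y carrying (c, d),
#' the focal numerator is 0.5 (dac + dad + dbc + dbd) - pa - pb and the
#' denominator 1 + dab - pa - pb (d = identity indicator, p = reference
#' frequency).  Numerators and denominators are summed over usable loci
#' before dividing, and the estimate is the average of the x-focal and
#' y-focal values.  Loci monomorphic in the reference or untyped in either
#' bird are skipped.  Expectation is about 0.5 for first-degree relatives,
#' 0.25 for half-sibs, 0 for unrelated dyads; a bird compared with itself
#' gives exactly 1.
#'
#' @param cohort a \code{\linkS4class{Cohort}}.
#' @param idX,idY individual ids.
#' @param ref a \code{\linkS4class{PopulationReference}} (default: computed
#'   from the whole cohort, focal pair included).
#' @return a real, typically in about [-1, 1].
#' @seealso \code{\link{qgFromGenotypes}} for raw genotype vectors.
#' @export
relatednessQG <- function(cohort, idX, idY, ref = populationReference(cohort)) {
  ind <- cohortIndividuals(cohort)
  i <- match(c(idX, idY), ind$id)
  if (anyNA(i)) stop("unknown individual id")
  g <- genotypeMatrix(cohort)
  qgFromGenotypes(g[i[1L], ], g[i[2L], ], ref)
}

#' @rdname relatednessQG
#' @param gx,gy numeric genotype vectors, two entries per locus in reference
#'   locus order.
#' @export
qgFromGenotypes <- function(gx, gy, ref) {
  fx <- .qgOneDirection(gx, gy, ref)
  fy <- .qgOneDirection(gy, gx, ref)
  if (fx[["used"]] == 0L)
    stop("no usable locus (typed in both individuals and polymorphic in reference)")
  # A direction's summed denominator can vanish (focal fully heterozygous at
  # loci whose alleles sit at frequency 1/2); pool numerators and
  # denominators across directions then, the original pooled estimator form.
  tol <- 1e-12
  if (abs(fx[["den"]]) < tol || abs(fy[["den"]]) < tol) {
    den <- fx[["den"]] + fy[["den"]]
    if (abs(den) < tol)
      stop("relatedness undefined: zero denominator in both focal directions")
    return((fx[["num"]] + fy[["num"]]) / den)
  }
  (fx[["num"]] / fx[["den"]] + fy[["num"]] / fy[["den"]]) / 2
}
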