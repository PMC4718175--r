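#' AllelePanel: MHC variants, their amino-acid sequences and codon masks
#'
#' An \code{AllelePanel} holds the pool of named MHC class I variants
#' segregating in a study system, the translated exon amino-acid sequence of
#' each variant (all the same length, one residue per codon), and one or more
#' named codon masks: 1-based codon index sets such as the peptide-binding
#' region (PBR) and the putatively positively selected sites (PSS).  The
#' masks restrict amino-acid p-distance calculations to functionally relevant
#' codons.
#'
#' @slot sequences an \code{\link[Biostrings]{AAStringSet}} of equal-length
#'   amino-acid sequences, uniquely named by variant.
#' @slot masks named list of strictly increasing integer vectors; 1-based
#'   codon indices into the alignment, each within \code{[1, nCodons]}.
#'
#' @seealso \code{\link{readAllelePanel}}, \code{\link{genAllelePanel}},
#'   \code{\link{pDistance}}
#' @export
setClass("AllelePanel",
  representation(sequences = "AAStringSet", masks = "list"))

setValidity("AllelePanel", function(object) {
  msg <- character()
  sq <- object@sequences
  if (length(sq) == 0L)
    msg <- c(msg, "panel has no sequences")
  if (is.null(names(sq)) || anyDuplicated(names(sq)) || any(names(sq) == ""))
    msg <- c(msg, "variant names must be present and unique")
  w <- Biostrings::width(sq)
  if (length(unique(w)) > 1L)
    msg <- c(msg, sprintf("sequences have unequal lengths: %s",
                          paste(unique(w), collapse = ", ")))
  nc <- if (length(w)) w[1L] else 0L
  for (mn in names(object@masks)) {
    m <- object@masks[[mn]]
    if (!is.numeric(m) || length(m) == 0L)
      msg <- c(msg, sprintf("mask '%s' is empty or non-numeric", mn))
    else if (any(m < 1L) || any(m > nc))
      msg <- c(msg, sprintf("mask '%s' has codon index outside [1, %d]", mn, nc))
    else if (anyDuplicated(m))
      msg <- c(msg, sprintf("mask '%s' has duplicated codon indices", mn))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AllelePanel
#'
#' @param sequences named \code{AAStringSet} (or named character vector) of
#'   equal-length amino-acid sequences, one per variant.
#' @param masks named list of 1-based codon index vectors (e.g.
#'   \code{list(pbr = ..., pss = ...)}).
#' @return an \code{\linkS4class{AllelePanel}}.
#' @examples
#' p <- AllelePanel(c(ua1 = "ARND", ua2 = "ARNE"), masks = list(pss = c(3, 4)))
#' panelPDistMatrix(p, "pss")["ua1", "ua2"]   # 0.5: differ at 1 of 2 codons
#' @export
AllelePanel <- function(sequences, masks = list()) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  masks <- lapply(masks, function(m) sort(as.integer(m)))
  new("AllelePanel", sequences = sequences, masks = masks)
}

#' @describeIn AllelePanel number of variants in the panel.
#' @param x,object an \code{AllelePanel}.
#' @export
setMethod("length", "AllelePanel", function(x) length(x@sequences))

#' Accessors for AllelePanel
#'
#' \code{panelSequences} returns the \code{AAStringSet}; \code{variantNames}
#' the variant names; \code{nCodons} the shared sequence length;
#' \code{maskCodons} one named mask (1-based codon indices);
#' \code{panelMasks} the full mask list.
#'
#' @param panel an \code{\linkS4class{AllelePanel}}.
#' @param name mask name, e.g. \code{"pbr"} or \code{"pss"}.
#' @return see individual descriptions.
#' @export
panelSequences <- function(panel) panel@sequences

#' @rdname panelSequences
#' @export
variantNames <- function(panel) names(panel@sequences)

#' @rdname panelSequences
#' @export
nCodons <- function(panel) Biostrings::width(panel@sequences)[1L]

#' @rdname panelSequences
#' @export
panelMasks <- function(panel) panel@masks

#' @rdname panelSequences
#' @export
maskCodons <- function(panel, name) {
  if (!name %in% names(panel@masks))
    stop(sprintf("panel has no mask named '%s' (available: %s)",
                 name, paste(names(panel@masks), collapse = ", ")))
  panel@masks[[name]]
}

setMethod("show", "AllelePanel", function(object) {
  cat(sprintf("AllelePanel: %d variants x %d codons\n",
              length(object@sequences), nCodons(object)))
  cat("  variants:", paste(names(object@sequences), collapse = " "), "\n")
  for (mn in names(object@masks))
    cat(sprintf("  mask '%s': %d codons\n", mn, length(object@masks[[mn]])))
})
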