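#' TranscriptModel: a coding transcript with its exon map
#'
#' Holds one transcript model: identifiers, genomic location (exon intervals,
#' 1-based inclusive, stored in transcript 5'-to-3' order), the coding
#' sequence, and the protein derived from it. All downstream reconstruction
#' (variant application, mutant-protein translation, neoepitope windows) is
#' performed against these models, so any assembly whose coordinates match the
#' supplied annotation works.
#'
#' Validity requires: strand in \code{+}/\code{-}; exon intervals
#' non-overlapping and ordered 5' to 3' in transcript orientation (ascending
#' genomic coordinates on \code{+}, descending on \code{-}); the exon widths
#' summing to the CDS length; and the stored protein equal to
#' \code{translateCds(cdsSequence)}.
#'
#' @slot transcriptId character(1) transcript identifier.
#' @slot geneSymbol character(1) gene symbol.
#' @slot chrom character(1) chromosome name.
#' @slot strand character(1), \code{"+"} or \code{"-"}.
#' @slot exons [IRanges::IRanges] of exon intervals in transcript order.
#' @slot cdsSequence character(1) coding sequence (A/C/G/T/N).
#' @slot proteinSequence character(1) derived protein.
#'
#' @aliases TranscriptModel
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId    = "character",
    geneSymbol      = "character",
    chrom           = "character",
    strand          = "character",
    exons           = "IRanges",
    cdsSequence     = "character",
    proteinSequence = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  msgs <- character()
  if (!object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L)
    msgs <- c(msgs, "at least one exon required")
  if (length(ex) > 1L) {
    s <- IRanges::start(ex); e <- IRanges::end(ex)
    ord <- if (object@strand == "+") all(diff(s) > 0) && all(e[-length(e)] < s[-1L])
           else all(diff(s) < 0) && all(s[-length(s)] > e[-1L])
    if (!ord)
      msgs <- c(msgs, "exons must be non-overlapping and ordered 5'->3' in transcript orientation")
  }
  if (length(ex) && sum(IRanges::width(ex)) != nchar(object@cdsSequence))
    msgs <- c(msgs, sprintf("exon lengths sum to %d but CDS has %d nt",
                            sum(IRanges::width(ex)), nchar(object@cdsSequence)))
  prot <- tryCatch(translateCds(object@cdsSequence), error = function(e) NULL)
  if (is.null(prot))
    msgs <- c(msgs, "cdsSequence is not a valid nucleotide string")
  else if (!identical(prot, object@proteinSequence))
    msgs <- c(msgs, "proteinSequence does not equal translateCds(cdsSequence)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneSymbol,chrom Character scalars.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exonStarts,exonEnds Integer vectors of exon bounds (1-based
#'   inclusive) in transcript 5'-to-3' order.
#' @param cdsSequence Coding sequence; a CDS whose length is not a multiple of
#'   three is accepted with a warning (trailing bases are ignored in
#'   translation).
#' @return A validated \code{TranscriptModel}.
#' @examples
#' tm <- TranscriptModel("tx1", "GENE1", "chr1", "+", 101, 109, "ATGAAATAG")
#' proteinSequence(tm)  # "MK"
#' @export
TranscriptModel <- function(transcriptId, geneSymbol, chrom, strand,
                            exonStarts, exonEnds, cdsSequence) {
  cdsSequence <- toupper(cdsSequence)
  if (nchar(cdsSequence) %% 3L != 0L)
    warning("CDS of ", transcriptId, " is not a multiple of 3; trailing bases ignored")
  new("TranscriptModel",
      transcriptId    = as.character(transcriptId),
      geneSymbol      = as.character(geneSymbol),
      chrom           = as.character(chrom),
      strand          = as.character(strand),
      exons           = IRanges::IRanges(start = as.integer(exonStarts),
                                         end   = as.integer(exonEnds)),
      cdsSequence     = cdsSequence,
      proteinSequence = translateCds(cdsSequence))
}

#' @describeIn TranscriptModel-class Transcript identifier.
#' @param object,x A \code{TranscriptModel}.
#' @export
setGeneric("transcriptId", function(object) standardGeneric("transcriptId"))
#' @rdname TranscriptModel-class
#' @export
setMethod("transcriptId", "TranscriptModel", function(object) object@transcriptId)

#' @describeIn TranscriptModel-class Gene symbol.
#' @export
setGeneric("geneSymbol", function(object) standardGeneric("geneSymbol"))
#' @rdname TranscriptModel-class
#' @export
setMethod("geneSymbol", "TranscriptModel", function(object) object@geneSymbol)

#' @describeIn TranscriptModel-class Chromosome name.
#' @export
setGeneric("chrom", function(object) standardGeneric("chrom"))
#' @rdname TranscriptModel-class
#' @export
setMethod("chrom", "TranscriptModel", function(object) object@chrom)

#' @describeIn TranscriptModel-class Exon intervals (IRanges, transcript order).
#' @export
setGeneric("exons", function(object) standardGeneric("exons"))
#' @rdname TranscriptModel-class
#' @export
setMethod("exons", "TranscriptModel", function(object) object@exons)

#' @describeIn TranscriptModel-class Coding sequence.
#' @export
setGeneric("cdsSequence", function(object) standardGeneric("cdsSequence"))
#' @rdname TranscriptModel-class
#' @export
setMethod("cdsSequence", "TranscriptModel", function(object) object@cdsSequence)

#' @describeIn TranscriptModel-class Derived protein sequence.
#' @export
setGeneric("proteinSequence", function(object) standardGeneric("proteinSequence"))
#' @rdname TranscriptModel-class
#' @export
setMethod("proteinSequence", "TranscriptModel", function(object) object@proteinSequence)

#' @rdname TranscriptModel-class
#' @export
setMethod("strand", "TranscriptModel", function(x) x@strand)

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@transcriptId,
      sprintf("(%s, %s%s)", object@geneSymbol, object@chrom, object@strand), "\n")
  cat("  ", length(object@exons), "exon(s),",
      nchar(object@cdsSequence), "nt CDS,",
      nchar(object@proteinSequence), "aa protein\n")
})
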