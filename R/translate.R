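#' Translate a coding sequence
#'
#' Translates a CDS with the standard genetic code. Translation stops at (and
#' excludes) the first stop codon; a trailing partial codon is ignored; any
#' codon containing \code{N} yields \code{X}.
#'
#' @param cds Single non-empty string over \code{A,C,G,T,N} (case-insensitive).
#' @return Amino-acid string (possibly empty if the CDS is shorter than one
#'   codon or starts with a stop codon).
#' @examples
#' translateCds("ATGAAATAG")  # "MK"
#' translateCds("ATGGCANAA")  # "MAX"
#' translateCds("ATGCC")      # "M", partial codon dropped
#' @export
translateCds <- function(cds) {
  if (!is.character(cds) || length(cds) != 1L || is.na(cds) || !nzchar(cds))
    stop("cds must be a single non-empty nucleotide string")
  cds <- toupper(cds)
  if (grepl("[^ACGTN]", cds))
    stop("cds contains characters outside {A,C,G,T,N}")
  n <- nchar(cds) %/% 3L
  if (n == 0L)
    return("")
  starts <- seq(1L, by = 3L, length.out = n)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"   # codon containing N
  stops <- which(aa == "*")
  if (length(stops))
    aa <- aa[seq_len(stops[1L] - 1L)]
  paste(aa, collapse = "")
}

#' Map a genomic position into CDS coordinates
#'
#' Strand-aware conversion of a 1-based genomic position to a 1-based CDS
#' position. On the minus strand the 3'-most genomic base of the first exon in
#' transcript order maps to CDS position 1.
#'
#' @param transcript A [TranscriptModel-class] object.
#' @param genomicPos Integer genomic position (1-based).
#' @return Integer CDS position in \code{1..nchar(cdsSequence(transcript))}.
#' @seealso [cdsToGenomic()] for the inverse mapping.
#' @export
genomicToCds <- function(transcript, genomicPos) {
  stopifnot(is(transcript, "TranscriptModel"))
  genomicPos <- as.integer(genomicPos)
  ex <- exons(transcript)
  minus <- strand(transcript) == "-"
  offset <- 0L
  for (i in seq_along(ex)) {
    s <- IRanges::start(ex)[i]
    e <- IRanges::end(ex)[i]
    if (genomicPos >= s && genomicPos <= e) {
      within <- if (minus) e - genomicPos + 1L else genomicPos - s + 1L
      return(offset + within)
    }
    offset <- offset + (e - s + 1L)
  }
  stop("position ", genomicPos, " not in CDS of ", transcriptId(transcript))
}

#' Map a CDS position back to the genome
#'
#' Inverse of [genomicToCds()].
#'
#' @inheritParams genomicToCds
#' @param cdsPos Integer CDS position (1-based).
#' @return Integer genomic position.
#' @export
cdsToGenomic <- function(transcript, cdsPos) {
  stopifnot(is(transcript, "TranscriptModel"))
  cdsPos <- as.integer(cdsPos)
  if (cdsPos < 1L || cdsPos > nchar(cdsSequence(transcript)))
    stop("cdsPos ", cdsPos, " outside CDS of ", transcriptId(transcript))
  ex <- exons(transcript)
  minus <- strand(transcript) == "-"
  offset <- 0L
  for (i in seq_along(ex)) {
    w <- IRanges::width(ex)[i]
    if (cdsPos <= offset + w) {
      within <- cdsPos - offset
      return(if (minus) IRanges::end(ex)[i] - within + 1L
             else IRanges::start(ex)[i] + within - 1L)
    }
    offset <- offset + w
  }
  stop("cdsPos ", cdsPos, " outside CDS")   # unreachable if validity holds
}

# reverse complement of a plain character DNA string
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
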