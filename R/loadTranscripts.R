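#' Load transcript models from a CDS FASTA and an annotation table
#'
#' Reads coding sequences from \code{cdsFasta} and joins them with the exon
#' annotation table. The annotation table is TSV with columns
#' \code{transcript_id}, \code{gene_symbol}, \code{chrom}, \code{strand},
#' \code{exon_starts}, \code{exon_ends} (the last two comma-separated, in
#' transcript 5'-to-3' order). FASTA records without an annotation row are
#' skipped with a warning; models that fail the [TranscriptModel-class]
#' invariants (e.g. exon lengths not matching the CDS length) are rejected
#' with a warning naming the reason.
#'
#' @param cdsFasta Path to a FASTA file of coding sequences; record ids must
#'   match \code{transcript_id} in the annotation table.
#' @param annotationTable Path to the annotation TSV.
#' @return Named list of \code{TranscriptModel} objects, keyed by transcript id.
#' @export
loadTranscripts <- function(cdsFasta, annotationTable) {
  seqs <- Biostrings::readDNAStringSet(cdsFasta)
  ann <- read.delim(annotationTable, stringsAsFactors = FALSE,
                    colClasses = "character")
  needed <- c("transcript_id", "gene_symbol", "chrom", "strand",
              "exon_starts", "exon_ends")
  if (!all(needed %in% names(ann)))
    stop("annotation table lacks column(s): ",
         paste(setdiff(needed, names(ann)), collapse = ", "))
  ids <- sub("\\s.*$", "", names(seqs))   # FASTA id = first token
  out <- list()
  for (i in seq_along(seqs)) {
    id <- ids[i]
    row <- ann[ann$transcript_id == id, , drop = FALSE]
    if (nrow(row) == 0L) {
      warning("no annotation row for FASTA record ", id, "; skipped")
      next
    }
    row <- row[1L, ]
    tm <- tryCatch(
      TranscriptModel(
        transcriptId = id,
        geneSymbol   = row$gene_symbol,
        chrom        = row$chrom,
        strand       = row$strand,
        exonStarts   = as.integer(strsplit(row$exon_starts, ",")[[1]]),
        exonEnds     = as.integer(strsplit(row$exon_ends, ",")[[1]]),
        cdsSequence  = as.character(seqs[[i]])),
      error = function(e) {
        warning("transcript ", id, " rejected: ", conditionMessage(e))
        NULL
      })
    if (!is.null(tm))
      out[[id]] <- tm
  }
  out
}
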