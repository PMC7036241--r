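#' Read a transcript-abundance table
#'
#' Reads the TSV layout emitted by pseudo-alignment quantifiers
#' (\code{target_id, length, eff_length, est_counts, tpm}); only
#' \code{target_id} and \code{tpm} are required, extra columns are ignored.
#'
#' @param path Path to the abundance TSV.
#' @return data.frame with columns \code{target_id} and \code{tpm}.
#' @export
readAbundance <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("target_id", "tpm") %in% names(tab)))
    stop("abundance table must have 'target_id' and 'tpm' columns")
  tpm <- as.numeric(tab$tpm)
  if (any(is.na(tpm) | tpm < 0))
    stop("tpm column contains missing or negative values")
  data.frame(target_id = as.character(tab$target_id), tpm = tpm,
             stringsAsFactors = FALSE)
}

#' Aggregate transcript TPM to gene level
#'
#' Gene expression is the sum of the TPM of its member transcripts.
#' Transcripts missing from the transcript-to-gene map are ignored with a
#' warning; genes with no quantified transcript are absent from the result.
#'
#' @param records data.frame from [readAbundance()].
#' @param tx2gene Named character vector (names = transcript ids, values =
#'   gene symbols) or data.frame with columns \code{transcript_id},
#'   \code{gene_symbol}.
#' @return Named numeric vector of gene TPM.
#' @export
geneTpm <- function(records, tx2gene) {
  if (is.data.frame(tx2gene)) {
    stopifnot(all(c("transcript_id", "gene_symbol") %in% names(tx2gene)))
    tx2gene <- stats::setNames(as.character(tx2gene$gene_symbol),
                               tx2gene$transcript_id)
  }
  if (nrow(records) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  genes <- tx2gene[records$target_id]
  if (anyNA(genes)) {
    warning(sum(is.na(genes)), " transcript(s) absent from tx2gene map; ignored")
    keep <- !is.na(genes)
    records <- records[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  if (!nrow(records))
    return(stats::setNames(numeric(0), character(0)))
  out <- tapply(records$tpm, genes, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Expression filter for candidate neoantigens
#'
#' Candidates from genes expressed below \code{threshold} TPM are excluded.
#' Genes absent from the expression map are kept and flagged
#' \code{noExpressionData}, since expression filtering is an optional stage.
#' The two returned sets partition the input exactly.
#'
#' @param candidates data.frame from [annotateCandidates()] (any data.frame
#'   with a \code{geneSymbol} column works).
#' @param geneTpm Named numeric vector of gene-level TPM ([geneTpm()]).
#' @param threshold Minimum TPM (default 1); genes strictly below it are
#'   excluded.
#' @return List with elements \code{kept} and \code{excluded}; \code{kept}
#'   gains logical columns \code{noExpressionData} and numeric \code{tpm}
#'   (NA when unquantified).
#' @export
filterByExpression <- function(candidates, geneTpm, threshold = 1.0) {
  tpm <- unname(geneTpm[candidates$geneSymbol])
  hasData <- !is.na(tpm)
  excl <- hasData & tpm < threshold
  kept <- candidates[!excl, , drop = FALSE]
  kept$tpm <- tpm[!excl]
  kept$noExpressionData <- !hasData[!excl]
  excluded <- candidates[excl, , drop = FALSE]
  excluded$tpm <- tpm[excl]
  excluded$noExpressionData <- logical(nrow(excluded))
  list(kept = kept, excluded = excluded)
}
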