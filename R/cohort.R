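roundHalfUp <- function(x, digits = 2L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Shared-neoantigen recurrence table
#'
#' Aggregates per-sample annotated candidates into one row per distinct
#' (gene, amino-acid change, peptide, HLA allele) combination whose binder
#' category falls in \code{categoryFilter} in at least one sample. The same
#' peptide restricted by different alleles yields distinct rows. Frequencies
#' are percentages of the cohort, rounded half-up to two decimals
#' (17/466 = 3.65).
#'
#' @param candidates data.frame of annotated candidates across samples
#'   (requires columns \code{sampleId}, \code{geneSymbol}, \code{label},
#'   \code{mutPeptide}, \code{allele}, \code{category}).
#' @param cohortSize Total number of samples in the cohort; must be at least
#'   the number of distinct sample ids observed.
#' @param categoryFilter Binder categories to keep (default \code{"strong"}).
#' @return data.frame with columns \code{geneSymbol}, \code{aaChange},
#'   \code{peptide}, \code{allele}, \code{nSamples}, \code{cohortSize},
#'   \code{frequencyPct}, sorted by \code{nSamples} descending with ties
#'   broken by gene then peptide.
#' @export
recurrenceTable <- function(candidates, cohortSize,
                            categoryFilter = "strong") {
  nObserved <- length(unique(candidates$sampleId))
  if (cohortSize < nObserved)
    stop("cohortSize (", cohortSize, ") is smaller than the number of ",
         "observed samples (", nObserved, ")")
  sel <- candidates[candidates$category %in% categoryFilter, , drop = FALSE]
  out0 <- data.frame(geneSymbol = character(), aaChange = character(),
                     peptide = character(), allele = character(),
                     nSamples = integer(), cohortSize = integer(),
                     frequencyPct = numeric(), stringsAsFactors = FALSE)
  if (nrow(sel) == 0L)
    return(out0)
  key <- paste(sel$geneSymbol, sel$label, sel$mutPeptide, sel$allele,
               sep = "\r")
  n <- tapply(sel$sampleId, key, function(s) length(unique(s)))
  parts <- strsplit(names(n), "\r", fixed = TRUE)
  out <- data.frame(
    geneSymbol = vapply(parts, `[`, "", 1L),
    aaChange = vapply(parts, `[`, "", 2L),
    peptide = vapply(parts, `[`, "", 3L),
    allele = vapply(parts, `[`, "", 4L),
    nSamples = as.integer(n),
    cohortSize = as.integer(cohortSize),
    frequencyPct = roundHalfUp(100 * as.integer(n) / cohortSize, 2L),
    stringsAsFactors = FALSE)
  out <- out[order(-out$nSamples, out$geneSymbol, out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-residue binder coverage profile
#'
#' Builds the coverage track of predicted binders along a protein: every
#' residue starts at frequency 1 (so regions without any high-affinity
#' peptide remain visible at baseline), and each binder interval increments
#' the residues it covers by one.
#'
#' @param proteinLength Protein length in residues.
#' @param binderPositions Two-column matrix or data.frame of 1-based
#'   inclusive (start, end) intervals; may have zero rows.
#' @return data.frame with columns \code{residue} and \code{count}.
#' @export
coverageProfile <- function(proteinLength, binderPositions) {
  proteinLength <- as.integer(proteinLength)
  stopifnot(proteinLength >= 1L)
  counts <- rep(1L, proteinLength)
  bp <- as.matrix(binderPositions)
  if (length(bp)) {
    if (ncol(bp) != 2L)
      stop("binderPositions must have two columns (start, end)")
    for (i in seq_len(nrow(bp))) {
      s <- as.integer(bp[i, 1L]); e <- as.integer(bp[i, 2L])
      if (is.na(s) || is.na(e) || s < 1L || e > proteinLength || s > e)
        stop("interval (", s, ", ", e, ") out of range for protein of length ",
             proteinLength)
      counts[s:e] <- counts[s:e] + 1L
    }
  }
  data.frame(residue = seq_len(proteinLength), count = counts)
}

#' Genotype concordance of called variants against a truth set
#'
#' Fraction of called variants whose (chrom, pos, ref, alt) key appears in
#' the truth genotype set; the benchmark used to assess variant calls made
#' from RNA-seq against matched genome sequencing. Zygosity is not compared.
#'
#' @param called data.frame of called variants with columns \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt} (extra columns ignored; the layout
#'   of [readVcfRecords()] works directly).
#' @param truth data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}; keys must be unique.
#' @return Single numeric in [0, 1]; 0 with a warning when no variants were
#'   called.
#' @export
genotypeConcordance <- function(called, truth) {
  truthKey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
  if (anyDuplicated(truthKey))
    stop("truth set contains duplicate (chrom, pos, ref, alt) keys")
  if (nrow(called) == 0L) {
    warning("no called variants; concordance undefined, returning 0")
    return(0)
  }
  calledKey <- paste(called$chrom, called$pos, called$ref, called$alt,
                     sep = ":")
  mean(calledKey %in% truthKey)
}

#' Read a truth-genotype table
#'
#' @param path TSV with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @return data.frame.
#' @export
readTruthTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(tab)))
    stop("truth table must have columns chrom, pos, ref, alt")
  tab[needed]
}
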