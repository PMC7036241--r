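#' Read somatic variant records from a VCF
#'
#' Reads a single- or multi-sample VCF 4.x file and returns one row per
#' (sample, biallelic alt allele) with a called non-reference genotype.
#' Multi-allelic records are split into independent biallelic records; star
#' alleles are dropped. Read depth is taken from FORMAT \code{DP} (falling
#' back to INFO \code{DP}); alt-supporting read count from the corresponding
#' entry of FORMAT \code{AD}. Missing depth values are recorded as 0 with the
#' matching \code{*Known} flag set \code{FALSE}. snpEff-style INFO \code{ANN}
#' strings matching the alt allele, when present, are carried along in the
#' \code{annotations} list-column.
#'
#' @param path Path to a VCF file.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{sampleId}, \code{depth}, \code{altDepth},
#'   \code{depthKnown}, \code{altDepthKnown}, \code{annotations} (list).
#' @export
readVcfRecords <- function(path) {
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "unknown"),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e)))
  n <- nrow(vcf)
  samples <- colnames(vcf)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), sampleId = character(),
                      depth = integer(), altDepth = integer(),
                      depthKnown = logical(), altDepthKnown = logical(),
                      stringsAsFactors = FALSE)
  empty$annotations <- list()
  attr(empty, "samples") <- samples
  if (n == 0L || length(samples) == 0L)
    return(empty)

  rr <- SummarizedExperiment::rowRanges(vcf)
  chroms <- as.character(GenomicRanges::seqnames(rr))
  poss <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)           # DNAStringSetList-like
  geno <- VariantAnnotation::geno(vcf)
  gt <- if ("GT" %in% names(geno)) geno$GT else NULL
  if (is.null(gt))
    stop("VCF '", path, "' has no GT field; cannot determine called genotypes")
  dp <- if ("DP" %in% names(geno)) geno$DP else NULL
  ad <- if ("AD" %in% names(geno)) geno$AD else NULL
  info <- VariantAnnotation::info(vcf)
  infoDp <- if ("DP" %in% names(info)) info$DP else NULL
  ann <- if ("ANN" %in% names(info)) info$ANN else NULL

  rows <- vector("list", 0L)
  for (i in seq_len(n)) {
    altSet <- as.character(alts[[i]])
    for (j in seq_along(samples)) {
      g <- gt[i, j]
      if (is.na(g) || g %in% c(".", "./.", ".|."))
        next
      calledIdx <- suppressWarnings(
        unique(as.integer(strsplit(g, "[/|]")[[1]])))
      calledIdx <- calledIdx[!is.na(calledIdx) & calledIdx > 0L]
      for (a in calledIdx) {
        if (a > length(altSet))
          next
        altAllele <- altSet[a]
        if (altAllele %in% c("*", "<*>", "") || is.na(altAllele))
          next
        d <- NA_integer_
        if (!is.null(dp)) d <- dp[i, j]
        if (is.na(d) && !is.null(infoDp)) d <- infoDp[i]
        adv <- NA_integer_
        if (!is.null(ad)) {
          adij <- ad[[i, j]]
          if (!is.null(adij) && length(adij) >= a + 1L)
            adv <- adij[a + 1L]
        }
        annRec <- character()
        if (!is.null(ann)) {
          anni <- ann[[i]]
          if (length(anni))
            annRec <- anni[sub("\\|.*$", "", anni) == altAllele]
        }
        rows[[length(rows) + 1L]] <- list(
          chrom = chroms[i], pos = poss[i], ref = refs[i], alt = altAllele,
          sampleId = samples[j],
          depth = if (is.na(d)) 0L else as.integer(d),
          altDepth = if (is.na(adv)) 0L else as.integer(adv),
          depthKnown = !is.na(d), altDepthKnown = !is.na(adv),
          annotations = list(annRec))
      }
    }
  }
  if (!length(rows))
    return(empty)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(r[setdiff(names(r), "annotations")], stringsAsFactors = FALSE)))
  out$annotations <- lapply(rows, function(r) r$annotations[[1]])
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  out
}

#' RNA-seq variant quality filter
#'
#' Keeps records with total read depth at least \code{minDepth} and
#' alt-supporting reads at least \code{minAlt}. Records with unknown depth or
#' allele-depth fail the filter. Input order is preserved.
#'
#' @param records data.frame from [readVcfRecords()].
#' @param minDepth Minimum total read depth (default 10).
#' @param minAlt Minimum alt-supporting reads (default 5); read as
#'   alt-allele-supporting reads from the AD field.
#' @return Filtered data.frame.
#' @export
filterRnaseqVariants <- function(records, minDepth = 10L, minAlt = 5L) {
  if (nrow(records) == 0L)
    return(records)
  keep <- records$depthKnown & records$altDepthKnown &
    records$depth >= minDepth & records$altDepth >= minAlt
  records[keep, , drop = FALSE]
}

# Apply one VCF-style variant (genomic-strand ref/alt) to the CDS of a
# transcript. Handles minus-strand transcripts by reverse-complementing the
# alleles. Errors if the reference allele does not match the CDS or spans a
# splice boundary.
applyVariantToCds <- function(transcript, pos, ref, alt) {
  nr <- nchar(ref)
  cpos <- vapply(pos:(pos + nr - 1L),
                 function(p) genomicToCds(transcript, p), integer(1))
  step <- if (strand(transcript) == "-") -1L else 1L
  if (nr > 1L && !all(diff(cpos) == step))
    stop("reference allele spans a splice boundary in ",
         transcriptId(transcript))
  minus <- strand(transcript) == "-"
  cstart <- min(cpos); cend <- max(cpos)
  cds <- cdsSequence(transcript)
  refCds <- if (minus) revComp(ref) else ref
  altCds <- if (minus) revComp(alt) else alt
  if (substr(cds, cstart, cend) != refCds)
    stop("reference allele mismatch at CDS position ", cstart,
         " of ", transcriptId(transcript))
  paste0(substr(cds, 1L, cstart - 1L), altCds,
         substr(cds, cend + 1L, nchar(cds)))
}

firstProteinDiff <- function(wt, mut) {
  nw <- nchar(wt); nm <- nchar(mut)
  k <- min(nw, nm)
  if (k > 0L) {
    w <- strsplit(wt, "")[[1]][seq_len(k)]
    m <- strsplit(mut, "")[[1]][seq_len(k)]
    d <- which(w != m)
    if (length(d))
      return(d[1L])
  }
  if (nw != nm) k + 1L else NA_integer_
}

#' Classify the effect of a variant on a transcript
#'
#' Applies the variant to the transcript CDS, translates both sequences and
#' compares the proteins. A single-residue substitution is \code{missense};
#' an indel whose net length change is divisible by three is
#' \code{inframe_insertion}/\code{inframe_deletion}; any other net length
#' change is a \code{frameshift}; identical proteins are \code{synonymous};
#' stop-gain, stop-loss and start-loss (and multi-residue substitutions) are
#' \code{other}.
#'
#' @param variant One-row data.frame or list with \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (and optionally \code{sampleId}).
#' @param transcript A [TranscriptModel-class].
#' @return List of class \code{EffectCall} with fields \code{variant},
#'   \code{transcriptId}, \code{geneSymbol}, \code{effectClass},
#'   \code{cdsPos}, \code{proteinPos}, \code{refAa}, \code{altAa},
#'   \code{label} and the mutant CDS (\code{mutCds}).
#' @export
classifyEffect <- function(variant, transcript) {
  v <- as.list(variant)
  if (!is.null(v$chrom) && v$chrom != chrom(transcript))
    stop("variant chromosome ", v$chrom, " does not match transcript ",
         transcriptId(transcript))
  mutCds <- applyVariantToCds(transcript, v$pos, v$ref, v$alt)
  wtProt <- proteinSequence(transcript)
  mutProt <- translateCds(mutCds)
  indel <- nchar(v$alt) - nchar(v$ref)
  cposRef <- vapply(v$pos:(v$pos + nchar(v$ref) - 1L),
                    function(p) genomicToCds(transcript, p), integer(1))
  cdsPos <- min(cposRef)
  p <- firstProteinDiff(wtProt, mutProt)
  effectClass <-
    if (indel %% 3L != 0L) "frameshift"   # by frame, even if residues coincide
    else if (identical(wtProt, mutProt)) "synonymous"
    else if (indel > 0L) "inframe_insertion"
    else if (indel < 0L) "inframe_deletion"
    else {
      # same-length alleles: SNV or MNV
      if (nchar(mutProt) != nchar(wtProt)) "other"          # stop gain/loss
      else if (!is.na(p) && p == 1L && substr(wtProt, 1, 1) == "M" &&
               substr(mutProt, 1, 1) != "M") "other"        # start loss
      else {
        w <- strsplit(wtProt, "")[[1]]; m <- strsplit(mutProt, "")[[1]]
        if (sum(w != m) == 1L) "missense" else "other"
      }
    }
  if (is.na(p))
    p <- (cdsPos - 1L) %/% 3L + 1L     # frame-shifted but protein unchanged
  refAa <- if (p <= nchar(wtProt)) substr(wtProt, p, p) else ""
  altAa <- if (p <= nchar(mutProt)) substr(mutProt, p, p) else ""
  label <- switch(effectClass,
    missense          = paste0(refAa, p, altAa),
    synonymous        = paste0(refAa, p, "="),
    frameshift        = paste0(refAa, p, "fs"),
    inframe_insertion = paste0(refAa, p, "ins"),
    inframe_deletion  = paste0(refAa, p, "del"),
    paste0(refAa, p, altAa))
  structure(list(variant = v,
                 transcriptId = transcriptId(transcript),
                 geneSymbol = geneSymbol(transcript),
                 effectClass = effectClass,
                 cdsPos = cdsPos, proteinPos = p,
                 refAa = refAa, altAa = altAa, label = label,
                 mutCds = mutCds),
            class = "EffectCall")
}

# snpEff ANN effect terms mapped onto the internal effect classes; used when
# the caller opts to trust pre-parsed annotations instead of re-deriving them
# from transcript models.
annEffectClass <- function(annStrings) {
  if (!length(annStrings))
    return(NA_character_)
  terms <- vapply(strsplit(annStrings, "\\|"),
                  function(f) if (length(f) >= 2L) f[2L] else "", "")
  hit <- function(p) any(grepl(p, terms))
  if (hit("frameshift_variant")) "frameshift"
  else if (hit("inframe_insertion|conservative_inframe_insertion|disruptive_inframe_insertion")) "inframe_insertion"
  else if (hit("inframe_deletion|conservative_inframe_deletion|disruptive_inframe_deletion")) "inframe_deletion"
  else if (hit("missense_variant")) "missense"
  else if (hit("synonymous_variant")) "synonymous"
  else "other"
}

#' Map variant records onto transcripts and classify effects
#'
#' For each variant record, finds every transcript whose exons contain the
#' variant position (same chromosome) and classifies the effect. Variants
#' falling outside all transcript CDSs, or whose reference allele does not
#' match the model, are dropped with a warning.
#'
#' @param records data.frame from [readVcfRecords()].
#' @param transcripts Named list of [TranscriptModel-class] objects.
#' @param classes Effect classes to keep (default: the non-synonymous classes
#'   used for neoepitope construction).
#' @param trustAnnotations When \code{TRUE}, a record carrying snpEff-style
#'   ANN strings is gated on the annotated effect term instead of this
#'   package's own classification: records annotated outside \code{classes}
#'   are skipped without touching the transcript models (reconstruction of
#'   the kept records still runs against the models).
#' @return List of \code{EffectCall} objects.
#' @export
effectCallsForVariants <- function(records, transcripts,
                                   classes = c("missense", "inframe_insertion",
                                               "inframe_deletion", "frameshift"),
                                   trustAnnotations = FALSE) {
  calls <- list()
  for (i in seq_len(nrow(records))) {
    v <- records[i, , drop = FALSE]
    annGate <- NA_character_
    if (trustAnnotations && !is.null(records$annotations))
      annGate <- annEffectClass(records$annotations[[i]])
    if (!is.na(annGate) && !annGate %in% classes)
      next
    for (tm in transcripts) {
      if (chrom(tm) != v$chrom)
        next
      inExon <- any(v$pos >= IRanges::start(exons(tm)) &
                    v$pos <= IRanges::end(exons(tm)))
      if (!inExon)
        next
      eff <- tryCatch(classifyEffect(v, tm), error = function(e) {
        warning("variant ", v$chrom, ":", v$pos, " on ", transcriptId(tm),
                ": ", conditionMessage(e))
        NULL
      })
      if (is.null(eff))
        next
      if ((!is.na(annGate)) || eff$effectClass %in% classes)
        calls[[length(calls) + 1L]] <- eff
    }
  }
  calls
}
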