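CATEGORY_ALIASES <- c(strong = "High", intermediate = "Moderate",
                      weak = "Low", `non-binding` = "Non-binding")

#' Read an HLA allele list
#'
#' One allele per line; blank lines and \code{#} comments ignored; names
#' normalized via [normalizeHlaAllele()].
#'
#' @param path Text file of allele names.
#' @return Character vector of normalized alleles.
#' @export
readAlleleList <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  normalizeHlaAllele(lines)
}

#' Assemble and validate a pipeline run configuration
#'
#' @param vcf Path to a VCF file, or a directory of \code{.vcf} files (one
#'   per sample).
#' @param transcripts Path to the CDS FASTA.
#' @param annotation Path to the transcript annotation TSV.
#' @param alleles Character vector of HLA alleles, or path to an allele list
#'   file.
#' @param expression Optional path to an abundance TSV, or a directory of
#'   per-sample \code{<sampleId>.tsv} tables.
#' @param tx2gene Optional transcript-to-gene TSV (required with
#'   \code{expression}).
#' @param lengths Peptide lengths, \code{NULL} for class defaults.
#' @param method Binding method name (see [methodRegistry()]).
#' @param minDp,minAlt RNA-seq variant filter thresholds.
#' @param minTpm Expression filter threshold.
#' @param jobs Scoring batch size knob (results are identical for any value).
#' @param seed Seed recorded in the manifest.
#' @param outputDir Output directory.
#' @return List of class \code{RunConfig}.
#' @export
runConfig <- function(vcf, transcripts, annotation, alleles,
                      expression = NULL, tx2gene = NULL, lengths = NULL,
                      method = "toy", minDp = 10L, minAlt = 5L,
                      minTpm = 1.0, jobs = 1L, seed = 1L, outputDir) {
  for (p in c(vcf, transcripts, annotation))
    if (!file.exists(p))
      stop("input path does not exist: ", p)
  if (!is.null(expression)) {
    if (!file.exists(expression))
      stop("expression path does not exist: ", expression)
    if (is.null(tx2gene))
      stop("tx2gene is required when expression data are supplied")
  }
  if (length(alleles) == 1L && file.exists(alleles))
    alleles <- readAlleleList(alleles)
  else
    alleles <- normalizeHlaAllele(alleles)
  structure(list(vcf = vcf, transcripts = transcripts,
                 annotation = annotation, alleles = alleles,
                 expression = expression, tx2gene = tx2gene,
                 lengths = lengths, method = method,
                 minDp = as.integer(minDp), minAlt = as.integer(minAlt),
                 minTpm = minTpm, jobs = as.integer(jobs),
                 seed = as.integer(seed), outputDir = outputDir),
            class = "RunConfig")
}

renderReport <- function(candidates) {
  data.frame(
    Gene = candidates$geneSymbol,
    HLA_Allele = candidates$allele,
    Mutation_Type = candidates$effectClass,
    Ref_Peptide = ifelse(is.na(candidates$wtPeptide), "-",
                         candidates$wtPeptide),
    Alt_Peptide = candidates$mutPeptide,
    Ref_IC50 = round(candidates$ic50Wt, 2),
    Alt_IC50 = round(candidates$ic50Mut, 2),
    Category = unname(CATEGORY_ALIASES[candidates$category]),
    DAI = round(candidates$dai, 4),
    stringsAsFactors = FALSE)
}

vcfInputs <- function(vcf) {
  if (dir.exists(vcf)) {
    paths <- sort(list.files(vcf, pattern = "\\.vcf$", full.names = TRUE))
    if (!length(paths))
      stop("no .vcf files in directory ", vcf)
    paths
  } else vcf
}

#' Run the neoepitope prediction pipeline
#'
#' Loads the transcript models, reads the VCF input(s), applies the RNA-seq
#' quality filter, classifies variant effects against the models, builds
#' paired mutant/wild-type neoepitope windows, scores every covering k-mer
#' for each HLA allele, applies the expression filter when abundance data
#' are supplied, and writes per-sample output folders, each containing the
#' window FASTA and a candidate table with columns Gene, HLA_Allele,
#' Mutation_Type, Ref_Peptide, Alt_Peptide, Ref_IC50, Alt_IC50, Category and
#' DAI (categories reported as High/Moderate/Low/Non-binding), sorted by
#' mutant IC50 ascending. A YAML manifest records the configuration and
#' seed; a rerun with the same configuration reproduces the outputs exactly
#' under the built-in predictor.
#'
#' @param config A [runConfig()].
#' @return Invisibly, a named list (per sample) of annotated candidate
#'   data.frames (internal column layout, before report renaming).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  transcripts <- loadTranscripts(config$transcripts, config$annotation)
  if (!length(transcripts))
    stop("no usable transcript models")
  perFile <- lapply(vcfInputs(config$vcf), readVcfRecords)
  allSamples <- sort(unique(unlist(lapply(perFile, attr, "samples"))))
  records <- do.call(rbind, perFile)
  records <- filterRnaseqVariants(records, config$minDp, config$minAlt)

  tx2geneMap <- NULL
  if (!is.null(config$tx2gene))
    tx2geneMap <- read.delim(config$tx2gene, stringsAsFactors = FALSE)

  results <- list()
  for (sid in allSamples) {
    sampleRecords <- records[records$sampleId == sid, , drop = FALSE]
    effects <- effectCallsForVariants(sampleRecords, transcripts)
    windows <- buildWindows(effects, transcripts, sampleId = sid)
    sampleDir <- file.path(config$outputDir, sid)
    dir.create(sampleDir, showWarnings = FALSE, recursive = TRUE)
    writeWindowFasta(windows, file.path(sampleDir, "windows.fasta"))
    cand <- annotateCandidates(windows, config$alleles, config$lengths,
                               method = config$method,
                               batchSize = max(1L, 64L %/% config$jobs))
    if (!is.null(config$expression) && nrow(cand)) {
      expPath <- config$expression
      if (dir.exists(expPath)) {
        expPath <- file.path(expPath, paste0(sid, ".tsv"))
        if (!file.exists(expPath))
          stop("no abundance table for sample ", sid, " in ",
               config$expression)
      }
      gt <- geneTpm(readAbundance(expPath), tx2geneMap)
      split <- filterByExpression(cand, gt, config$minTpm)
      cand <- split$kept
      writeExcluded <- renderReport(split$excluded)
      write.table(writeExcluded, file.path(sampleDir, "excluded.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cand <- cand[order(cand$ic50Mut), , drop = FALSE]
    write.table(renderReport(cand), file.path(sampleDir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results[[sid]] <- cand
  }
  yaml::write_yaml(list(
    config = list(vcf = config$vcf, transcripts = config$transcripts,
                  annotation = config$annotation,
                  alleles = config$alleles,
                  expression = config$expression, tx2gene = config$tx2gene,
                  lengths = config$lengths, method = config$method,
                  minDp = config$minDp, minAlt = config$minAlt,
                  minTpm = config$minTpm, jobs = config$jobs,
                  seed = config$seed),
    package = as.character(packageVersion("neoepitopes")),
    samples = names(results)),
    file.path(config$outputDir, "run_manifest.yaml"))
  invisible(results)
}

#' Collect annotated candidates across a cohort of per-sample VCFs
#'
#' Lighter-weight cohort path than [runPipeline()]: classifies, windows and
#' scores each sample's variants and returns the pooled candidate table,
#' ready for [recurrenceTable()]. No files are written.
#'
#' @param vcfPaths Character vector of per-sample VCF paths (or a directory).
#' @param transcripts Named list of [TranscriptModel-class] objects.
#' @param alleles HLA alleles.
#' @param lengths Peptide lengths (default 9-mers, the canonical class I
#'   length).
#' @param minDp,minAlt Variant filter thresholds.
#' @param method,predictor Passed to [annotateCandidates()].
#' @return data.frame of pooled annotated candidates.
#' @export
cohortCandidates <- function(vcfPaths, transcripts, alleles, lengths = 9L,
                             minDp = 10L, minAlt = 5L,
                             method = "toy", predictor = NULL) {
  if (length(vcfPaths) == 1L && dir.exists(vcfPaths))
    vcfPaths <- vcfInputs(vcfPaths)
  pooled <- list()
  for (path in vcfPaths) {
    records <- filterRnaseqVariants(readVcfRecords(path), minDp, minAlt)
    if (!nrow(records))
      next
    effects <- effectCallsForVariants(records, transcripts)
    windows <- buildWindows(effects, transcripts)
    cand <- annotateCandidates(windows, alleles, lengths,
                               method = method, predictor = predictor)
    if (nrow(cand))
      pooled[[length(pooled) + 1L]] <- cand
  }
  if (!length(pooled))
    return(annotateCandidates(buildWindows(list(), list()), character(0)))
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out
}
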