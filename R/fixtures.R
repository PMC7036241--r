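# run expr with a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed)
    old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification for a synthetic cohort fixture
#'
#' Describes the synthetic reference, cohort and expression data produced by
#' [makeReference()], [makeCohortVcfs()] and [makeAbundance()]. The defaults
#' emulate a melanoma-sized tumor cohort: 466 samples with recurrent
#' missense variants planted in 17, 6 and 5 carriers (the carrier counts of
#' the most recurrent shared neoantigens such a cohort yields), against a
#' small gene panel.
#'
#' @param nGenes Number of genes (one transcript each).
#' @param cdsLengthRange Min/max CDS length in codons; genes carrying a
#'   planted variant are lengthened as needed to contain it.
#' @param nSamples Cohort size.
#' @param plantedVariants data.frame with columns \code{geneIndex},
#'   \code{effectClass} (\code{missense} or \code{frameshift}),
#'   \code{proteinPos}, \code{nCarriers}. Carriers are always samples
#'   \code{1..nCarriers}, so planted content is independent of the seed.
#' @param backgroundRate Mean number of private background variants per
#'   sample (Poisson).
#' @param seed Integer seed driving every random choice.
#' @return List of class \code{FixtureSpec}.
#' @export
fixtureSpec <- function(nGenes = 6L,
                        cdsLengthRange = c(60L, 320L),
                        nSamples = 466L,
                        plantedVariants = data.frame(
                          geneIndex = c(1L, 2L, 1L),
                          effectClass = "missense",
                          proteinPos = c(29L, 250L, 29L),
                          nCarriers = c(17L, 6L, 5L)),
                        backgroundRate = 1.5,
                        seed = 1L) {
  stopifnot(nGenes >= 1L, nSamples >= 1L,
            all(plantedVariants$nCarriers <= nSamples),
            all(plantedVariants$geneIndex <= nGenes))
  structure(list(nGenes = as.integer(nGenes),
                 cdsLengthRange = as.integer(cdsLengthRange),
                 nSamples = as.integer(nSamples),
                 plantedVariants = plantedVariants,
                 backgroundRate = backgroundRate,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a synthetic reference (CDS FASTA + annotation + tx2gene)
#'
#' Builds \code{nGenes} random coding sequences (starting ATG, ending with a
#' stop codon, no internal stops), lays them out as two-exon transcripts on
#' alternating strands of one synthetic chromosome, and writes the CDS FASTA,
#' the exon annotation TSV and the transcript-to-gene TSV. Fully reproducible
#' from the spec seed.
#'
#' @param spec A [fixtureSpec()].
#' @param dir Output directory (created if needed).
#' @return List with \code{transcripts} (named list of
#'   [TranscriptModel-class]), and paths \code{cdsFasta}, \code{annotation},
#'   \code{tx2gene}.
#' @export
makeReference <- function(spec, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  codons <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  withSeed(spec$seed, {
    lens <- sample(spec$cdsLengthRange[1]:spec$cdsLengthRange[2],
                   spec$nGenes, replace = TRUE)
    for (j in seq_len(nrow(spec$plantedVariants))) {
      g <- spec$plantedVariants$geneIndex[j]
      lens[g] <- max(lens[g], spec$plantedVariants$proteinPos[j] + 15L)
    }
    transcripts <- list()
    ann <- list(); cursor <- 1000L
    fastaLines <- character()
    for (g in seq_len(spec$nGenes)) {
      body <- sample(codons, lens[g] - 1L, replace = TRUE)
      cds <- paste0("ATG", paste(body, collapse = ""),
                    sample(STOP_CODONS, 1L))
      n <- nchar(cds)
      strandG <- if (g %% 2L == 1L) "+" else "-"
      # split into two exons with an intron gap
      w1 <- n %/% 2L
      e1 <- c(cursor, cursor + w1 - 1L)
      gap <- 200L
      e2 <- c(e1[2] + gap + 1L, e1[2] + gap + (n - w1))
      # exon order 5'->3' in transcript orientation
      if (strandG == "+") {
        starts <- c(e1[1], e2[1]); ends <- c(e1[2], e2[2])
      } else {
        starts <- c(e2[1], e1[1]); ends <- c(e2[2], e1[2])
      }
      txId <- sprintf("TX%03d", g); gene <- sprintf("GENE%03d", g)
      transcripts[[txId]] <- TranscriptModel(txId, gene, "chrS", strandG,
                                             starts, ends, cds)
      ann[[g]] <- data.frame(transcript_id = txId, gene_symbol = gene,
                             chrom = "chrS", strand = strandG,
                             exon_starts = paste(starts, collapse = ","),
                             exon_ends = paste(ends, collapse = ","),
                             stringsAsFactors = FALSE)
      fastaLines <- c(fastaLines, paste0(">", txId), cds)
      cursor <- e2[2] + 500L
    }
    cdsFasta <- file.path(dir, "cds.fasta")
    writeLines(fastaLines, cdsFasta)
    annPath <- file.path(dir, "annotation.tsv")
    write.table(do.call(rbind, ann), annPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    t2gPath <- file.path(dir, "tx2gene.tsv")
    write.table(data.frame(transcript_id = names(transcripts),
                           gene_symbol = vapply(transcripts, geneSymbol, "")),
                t2gPath, sep = "\t", quote = FALSE, row.names = FALSE)
    list(transcripts = transcripts, cdsFasta = cdsFasta,
         annotation = annPath, tx2gene = t2gPath)
  })
}

# genomic-strand base at genomic position y of a transcript's CDS
genomicBase <- function(tm, y) {
  cpos <- genomicToCds(tm, y)
  b <- substr(cdsSequence(tm), cpos, cpos)
  if (strand(tm) == "-") revComp(b) else b
}

# deterministic non-synonymous SNV at protein position p; `used` holds
# "pos:ref:alt" keys already planted so repeat plants at one site differ
plantMissenseSnv <- function(tm, p, used = character()) {
  cds <- cdsSequence(tm)
  codon <- substr(cds, 3L * p - 2L, 3L * p)
  oldAa <- unname(Biostrings::GENETIC_CODE[codon])
  for (b in 1:3) {
    for (nt in c("A", "C", "G", "T")) {
      if (substr(codon, b, b) == nt)
        next
      newCodon <- codon
      substr(newCodon, b, b) <- nt
      newAa <- unname(Biostrings::GENETIC_CODE[newCodon])
      if (is.na(newAa) || newAa == "*" || newAa == oldAa)
        next
      cdsPos <- 3L * p - 3L + b
      gpos <- cdsToGenomic(tm, cdsPos)
      refG <- genomicBase(tm, gpos)
      altG <- if (strand(tm) == "-") revComp(nt) else nt
      key <- paste(gpos, refG, altG, sep = ":")
      if (key %in% used)
        next
      return(list(chrom = chrom(tm), pos = gpos, ref = refG, alt = altG,
                  key = key))
    }
  }
  stop("no plantable missense SNV at protein position ", p, " of ",
       transcriptId(tm))
}

# deterministic 1-nt deletion causing a frameshift at/near codon p
plantFrameshiftDel <- function(tm, p, used = character()) {
  cdsRange <- (3L * p - 3L):(3L * p + 2L)
  cdsRange <- cdsRange[cdsRange >= 1L & cdsRange < nchar(cdsSequence(tm))]
  gpos <- sort(vapply(cdsRange, function(cp) cdsToGenomic(tm, cp), integer(1)))
  for (y in gpos) {
    ok <- tryCatch({ genomicToCds(tm, y + 1L); TRUE },
                   error = function(e) FALSE)
    if (!ok)
      next
    refG <- paste0(genomicBase(tm, y), genomicBase(tm, y + 1L))
    altG <- substr(refG, 1L, 1L)
    key <- paste(y, refG, altG, sep = ":")
    if (key %in% used)
      next
    return(list(chrom = chrom(tm), pos = y, ref = refG, alt = altG,
                key = key))
  }
  stop("no plantable frameshift deletion near codon ", p, " of ",
       transcriptId(tm))
}

writeSimpleVcf <- function(path, sampleId, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleId, sep = "\t"))
  body <- character()
  if (nrow(records)) {
    records <- records[order(records$chrom, records$pos), , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AD\t0/1:%d:%d,%d",
                    records$chrom, records$pos, records$ref, records$alt,
                    records$dp, records$dp - records$ad, records$ad)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate per-sample cohort VCFs with planted recurrent variants
#'
#' Writes one single-sample VCF per cohort member. Planted variants appear in
#' exactly samples \code{1..nCarriers} with read depths comfortably above the
#' RNA-seq filter thresholds (their choice involves no randomness, so carrier
#' content is identical under any seed); seeded private background variants
#' are added per sample with DP/AD spanning both sides of the (10, 5) filter
#' thresholds.
#'
#' @param spec A [fixtureSpec()].
#' @param reference Result of [makeReference()].
#' @param dir Output directory for the VCFs.
#' @return List with \code{vcfPaths} (named by sample id) and
#'   \code{plantedRecords} (data.frame of the planted variant records).
#' @export
makeCohortVcfs <- function(spec, reference, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txs <- reference$transcripts
  txIds <- names(txs)
  used <- character()
  planted <- list()
  pv <- spec$plantedVariants
  for (j in seq_len(nrow(pv))) {
    tm <- txs[[pv$geneIndex[j]]]
    rec <- if (pv$effectClass[j] == "frameshift")
      plantFrameshiftDel(tm, pv$proteinPos[j], used)
    else
      plantMissenseSnv(tm, pv$proteinPos[j], used)
    used <- c(used, rec$key)
    planted[[j]] <- data.frame(chrom = rec$chrom, pos = rec$pos,
                               ref = rec$ref, alt = rec$alt,
                               geneIndex = pv$geneIndex[j],
                               nCarriers = pv$nCarriers[j],
                               stringsAsFactors = FALSE)
  }
  plantedRecords <- do.call(rbind, planted)

  sampleIds <- sprintf("sample%03d", seq_len(spec$nSamples))
  vcfPaths <- character(spec$nSamples)
  withSeed(spec$seed + 1L, {
    for (s in seq_len(spec$nSamples)) {
      recs <- list()
      for (j in seq_len(nrow(plantedRecords))) {
        if (s <= plantedRecords$nCarriers[j]) {
          dp <- 30L + ((s * 7L + j) %% 40L)    # depth always passes the filter
          recs[[length(recs) + 1L]] <- data.frame(
            chrom = plantedRecords$chrom[j], pos = plantedRecords$pos[j],
            ref = plantedRecords$ref[j], alt = plantedRecords$alt[j],
            dp = dp, ad = dp %/% 2L, stringsAsFactors = FALSE)
        }
      }
      nBg <- rpois(1L, spec$backgroundRate)
      tries <- 0L
      while (nBg > 0L && tries < 50L) {
        tries <- tries + 1L
        tm <- txs[[sample(txIds, 1L)]]
        cp <- sample(seq_len(nchar(cdsSequence(tm)) - 3L), 1L) + 3L  # spare ATG
        gpos <- cdsToGenomic(tm, cp)
        if (gpos %in% plantedRecords$pos ||
            gpos %in% vapply(recs, function(r) r$pos, integer(1)))
          next
        refG <- genomicBase(tm, gpos)
        altG <- sample(setdiff(c("A", "C", "G", "T"), refG), 1L)
        dp <- sample(3:40, 1L)                 # straddles the DP >= 10 bound
        ad <- sample(0:dp, 1L)                 # straddles the alt >= 5 bound
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = chrom(tm), pos = gpos, ref = refG, alt = altG,
          dp = dp, ad = ad, stringsAsFactors = FALSE)
        nBg <- nBg - 1L
      }
      recdf <- if (length(recs)) do.call(rbind, recs)
               else data.frame(chrom = character(), pos = integer(),
                               ref = character(), alt = character(),
                               dp = integer(), ad = integer())
      vcfPaths[s] <- file.path(dir, paste0(sampleIds[s], ".vcf"))
      writeSimpleVcf(vcfPaths[s], sampleIds[s], recdf)
    }
  })
  names(vcfPaths) <- sampleIds
  list(vcfPaths = vcfPaths, plantedRecords = plantedRecords)
}

#' Generate per-sample transcript-abundance tables
#'
#' Writes one abundance TSV per sample in the layout consumed by
#' [readAbundance()]. Transcripts of planted genes are always expressed well
#' above 1 TPM (so planted candidates survive the expression filter); the
#' last unplanted gene is pinned below 1 TPM so each table straddles the
#' filter boundary; remaining genes draw seeded log-normal TPM.
#'
#' @param reference Result of [makeReference()].
#' @param spec A [fixtureSpec()].
#' @param dir Output directory.
#' @return Named character vector of per-sample abundance paths.
#' @export
makeAbundance <- function(reference, spec, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txs <- reference$transcripts
  txIds <- names(txs)
  plantedIdx <- unique(spec$plantedVariants$geneIndex)
  lowIdx <- setdiff(rev(seq_along(txIds)), plantedIdx)[1]
  sampleIds <- sprintf("sample%03d", seq_len(spec$nSamples))
  paths <- character(spec$nSamples)
  withSeed(spec$seed + 2L, {
    for (s in seq_len(spec$nSamples)) {
      tpm <- round(rlnorm(length(txIds), meanlog = 1, sdlog = 1.2), 3)
      tpm[plantedIdx] <- round(5 + runif(length(plantedIdx), 0, 20), 3)
      if (!is.na(lowIdx))
        tpm[lowIdx] <- round(runif(1, 0.05, 0.95), 3)
      len <- vapply(txs, function(t) nchar(cdsSequence(t)), integer(1))
      tab <- data.frame(target_id = txIds, length = len,
                        eff_length = pmax(len - 100L, 10L),
                        est_counts = round(tpm * 10, 1), tpm = tpm)
      paths[s] <- file.path(dir, paste0(sampleIds[s], ".tsv"))
      write.table(tab, paths[s], sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
  stats::setNames(paths, sampleIds)
}

#' Emit a self-contained synthetic fixture directory
#'
#' Runs [makeReference()], [makeCohortVcfs()] and [makeAbundance()] into one
#' directory, adds an HLA allele list, a truth-genotype table (the planted
#' variant sites) and a YAML run manifest recording the spec and seed.
#'
#' @param dir Target directory.
#' @param spec A [fixtureSpec()].
#' @param alleles HLA alleles written to \code{alleles.txt}.
#' @return Invisibly, a list with all generated paths plus the reference and
#'   planted records.
#' @export
simulateFixtures <- function(dir, spec = fixtureSpec(),
                             alleles = c("HLA-A*02:01", "HLA-A*11:01")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- makeReference(spec, dir)
  cohort <- makeCohortVcfs(spec, ref, file.path(dir, "vcf"))
  abundance <- makeAbundance(ref, spec, file.path(dir, "abundance"))
  allelePath <- file.path(dir, "alleles.txt")
  writeLines(alleles, allelePath)
  truthPath <- file.path(dir, "truth.tsv")
  write.table(cohort$plantedRecords[, c("chrom", "pos", "ref", "alt")],
              truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    spec = list(nGenes = spec$nGenes,
                cdsLengthRange = spec$cdsLengthRange,
                nSamples = spec$nSamples,
                plantedVariants = as.list(spec$plantedVariants),
                backgroundRate = spec$backgroundRate,
                seed = spec$seed),
    alleles = alleles,
    files = list(cdsFasta = ref$cdsFasta, annotation = ref$annotation,
                 tx2gene = ref$tx2gene, truth = truthPath)), manifest)
  invisible(list(reference = ref, cohort = cohort, abundance = abundance,
                 alleles = allelePath, truth = truthPath,
                 manifest = manifest))
}
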