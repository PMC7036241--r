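# Shared helpers: fixture builders and independent oracles used across tests.

# one codon per amino acid, used to build CDSs encoding a chosen protein
CODON_FOR <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
               M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

reverseTranslate <- function(protein, stop = TRUE) {
  aa <- strsplit(protein, "")[[1]]
  paste0(paste(CODON_FOR[aa], collapse = ""), if (stop) "TAA" else "")
}

# single-exon plus-strand transcript encoding `protein`, CDS starting at
# genomic position `at`
proteinTranscript <- function(protein, id = "tx1", gene = "G1", at = 1000L) {
  cds <- reverseTranslate(protein)
  TranscriptModel(id, gene, "chr1", "+", at, at + nchar(cds) - 1L, cds)
}

# independent translation oracle: Biostrings on the in-frame prefix,
# truncated at the first stop
oracleTranslate <- function(cds) {
  n <- 3L * (nchar(cds) %/% 3L)
  if (n == 0L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n)),
    if.fuzzy.codon = "X"))
  sub("\\*.*$", "", aa)
}

# write a VCF from header-free record lines (single FORMAT GT:DP:AD layout)
writeTestVcf <- function(lines, samples = "s1",
                         path = withr::local_tempfile(fileext = ".vcf",
                                                      .local_envir = parent.frame())) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, lines), path)
  path
}

# variant record row in the layout of readVcfRecords()
variantRow <- function(chrom = "chr1", pos, ref, alt, sampleId = "s1",
                       depth = 50L, altDepth = 25L) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             sampleId = sampleId, depth = as.integer(depth),
             altDepth = as.integer(altDepth),
             depthKnown = TRUE, altDepthKnown = TRUE,
             stringsAsFactors = FALSE)
}

# brute-force k-mer enumeration oracle: all k-mers of the mutant window
# overlapping any altered position
oracleEnumerate <- function(mutWindow, altFrom, altTo, k) {
  L <- nchar(mutWindow)
  starts <- Filter(function(i) {
    any(seq(i, i + k - 1L) %in% seq(altFrom, altTo))
  }, seq_len(max(L - k + 1L, 0L)))
  vapply(starts, function(i) substr(mutWindow, i, i + k - 1L), "")
}

randomProtein <- function(n) {
  paste(sample(names(CODON_FOR), n, replace = TRUE), collapse = "")
}

randomProteinSeeded <- function(n, seed, exclude = character()) {
  neoepitopes:::withSeed(seed,
    paste(sample(setdiff(names(CODON_FOR), exclude), n, replace = TRUE),
          collapse = ""))
}

# fixed 300-aa protein free of tryptophan (so a W substitution always alters)
randomProteinFixed300 <- function() {
  randomProteinSeeded(300, seed = 300, exclude = "W")
}
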