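test_that("readVcfRecords yields one record per called sample x alt allele", {
  p1 <- writeTestVcf("chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP:AD\t0/1:20:10,10")
  r1 <- readVcfRecords(p1)
  expect_identical(nrow(r1), 1L)
  expect_identical(r1$alt, "G")
  expect_identical(r1$depth, 20L)
  expect_identical(r1$altDepth, 10L)

  # multi-allelic 1/2 genotype splits into two biallelic records
  p2 <- writeTestVcf("chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT:DP:AD\t1/2:30:0,12,18")
  r2 <- readVcfRecords(p2)
  expect_identical(nrow(r2), 2L)
  expect_setequal(r2$alt, c("G", "T"))
  expect_identical(r2$altDepth[r2$alt == "G"], 12L)
  expect_identical(r2$altDepth[r2$alt == "T"], 18L)

  # 3 samples, called in 2
  p3 <- writeTestVcf(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP:AD\t0/1:20:10,10\t0/0:15:15,0\t1/1:8:0,8",
    samples = c("s1", "s2", "s3"))
  r3 <- readVcfRecords(p3)
  expect_identical(nrow(r3), 2L)
  expect_setequal(r3$sampleId, c("s1", "s3"))
})

test_that("missing depth fields are flagged unknown and fail the filter", {
  p <- writeTestVcf("chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1")
  r <- readVcfRecords(p)
  expect_false(r$depthKnown)
  expect_false(r$altDepthKnown)
  expect_identical(nrow(filterRnaseqVariants(r)), 0L)
})

test_that("the RNA-seq filter keeps DP >= 10 and alt reads >= 5 exactly", {
  recs <- rbind(variantRow(pos = 1, ref = "A", alt = "G", depth = 10, altDepth = 5),
                variantRow(pos = 2, ref = "A", alt = "G", depth = 9, altDepth = 5),
                variantRow(pos = 3, ref = "A", alt = "G", depth = 100, altDepth = 4))
  kept <- filterRnaseqVariants(recs)
  expect_identical(kept$pos, 1L)

  # idempotent, order-preserving, monotone in both thresholds
  set.seed(5)
  rand <- do.call(rbind, lapply(1:60, function(i) {
    d <- sample(0:20, 1)
    variantRow(pos = i, ref = "A", alt = "G", depth = d,
               altDepth = sample(0:d, 1))
  }))
  k1 <- filterRnaseqVariants(rand)
  expect_identical(filterRnaseqVariants(k1), k1)
  expect_false(is.unsorted(k1$pos))
  for (md in c(0L, 5L, 10L)) {
    lowered <- filterRnaseqVariants(rand, minDepth = md, minAlt = 2L)
    expect_true(all(k1$pos %in% lowered$pos))
  }
})

test_that("effect classification recovers missense, inframe and frameshift", {
  prot <- "MTEYKLVVVGAGGVKSALTI"        # 20 aa, K5 at codon 5
  tm <- proteinTranscript(prot, at = 1000L)
  # SNV in codon 10 (G): GGT -> CGT = R
  v <- variantRow(pos = 1000L + 27L, ref = "G", alt = "C")
  eff <- classifyEffect(v, tm)
  expect_identical(eff$effectClass, "missense")
  expect_identical(eff$proteinPos, 10L)
  expect_identical(eff$refAa, "G")
  expect_identical(eff$altAa, "R")
  expect_identical(eff$label, "G10R")

  # 3-nt insertion between codons 2 and 3 (anchor: last base of codon 2)
  vIns <- variantRow(pos = 1000L + 5L, ref = "T", alt = "TGCT")
  effIns <- classifyEffect(vIns, tm)
  expect_identical(effIns$effectClass, "inframe_insertion")

  # 1-nt deletion in codon 5 (K5, AAA): frameshift at protein position 5
  vDel <- variantRow(pos = 1000L + 12L, ref = "AA", alt = "A")
  effDel <- classifyEffect(vDel, tm)
  expect_identical(effDel$effectClass, "frameshift")
  expect_identical(effDel$proteinPos, 5L)

  # synonymous: CTT -> CTG (both L), codon 6
  vSyn <- variantRow(pos = 1000L + 17L, ref = "T", alt = "G")
  expect_identical(classifyEffect(vSyn, tm)$effectClass, "synonymous")

  # stop-gain is "other": Y4 TAT -> TAA
  vStop <- variantRow(pos = 1000L + 11L, ref = "T", alt = "A")
  expect_identical(classifyEffect(vStop, tm)$effectClass, "other")

  # outside the CDS
  vOut <- variantRow(pos = 999L, ref = "A", alt = "G")
  expect_error(classifyEffect(vOut, tm), "not in CDS")
})

test_that("effect classes match a translate-and-diff oracle on random CDSs", {
  set.seed(23)
  for (i in 1:40) {
    prot <- randomProtein(sample(15:40, 1))
    tm <- proteinTranscript(prot, at = 500L)
    cds <- cdsSequence(tm)
    kind <- sample(c("snv", "ins", "del"), 1)
    cp <- sample(2:(nchar(cds) - 4L), 1)    # spare the start codon and stop
    refBase <- substr(cds, cp, cp)
    v <- switch(kind,
      snv = variantRow(pos = 499L + cp, ref = refBase,
                       alt = sample(setdiff(c("A", "C", "G", "T"), refBase), 1)),
      ins = variantRow(pos = 499L + cp, ref = refBase,
                       alt = paste0(refBase, paste(
                         sample(c("A", "C", "G", "T"),
                                sample(c(1, 2, 3), 1), replace = TRUE),
                         collapse = ""))),
      del = {
        w <- sample(c(1, 2, 3), 1)
        variantRow(pos = 499L + cp,
                   ref = substr(cds, cp, min(cp + w, nchar(cds) - 3L)),
                   alt = refBase)
      })
    eff <- classifyEffect(v, tm)
    # oracle: edit the CDS string directly and translate with Biostrings
    mutCds <- paste0(substr(cds, 1, v$pos - 500L),
                     v$alt,
                     substr(cds, v$pos - 499L + nchar(v$ref), nchar(cds)))
    mutProt <- oracleTranslate(mutCds)
    indel <- nchar(v$alt) - nchar(v$ref)
    expected <-
      if (indel %% 3 != 0) "frameshift"
      else if (identical(mutProt, prot)) "synonymous"
      else if (indel > 0) "inframe_insertion"
      else if (indel < 0) "inframe_deletion"
      else if (nchar(mutProt) != nchar(prot)) "other"
      else {
        nd <- sum(strsplit(mutProt, "")[[1]] != strsplit(prot, "")[[1]])
        if (nd == 1) "missense" else "other"
      }
    expect_identical(eff$effectClass, expected,
                     info = paste(kind, v$pos, v$ref, v$alt))
  }
})

test_that("minus-strand variants are applied in transcript orientation", {
  # protein MKPGF on the minus strand: genomic sequence is the reverse
  # complement of the CDS
  cds <- reverseTranslate("MKPGF")        # ATG AAA CCT GGT TTT TAA
  tm <- TranscriptModel("m", "G", "chr1", "-", 2000L,
                        2000L + nchar(cds) - 1L, cds)
  # K2 (AAA), codon bases at CDS 4..6 map to genomic 2012..2014; a genomic
  # T->C at 2013 is CDS A->G at position 5: AAA -> AGA = R
  expect_identical(genomicToCds(tm, 2013L), 5L)
  v <- variantRow(pos = 2013L, ref = "T", alt = "C")
  eff <- classifyEffect(v, tm)
  expect_identical(eff$label, "K2R")
})

test_that("snpEff-style ANN strings are carried through and interpretable", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##INFO=<ID=ANN,Number=.,Type=String,Description="Annotation">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\t.\tA\tG\t.\tPASS\tANN=G|missense_variant|MODERATE|GENE1\tGT:DP:AD\t0/1:20:10,10"),
    p)
  r <- readVcfRecords(p)
  expect_identical(nrow(r), 1L)
  expect_match(r$annotations[[1]], "missense_variant")
  expect_identical(neoepitopes:::annEffectClass(r$annotations[[1]]),
                   "missense")

  # when annotations are trusted, a synonymous-annotated record is gated out
  # before any model lookup, and an annotated missense passes the gate
  prot <- "MTEYKLVVVGAGGVKSALTI"
  # variant pos 100 lands on CDS position 8 (E3 GAA -> GGA, missense E3G)
  tm <- list(tx1 = proteinTranscript(prot, at = 93L))
  rSyn <- r
  rSyn$annotations <- list("G|synonymous_variant|LOW|GENE1")
  expect_length(effectCallsForVariants(rSyn, tm, trustAnnotations = TRUE), 0L)
  expect_length(effectCallsForVariants(r, tm, trustAnnotations = TRUE), 1L)
})
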