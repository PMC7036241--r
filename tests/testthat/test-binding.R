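test_that("HLA allele names normalize idempotently with class inference", {
  expect_identical(normalizeHlaAllele("hla-a*02:01"), "HLA-A*02:01")
  expect_identical(normalizeHlaAllele("A0201"), "HLA-A*02:01")
  expect_identical(normalizeHlaAllele("HLA-A*0201"), "HLA-A*02:01")
  expect_identical(normalizeHlaAllele("DRB1*01:01"), "DRB1*01:01")
  expect_identical(normalizeHlaAllele("HLA-DRB10101"), "DRB1*01:01")
  x <- c("a1101", "dqb1*05:01")
  expect_identical(normalizeHlaAllele(normalizeHlaAllele(x)),
                   normalizeHlaAllele(x))
  expect_identical(hlaClass(c("A*02:01", "DRB1*01:01")), c("I", "II"))
  expect_error(normalizeHlaAllele("notanallele"), "cannot parse")
})

test_that("the method registry lists 7 IEDB class I, MHCflurry, and 4 class II methods", {
  reg <- methodRegistry()
  expect_identical(sum(reg$mhcClass == "I" & reg$source == "IEDB"), 7L)
  expect_identical(sum(reg$mhcClass == "II" & !reg$internal), 4L)
  expect_true("MHCflurry" %in% reg$method[reg$mhcClass == "I"])
  np <- reg[reg$method == "NetMHCpan", ]
  expect_identical(np$mhcClass, "I")
  expect_false(np$internal)
  expect_true(all(c("NetMHCIIpan", "NN-align", "SMM-align", "Sturniolo")
                  %in% reg$method[reg$mhcClass == "II"]))
  # toy is flagged internal in both classes
  expect_identical(reg$mhcClass[reg$internal], c("I", "II"))
})

test_that("the built-in predictor is deterministic, bounded and anchor-sensitive", {
  peps <- c("FSGEYIPTV", "LSMIVLLPNK", "AAAAAAAAA", "WWWWWWWWW")
  s1 <- toyPredict(peps, "HLA-A*02:01")
  s2 <- toyPredict(peps, "HLA-A*02:01")
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 <= 50000))
  # single-residue change at an anchor position changes the score
  expect_false(toyPredict("FSGEYIPTV", "HLA-A*02:01") ==
               toyPredict("FSGEYIPTL", "HLA-A*02:01"))
  # allele identity matters
  expect_false(all(toyPredict(peps, "HLA-A*02:01") ==
                   toyPredict(peps, "HLA-A*11:01")))
  expect_error(toyPredict("FSGEYIPTB", "HLA-A*02:01"), "invalid residue")
})

test_that("DAI is the wild-type/mutant IC50 ratio with reciprocal symmetry", {
  expect_identical(computeDai(500, 50), 10)
  expect_identical(computeDai(50, 50), 1)
  set.seed(8)
  a <- runif(50, 1, 5e4); b <- runif(50, 1, 5e4)
  expect_equal(computeDai(a, b) * computeDai(b, a), rep(1, 50))
  expect_error(computeDai(-1, 10), "positive")
  expect_error(computeDai(10, 0), "positive")
})

test_that("binder tiers partition the positive axis at 50/250/500 nM", {
  expect_identical(classifyBinder(30), "strong")
  expect_identical(classifyBinder(150), "intermediate")
  expect_identical(classifyBinder(300), "weak")
  expect_identical(classifyBinder(600), "non-binding")
  # boundary values
  expect_identical(classifyBinder(c(49.999, 50, 250, 250.001, 499.999, 500)),
                   c("strong", "intermediate", "intermediate", "weak",
                     "weak", "non-binding"))
  # exactly one category per value, ordering monotone in IC50
  grid <- c(seq(0.5, 700, by = 0.25), 5000, 50000)
  cats <- classifyBinder(grid)
  expect_true(all(cats %in% c("strong", "intermediate", "weak", "non-binding")))
  rank <- match(cats, c("strong", "intermediate", "weak", "non-binding"))
  expect_true(all(diff(rank) >= 0))
  expect_error(classifyBinder(0), "positive")
})

test_that("k-mer enumeration matches the brute-force overlap oracle", {
  prot <- randomProteinFixed300()
  mut <- prot; substr(mut, 100, 100) <- "W"
  w <- extractWindow(prot, mut, 100L, "missense")
  peps9 <- enumerateCandidatePeptides(w, 9L)
  expect_identical(nrow(peps9), 9L)
  expect_identical(peps9$mutPeptide,
                   oracleEnumerate(w$mutWindow, 11L, 11L, 9L))
  expect_false(is.unsorted(peps9$offset))
  # wild-type peptides pair at the same offsets and differ at one position
  expect_identical(peps9$wtPeptide,
                   substring(w$wtWindow, peps9$offset, peps9$offset + 8L))
  diffs <- mapply(function(m, wt)
    sum(strsplit(m, "")[[1]] != strsplit(wt, "")[[1]]),
    peps9$mutPeptide, peps9$wtPeptide)
  expect_true(all(diffs == 1L))

  # whole window as a single 21-mer
  expect_identical(nrow(enumerateCandidatePeptides(w, 21L)), 1L)
  expect_warning(none <- enumerateCandidatePeptides(w, 22L), "exceeds")
  expect_identical(nrow(none), 0L)

  # frameshift window, 30 residues with novel tail at 11..30
  fsw <- data.frame(sampleId = "s", geneSymbol = "g", transcriptId = "t",
                    effectClass = "frameshift",
                    mutWindow = randomProteinSeeded(30, seed = 6),
                    wtWindow = NA_character_, mutIndex = 11L,
                    alteredSpan = 20L, label = "fs", stringsAsFactors = FALSE)
  got <- enumerateCandidatePeptides(fsw, 9L)
  expect_identical(got$mutPeptide, oracleEnumerate(fsw$mutWindow, 11L, 30L, 9L))
  expect_true(all(is.na(got$wtPeptide)))

  # randomized agreement with the oracle
  set.seed(17)
  for (i in 1:20) {
    L <- sample(15:40, 1)
    mi <- sample(seq_len(L), 1)
    span <- sample(seq_len(L - mi + 1L), 1)
    k <- sample(8:12, 1)
    if (k > L) next
    wr <- data.frame(sampleId = "s", geneSymbol = "g", transcriptId = "t",
                     effectClass = "frameshift",
                     mutWindow = randomProtein(L), wtWindow = NA_character_,
                     mutIndex = mi, alteredSpan = span, label = "x",
                     stringsAsFactors = FALSE)
    expect_identical(enumerateCandidatePeptides(wr, k)$mutPeptide,
                     oracleEnumerate(wr$mutWindow, mi, mi + span - 1L, k))
  }
})

test_that("annotateCandidates scores all covering k-mers with DAI and tiers", {
  prot <- randomProteinFixed300()
  mut <- prot; substr(mut, 100, 100) <- "W"
  w <- extractWindow(prot, mut, 100L, "missense", sampleId = "s1",
                     geneSymbol = "G1", transcriptId = "t1", label = "X100W")
  cand <- annotateCandidates(w, "HLA-A*02:01", 9L)
  expect_identical(nrow(cand), 9L)
  expect_true(all(!is.na(cand$dai)))
  expect_equal(cand$dai, cand$ic50Wt / cand$ic50Mut)
  expect_identical(cand$category, classifyBinder(cand$ic50Mut))
  # scores come from the registered toy scheme
  expect_identical(cand$ic50Mut, toyPredict(cand$mutPeptide, "HLA-A*02:01"))

  # frameshift candidates have no wild-type pairing and no DAI
  mutFs <- paste0(substr(prot, 1, 99), randomProteinSeeded(25, seed = 12))
  wf <- extractWindow(prot, mutFs, 100L, "frameshift", sampleId = "s1",
                      geneSymbol = "G2", transcriptId = "t2", label = "Y100fs")
  candFs <- annotateCandidates(wf, "HLA-A*02:01", 9L)
  expect_gt(nrow(candFs), 0L)
  expect_true(all(is.na(candFs$dai)))
  expect_true(all(is.na(candFs$wtPeptide)))

  # empty allele list gives an empty result
  expect_identical(nrow(annotateCandidates(w, character(0), 9L)), 0L)

  # default lengths follow the MHC class
  candI <- annotateCandidates(w, "HLA-A*02:01")
  expect_setequal(unique(candI$length), 8:11)
  candII <- annotateCandidates(w, "DRB1*01:01")
  expect_identical(unique(candII$length), 15L)
})

test_that("candidate scoring is invariant to window order and batch size", {
  prot <- randomProteinFixed300()
  windows <- do.call(rbind, lapply(c(50, 120, 200), function(p) {
    mut <- prot; substr(mut, p, p) <- "W"
    extractWindow(prot, mut, p, "missense", sampleId = "s1",
                  geneSymbol = paste0("G", p), transcriptId = paste0("t", p),
                  label = paste0("X", p, "W"))
  }))
  base <- annotateCandidates(windows, c("HLA-A*02:01", "HLA-A*11:01"), 9L)
  shuffled <- annotateCandidates(windows[c(3, 1, 2), ],
                                 c("HLA-A*11:01", "HLA-A*02:01"), 9L)
  expect_identical(base, shuffled, ignore_attr = TRUE)
  for (bs in c(1L, 7L, 1000L)) {
    expect_identical(annotateCandidates(windows,
                                        c("HLA-A*02:01", "HLA-A*11:01"), 9L,
                                        batchSize = bs),
                     base, ignore_attr = TRUE)
  }
})

test_that("adapter failures are confined to their batch", {
  prot <- randomProteinFixed300()
  mut <- prot; substr(mut, 100, 100) <- "W"
  w <- extractWindow(prot, mut, 100L, "missense", sampleId = "s1",
                     geneSymbol = "G1", transcriptId = "t1", label = "X100W")
  calls <- 0L
  flaky <- function(peptides, allele) {
    calls <<- calls + 1L
    if (calls == 1L) stop("adapter down")
    toyPredict(peptides, allele)
  }
  cand <- annotateCandidates(w, "HLA-A*02:01", 9L, method = "toy",
                             predictor = flaky, batchSize = 3L)
  errs <- attr(cand, "batchErrors")
  expect_length(errs, 1L)
  expect_match(errs, "adapter down")
  expect_identical(nrow(cand), 6L)          # 9 minus the failed batch of 3
  expect_true(all(!is.na(cand$ic50Mut)))
})
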