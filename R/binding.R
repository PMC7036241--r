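AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

CLASS_I_GENES <- c("A", "B", "C", "E", "F", "G")

#' Normalize HLA allele names
#'
#' Accepts common spellings (\code{"HLA-A*02:01"}, \code{"a*0201"},
#' \code{"A0201"}, \code{"DRB1*01:01"}, \code{"HLA-DRB10101"}) and returns
#' the canonical form: class I as \code{"HLA-A*02:01"}, class II as
#' \code{"DRB1*01:01"}. Normalization is idempotent.
#'
#' @param x Character vector of allele names.
#' @return Character vector of normalized names.
#' @export
normalizeHlaAllele <- function(x) {
  vapply(x, function(s) {
    s <- toupper(gsub("[[:space:]]", "", s))
    s <- sub("^HLA-", "", s)
    m <- regmatches(s, regexec(
      "^(A|B|C|E|F|G|DRB[1-9]|DRA|DQA1|DQB1|DPA1|DPB1)\\*?([0-9]{2,3}):?([0-9]{2,3})$", s))[[1]]
    if (length(m) != 4L)
      stop("cannot parse HLA allele name '", s, "'")
    gene <- m[2L]
    core <- paste0(gene, "*", m[3L], ":", m[4L])
    if (gene %in% CLASS_I_GENES) paste0("HLA-", core) else core
  }, character(1), USE.NAMES = FALSE)
}

#' MHC class of an HLA allele
#'
#' @param x Character vector of allele names (any form accepted by
#'   [normalizeHlaAllele()]).
#' @return Character vector, \code{"I"} or \code{"II"}.
#' @export
hlaClass <- function(x) {
  norm <- normalizeHlaAllele(x)
  ifelse(grepl("^HLA-", norm), "I", "II")
}

#' Registry of binding-prediction methods
#'
#' Lists the supported MHC binding-affinity prediction methods: for HLA
#' class I the seven IEDB algorithms (NetMHC, NetMHCpan, NetMHCcons,
#' NetMHCstabpan, PickPocket, SMM, SMMPMBEC) plus MHCflurry; for class II
#' the four IEDB algorithms (NetMHCIIpan, NN-align, SMM-align, Sturniolo).
#' External methods are adapter descriptors only (the scoring models
#' themselves are not bundled); the built-in deterministic \code{toy}
#' predictor appears in both lists flagged \code{internal}.
#'
#' @return data.frame with columns \code{method}, \code{mhcClass},
#'   \code{source} (\code{IEDB}, \code{MHCflurry} or \code{internal}) and
#'   \code{internal} (logical).
#' @export
methodRegistry <- function() {
  data.frame(
    method = c("NetMHC", "NetMHCpan", "NetMHCcons", "NetMHCstabpan",
               "PickPocket", "SMM", "SMMPMBEC", "MHCflurry", "toy",
               "NetMHCIIpan", "NN-align", "SMM-align", "Sturniolo", "toy"),
    mhcClass = c(rep("I", 9L), rep("II", 5L)),
    source = c(rep("IEDB", 7L), "MHCflurry", "internal",
               rep("IEDB", 4L), "internal"),
    internal = c(rep(FALSE, 8L), TRUE, rep(FALSE, 4L), TRUE),
    stringsAsFactors = FALSE)
}

# fixed residue and position weights of the built-in predictor; literal so
# results are identical across platforms
TOY_RESIDUE_W <- c(0.80, 1.50, 0.30, 1.00, 1.70, 0.50, 1.20, 1.90, 0.70, 1.40,
                   0.20, 0.90, 1.60, 0.40, 1.10, 1.80, 0.60, 1.30, 0.10, 0.85)
TOY_POSITION_W <- c(0.55, 1.00, 0.45, 0.91, 0.36, 0.82, 0.27, 0.73, 0.18)

#' Deterministic built-in binding predictor
#'
#' A fixed position-weight scoring scheme over the 20-residue alphabet, keyed
#' on the (peptide, allele) pair: each residue contributes the product of a
#' fixed residue weight and a position weight whose phase is set by the
#' allele name, and the average is mapped monotonically onto an IC50-like
#' scale in (0, 50000] nM. It is stable across runs and platforms and exists
#' so the whole pipeline is exercisable and testable without external
#' binding-prediction software; its values are not biological predictions.
#'
#' @param peptides Character vector of peptides over the 20-aa alphabet.
#' @param allele Single allele name (any form accepted by
#'   [normalizeHlaAllele()]).
#' @return Numeric vector of IC50 values in nM, one per peptide.
#' @export
toyPredict <- function(peptides, allele) {
  allele <- normalizeHlaAllele(allele)
  chars <- utf8ToInt(allele)
  phase <- sum(chars * seq_along(chars)) %% length(TOY_POSITION_W)
  vapply(peptides, function(pep) {
    codes <- match(strsplit(pep, "")[[1]], AA20)
    if (anyNA(codes) || !length(codes))
      stop("invalid residue in peptide '", pep, "'")
    j <- ((seq_along(codes) - 1L + phase) %% length(TOY_POSITION_W)) + 1L
    s <- mean(TOY_RESIDUE_W[codes] * TOY_POSITION_W[j])
    50000 * (s / 1.9)^3
  }, numeric(1), USE.NAMES = FALSE)
}

#' Differential agretopicity index
#'
#' Fold change between the wild-type and mutant peptide binding scores:
#' \code{DAI = IC50_wt / IC50_mut}, so DAI > 1 flags a mutation that improves
#' HLA binding of the mutant peptide relative to its wild-type counterpart.
#'
#' @param ic50Wt,ic50Mut Positive IC50 values (nM); vectorized.
#' @return Numeric vector of DAI values.
#' @examples
#' computeDai(500, 50)  # 10: mutant binds 10x more strongly
#' @export
computeDai <- function(ic50Wt, ic50Mut) {
  if (any(!is.finite(ic50Wt) | ic50Wt <= 0) ||
      any(!is.finite(ic50Mut) | ic50Mut <= 0))
    stop("IC50 values must be positive")
  ic50Wt / ic50Mut
}

#' IC50 binder tiers
#'
#' Classifies predicted binding affinity: strong below 50 nM, intermediate
#' from 50 to 250 nM inclusive, weak above 250 and below 500 nM, and
#' non-binding at 500 nM and above. The three tiers plus non-binding
#' partition the positive axis.
#'
#' @param ic50 Positive numeric vector of IC50 values in nM.
#' @return Character vector in \code{strong}, \code{intermediate},
#'   \code{weak}, \code{non-binding}.
#' @export
classifyBinder <- function(ic50) {
  if (any(!is.finite(ic50) | ic50 <= 0))
    stop("IC50 values must be positive")
  ifelse(ic50 < 50, "strong",
    ifelse(ic50 <= 250, "intermediate",
      ifelse(ic50 < 500, "weak", "non-binding")))
}

#' Enumerate candidate k-mer peptides from a window
#'
#' Slides a k-residue window across the mutant neoepitope window and keeps
#' every k-mer overlapping at least one altered residue, left to right. For
#' missense windows the same-offset k-mer of the wild-type window is paired
#' with each mutant peptide; for other effect classes no positionally
#' matched wild-type peptide exists and \code{wtPeptide} is \code{NA}.
#'
#' @param window One-row data.frame from [extractWindow()].
#' @param k Peptide length (8-15).
#' @return data.frame with columns \code{offset} (1-based start within the
#'   window), \code{mutPeptide}, \code{wtPeptide}.
#' @export
enumerateCandidatePeptides <- function(window, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  w <- as.list(window)
  L <- nchar(w$mutWindow)
  out0 <- data.frame(offset = integer(), mutPeptide = character(),
                     wtPeptide = character(), stringsAsFactors = FALSE)
  if (k > L) {
    warning("k = ", k, " exceeds window length ", L, "; no peptides")
    return(out0)
  }
  altFrom <- w$mutIndex
  altTo <- w$mutIndex + w$alteredSpan - 1L
  starts <- seq_len(L - k + 1L)
  keep <- starts <= altTo & (starts + k - 1L) >= altFrom
  starts <- starts[keep]
  if (!length(starts))
    return(out0)
  mut <- substring(w$mutWindow, starts, starts + k - 1L)
  wt <- if (w$effectClass == "missense" && !is.na(w$wtWindow))
    substring(w$wtWindow, starts, starts + k - 1L)
  else rep(NA_character_, length(starts))
  data.frame(offset = starts, mutPeptide = mut, wtPeptide = wt,
             stringsAsFactors = FALSE)
}

#' Default peptide lengths per MHC class
#'
#' Class I: 8-11-mers; class II: 15-mers.
#'
#' @return Named list with elements \code{I} and \code{II}.
#' @export
defaultPeptideLengths <- function() {
  list(I = 8:11, II = 15L)
}

# score peptides in batches through an adapter; order-preserving, failures
# confined to their batch
scoreInBatches <- function(peptides, allele, predictor, batchSize) {
  n <- length(peptides)
  scores <- rep(NA_real_, n)
  errors <- character()
  if (n == 0L)
    return(list(scores = scores, errors = errors))
  batch <- ceiling(seq_len(n) / batchSize)
  for (b in unique(batch)) {
    idx <- which(batch == b)
    res <- tryCatch(predictor(peptides[idx], allele), error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("batch %d (%s): %s", b, allele,
                                  conditionMessage(res)))
    } else {
      if (length(res) != length(idx))
        errors <- c(errors, sprintf("batch %d (%s): adapter returned %d scores for %d peptides",
                                    b, allele, length(res), length(idx)))
      else scores[idx] <- res
    }
  }
  list(scores = scores, errors = errors)
}

#' Score candidate peptides across alleles and lengths
#'
#' Enumerates every covering k-mer of each window for each allele and peptide
#' length, scores mutant (and, for missense, wild-type) peptides through the
#' predictor adapter, and attaches the DAI and the binder tier. Results are
#' returned in a canonical sort order (sample, gene, transcript, label,
#' allele, length, offset) so they are invariant to the order of input
#' windows and to the batch size used for scoring.
#'
#' @param windows data.frame of windows ([buildWindows()]).
#' @param alleles Character vector of HLA allele names.
#' @param lengths Integer vector of peptide lengths, or \code{NULL} for the
#'   class-dependent defaults ([defaultPeptideLengths()]).
#' @param method Method name from [methodRegistry()]; only \code{"toy"} is
#'   executable without supplying \code{predictor}.
#' @param predictor Adapter function \code{(peptides, allele) -> IC50 vector}
#'   (nM, order-preserving); defaults to [toyPredict()] for \code{"toy"}.
#' @param batchSize Number of peptides per adapter call.
#' @return data.frame of annotated candidates with columns \code{sampleId},
#'   \code{geneSymbol}, \code{transcriptId}, \code{effectClass}, \code{label},
#'   \code{allele}, \code{mhcClass}, \code{length}, \code{offset},
#'   \code{mutPeptide}, \code{wtPeptide}, \code{ic50Mut}, \code{ic50Wt},
#'   \code{dai}, \code{category}. Adapter failures are recorded in the
#'   \code{"batchErrors"} attribute and their candidates dropped.
#' @export
annotateCandidates <- function(windows, alleles, lengths = NULL,
                               method = "toy", predictor = NULL,
                               batchSize = 64L) {
  reg <- methodRegistry()
  if (!method %in% reg$method)
    stop("unknown method '", method, "'; see methodRegistry()")
  if (is.null(predictor)) {
    if (method != "toy")
      stop("method '", method, "' requires an external predictor adapter; ",
           "pass `predictor`")
    predictor <- toyPredict
  }
  out0 <- data.frame(sampleId = character(), geneSymbol = character(),
                     transcriptId = character(), effectClass = character(),
                     label = character(), allele = character(),
                     mhcClass = character(), length = integer(),
                     offset = integer(), mutPeptide = character(),
                     wtPeptide = character(), ic50Mut = numeric(),
                     ic50Wt = numeric(), dai = numeric(),
                     category = character(), stringsAsFactors = FALSE)
  if (length(alleles) == 0L || nrow(windows) == 0L)
    return(out0)
  alleles <- normalizeHlaAllele(alleles)
  classes <- hlaClass(alleles)
  defaults <- defaultPeptideLengths()

  pieces <- list()
  for (ai in seq_along(alleles)) {
    lens <- if (is.null(lengths)) defaults[[classes[ai]]] else lengths
    for (k in lens) {
      for (wi in seq_len(nrow(windows))) {
        w <- windows[wi, , drop = FALSE]
        peps <- withCallingHandlers(
          enumerateCandidatePeptides(w, k),
          warning = function(cnd) invokeRestart("muffleWarning"))
        if (nrow(peps) == 0L)
          next
        pieces[[length(pieces) + 1L]] <- data.frame(
          sampleId = w$sampleId, geneSymbol = w$geneSymbol,
          transcriptId = w$transcriptId, effectClass = w$effectClass,
          label = w$label, allele = alleles[ai], mhcClass = classes[ai],
          length = k, peps, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(pieces))
    return(out0)
  cand <- do.call(rbind, pieces)
  # canonical order before scoring so batching is reproducible
  ord <- order(cand$sampleId, cand$geneSymbol, cand$transcriptId, cand$label,
               cand$allele, cand$length, cand$offset)
  cand <- cand[ord, , drop = FALSE]

  errors <- character()
  cand$ic50Mut <- NA_real_
  cand$ic50Wt <- NA_real_
  for (al in unique(cand$allele)) {
    sel <- which(cand$allele == al)
    sm <- scoreInBatches(cand$mutPeptide[sel], al, predictor, batchSize)
    cand$ic50Mut[sel] <- sm$scores
    errors <- c(errors, sm$errors)
    hasWt <- sel[!is.na(cand$wtPeptide[sel])]
    if (length(hasWt)) {
      sw <- scoreInBatches(cand$wtPeptide[hasWt], al, predictor, batchSize)
      cand$ic50Wt[hasWt] <- sw$scores
      errors <- c(errors, sw$errors)
    }
  }
  failed <- is.na(cand$ic50Mut) | (!is.na(cand$wtPeptide) & is.na(cand$ic50Wt))
  cand <- cand[!failed, , drop = FALSE]
  cand$dai <- ifelse(is.na(cand$ic50Wt), NA_real_,
                     cand$ic50Wt / cand$ic50Mut)
  cand$category <- classifyBinder(cand$ic50Mut)
  rownames(cand) <- NULL
  attr(cand, "batchErrors") <- errors
  cand
}
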