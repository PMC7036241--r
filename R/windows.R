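WINDOW_SIZE <- 21L
WINDOW_FLANK <- 10L

#' Build the mutant protein for an effect call
#'
#' Re-applies the variant of \code{effect} to the transcript CDS and
#' translates the result. For frameshifts, translation simply continues in
#' the shifted frame until the first stop codon, so the returned protein ends
#' at the new C-terminus.
#'
#' @param transcript The [TranscriptModel-class] the effect was called on.
#' @param effect An \code{EffectCall} from [classifyEffect()].
#' @return List with \code{mutProtein} and \code{firstAlteredPos} (the first
#'   residue differing from the wild-type protein; for a frameshift that
#'   leaves the translated residues unchanged, the codon of the edit), or
#'   \code{NULL} with a warning when the mutant protein is empty.
#' @export
buildMutantProtein <- function(transcript, effect) {
  stopifnot(inherits(effect, "EffectCall"),
            identical(effect$transcriptId, transcriptId(transcript)))
  mutProtein <- translateCds(effect$mutCds)
  if (!nzchar(mutProtein)) {
    warning("mutant protein of ", effect$label, " on ",
            transcriptId(transcript), " is empty; window skipped")
    return(NULL)
  }
  p <- firstProteinDiff(proteinSequence(transcript), mutProtein)
  if (is.na(p))
    p <- effect$proteinPos
  if (p > nchar(mutProtein)) {
    warning("alteration of ", effect$label, " lies beyond the mutant protein",
            " C-terminus; window skipped")
    return(NULL)
  }
  list(mutProtein = mutProtein, firstAlteredPos = p)
}

# length of the run of altered residues starting at p, by trimming the
# longest common suffix of the two proteins (never reaching back before p)
alteredRun <- function(wtProtein, mutProtein, p) {
  nw <- nchar(wtProtein); nm <- nchar(mutProtein)
  s <- 0L
  while (s < nm - p + 1L && s < nw &&
         substr(mutProtein, nm - s, nm - s) == substr(wtProtein, nw - s, nw - s))
    s <- s + 1L
  max(1L, (nm - s) - p + 1L)
}

# 21-residue window bounds around position p in a protein of length len:
# centered when possible, clamped to the protein start/end otherwise
windowBounds <- function(p, len) {
  if (len <= WINDOW_SIZE)
    return(c(1L, len))
  if (p - 1L < WINDOW_FLANK)            # mutation near the protein start
    return(c(1L, WINDOW_SIZE))
  if (len - p < WINDOW_FLANK)           # mutation near the protein end
    return(c(len - WINDOW_SIZE + 1L, len))
  c(p - WINDOW_FLANK, p + WINDOW_FLANK)
}

#' Extract a paired mutant/wild-type neoepitope window
#'
#' For missense and inframe effects, returns the 21-residue window of the
#' mutant protein centered on the first altered residue; when fewer than 10
#' residues precede (follow) the alteration, the window is the first (last)
#' 21 residues instead, and a protein shorter than 21 residues is returned
#' whole. For frameshifts the window is up to 10 wild-type residues preceding
#' the first altered residue plus the entire novel sequence through the new
#' C-terminus, and no wild-type window is produced (no positionally matched
#' wild-type counterpart exists).
#'
#' @param wtProtein,mutProtein Wild-type and mutant protein sequences.
#' @param firstAlteredPos 1-based position of the first altered residue in
#'   \code{mutProtein}.
#' @param effectClass One of \code{missense}, \code{inframe_insertion},
#'   \code{inframe_deletion}, \code{frameshift}.
#' @param sampleId,geneSymbol,transcriptId,label Metadata carried into the
#'   window record (\code{label} is the protein-change string, e.g.
#'   \code{"P29S"}).
#' @return One-row data.frame with columns \code{sampleId}, \code{geneSymbol},
#'   \code{transcriptId}, \code{effectClass}, \code{mutWindow},
#'   \code{wtWindow} (\code{NA} for frameshift), \code{mutIndex} (1-based
#'   index of the first altered residue within \code{mutWindow}),
#'   \code{alteredSpan}, \code{label}.
#' @export
extractWindow <- function(wtProtein, mutProtein, firstAlteredPos, effectClass,
                          sampleId = "", geneSymbol = "", transcriptId = "",
                          label = "") {
  p <- as.integer(firstAlteredPos)
  nm <- nchar(mutProtein)
  stopifnot(p >= 1L, p <= nm)
  if (effectClass == "frameshift") {
    from <- max(1L, p - WINDOW_FLANK)
    mutWindow <- substr(mutProtein, from, nm)
    wtWindow <- NA_character_
    mutIndex <- p - from + 1L
    span <- nchar(mutWindow) - mutIndex + 1L
  } else {
    b <- windowBounds(p, nm)
    mutWindow <- substr(mutProtein, b[1L], b[2L])
    mutIndex <- p - b[1L] + 1L
    run <- alteredRun(wtProtein, mutProtein, p)
    span <- min(run, b[2L] - p + 1L)
    if (effectClass == "missense") {
      wtWindow <- substr(wtProtein, b[1L], b[2L])
    } else {
      # inframe indel: same centering rule applied to the wild-type protein;
      # lengths may differ, so there is no per-offset pairing downstream
      pw <- min(p, nchar(wtProtein))
      bw <- windowBounds(pw, nchar(wtProtein))
      wtWindow <- substr(wtProtein, bw[1L], bw[2L])
      if (!nzchar(wtWindow)) wtWindow <- NA_character_
    }
  }
  data.frame(sampleId = sampleId, geneSymbol = geneSymbol,
             transcriptId = transcriptId, effectClass = effectClass,
             mutWindow = mutWindow, wtWindow = wtWindow,
             mutIndex = mutIndex, alteredSpan = span, label = label,
             stringsAsFactors = FALSE)
}

#' Build neoepitope windows for a set of effect calls
#'
#' Convenience wrapper running [buildMutantProtein()] and [extractWindow()]
#' over a list of effect calls against their transcripts.
#'
#' @param effects List of \code{EffectCall} objects.
#' @param transcripts Named list of [TranscriptModel-class] objects.
#' @param sampleId Sample identifier attached to each window; defaults to the
#'   variant's own sample id when present.
#' @return data.frame of windows (see [extractWindow()]), zero rows if none.
#' @export
buildWindows <- function(effects, transcripts, sampleId = NULL) {
  rows <- list()
  for (eff in effects) {
    tm <- transcripts[[eff$transcriptId]]
    if (is.null(tm))
      stop("transcript ", eff$transcriptId, " not in supplied models")
    bp <- buildMutantProtein(tm, eff)
    if (is.null(bp))
      next
    sid <- if (!is.null(sampleId)) sampleId
           else if (!is.null(eff$variant$sampleId)) eff$variant$sampleId
           else ""
    rows[[length(rows) + 1L]] <- extractWindow(
      proteinSequence(tm), bp$mutProtein, bp$firstAlteredPos,
      eff$effectClass, sampleId = sid, geneSymbol = eff$geneSymbol,
      transcriptId = eff$transcriptId, label = eff$label)
  }
  if (!length(rows))
    return(extractWindow("M", "M", 1L, "missense")[0L, ])
  do.call(rbind, rows)
}

#' Write neoepitope windows to FASTA
#'
#' Each window produces a mutant record with header
#' \code{>sample|gene|transcript|label|MUT} and, when a wild-type window
#' exists, a paired \code{|WT} record.
#'
#' @param windows data.frame of windows from [extractWindow()]/[buildWindows()].
#' @param path Output FASTA path.
#' @export
writeWindowFasta <- function(windows, path) {
  seqs <- character(); nms <- character()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    key <- paste(w$sampleId, w$geneSymbol, w$transcriptId, w$label, sep = "|")
    nms <- c(nms, paste0(key, "|MUT")); seqs <- c(seqs, w$mutWindow)
    if (!is.na(w$wtWindow)) {
      nms <- c(nms, paste0(key, "|WT")); seqs <- c(seqs, w$wtWindow)
    }
  }
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- nms
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read neoepitope windows back from FASTA
#'
#' Inverse of [writeWindowFasta()] for the header-encoded fields. MUT/WT
#' records are paired on the header key. The effect class and the altered
#' position are re-derived from the sequence pair where this is unambiguous
#' (missense: single differing residue); for windows without a wild-type
#' record the class is \code{frameshift} and \code{mutIndex} is \code{NA}.
#'
#' @param path FASTA path written by [writeWindowFasta()].
#' @return data.frame of windows.
#' @export
readWindowFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L)
    return(extractWindow("M", "M", 1L, "missense")[0L, ])
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 5L | !vapply(parts, function(p)
    p[5L] %in% c("MUT", "WT"), logical(1)))
  if (length(bad))
    stop("malformed window FASTA header: '", names(aa)[bad[1L]], "'")
  keys <- vapply(parts, function(p) paste(p[1:4], collapse = "|"), "")
  rows <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    kinds <- vapply(parts[idx], `[`, "", 5L)
    mutSeq <- as.character(aa[[idx[kinds == "MUT"][1L]]])
    wtSeq <- if (any(kinds == "WT"))
      as.character(aa[[idx[kinds == "WT"][1L]]]) else NA_character_
    f <- parts[[idx[1L]]]
    if (is.na(wtSeq)) {
      cls <- "frameshift"; mi <- NA_integer_; span <- NA_integer_
    } else if (nchar(wtSeq) == nchar(mutSeq)) {
      d <- which(strsplit(mutSeq, "")[[1]] != strsplit(wtSeq, "")[[1]])
      if (length(d) == 1L) {
        cls <- "missense"; mi <- d; span <- 1L
      } else {
        cls <- "other"; mi <- if (length(d)) d[1L] else NA_integer_
        span <- length(d)
      }
    } else {
      cls <- if (nchar(mutSeq) > nchar(wtSeq)) "inframe_insertion"
             else "inframe_deletion"
      mi <- NA_integer_; span <- NA_integer_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sampleId = f[1L], geneSymbol = f[2L], transcriptId = f[3L],
      effectClass = cls, mutWindow = mutSeq, wtWindow = wtSeq,
      mutIndex = mi, alteredSpan = span, label = f[4L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
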