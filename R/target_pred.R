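# Rule-based plant miRNA target prediction: ungapped miRNA:mRNA duplexes
# scored positionwise from the miRNA 5' end, G:U wobbles counting half a
# mismatch, with the five positional acceptance criteria of the classic
# plant target rules (Allen/Schwab style).

# state codes used throughout: "|" match, "o" G:U wobble, "x" mismatch

# per-position duplex state of miRNA base (5'->3') vs target base. The
# target window is read 5'->3' on the transcript, so miRNA position i faces
# window position L - i + 1.
.duplex_state <- function(mirna_base, target_base) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  if (target_base == wc[[mirna_base]]) return("|")
  # G:U wobble: miRNA G opposite target U(T), or miRNA U(T) opposite target G
  if ((mirna_base == "G" && target_base == "T") ||
    (mirna_base == "T" && target_base == "G")) {
    return("o")
  }
  "x"
}

#' Align a miRNA against one transcript window
#'
#' Builds the ungapped duplex between a miRNA and an equal-length
#' transcript window (the candidate target site, read 5'->3' on the
#' transcript). Position i of the miRNA (counted from its 5' end) faces
#' window position L - i + 1. Watson-Crick pairs are matches, G:U pairs
#' wobbles (weight 0.5), everything else mismatches (weight 1).
#'
#' @param mirna_seq mature miRNA sequence (RNA or DNA).
#' @param transcript_window transcript subsequence of the same length.
#' @return a list of class `target_alignment`: `states` (character vector
#'   over miRNA positions 1..L with codes `|`, `o`, `x`),
#'   `weighted_mismatches` (total weight), `seed_weighted` (weight over
#'   positions 1-12).
#' @export
align_site <- function(mirna_seq, transcript_window) {
  m <- seq_chars(as_dna(mirna_seq))
  w <- seq_chars(as_dna(transcript_window))
  if (length(m) != length(w)) {
    stop("window length must equal miRNA length", call. = FALSE)
  }
  L <- length(m)
  states <- vapply(
    seq_len(L),
    function(i) .duplex_state(m[i], w[L - i + 1L]),
    character(1)
  )
  weight <- c("|" = 0, o = 0.5, x = 1)[states]
  structure(
    list(
      states = states,
      weighted_mismatches = sum(weight),
      seed_weighted = sum(weight[seq_len(min(12L, L))])
    ),
    class = "target_alignment"
  )
}

#' Apply the five plant target acceptance criteria
#'
#' Evaluates a duplex state vector against, in order: (i) at most four
#' weighted mismatches overall (G:U counts 0.5); (ii) no more than two
#' adjacent mismatches anywhere; (iii) no adjacent mismatches in positions
#' 2-12; (iv) no mismatch at positions 10-11; (v) at most 2.5 weighted
#' mismatches in positions 1-12. Positions count from the miRNA 5' end.
#' Under the default wobble semantics a G:U wobble contributes to the
#' weighted totals of (i) and (v) but is not a "mismatch" for the
#' adjacency/positional rules (ii)-(iv); `strict_wobble = TRUE` treats
#' wobbles as mismatches everywhere.
#'
#' @param alignment a `target_alignment` from [align_site()], or a bare
#'   character vector of states (`|`, `o`, `x`).
#' @param max_weighted criterion (i) bound.
#' @param max_seed_weighted criterion (v) bound.
#' @param strict_wobble treat G:U as a full mismatch in all criteria.
#' @return a list with `accepted` (logical) and `reason` (`"ok"` or the
#'   first violated criterion: `"total_mismatches"`, `"adjacent"`,
#'   `"adjacent_2_12"`, `"position_10_11"`, `"seed_mismatches"`).
#' @export
accept_target <- function(alignment, max_weighted = 4, max_seed_weighted = 2.5,
                          strict_wobble = FALSE) {
  states <- if (inherits(alignment, "target_alignment")) {
    alignment$states
  } else {
    alignment
  }
  stopifnot(all(states %in% c("|", "o", "x")))
  L <- length(states)
  weight <- c("|" = 0, o = 0.5, x = 1)[states]
  if (strict_wobble) weight[states == "o"] <- 1
  is_mm <- if (strict_wobble) states != "|" else states == "x"

  # (i) total weighted mismatches
  if (sum(weight) > max_weighted) {
    return(list(accepted = FALSE, reason = "total_mismatches"))
  }
  # (ii) no more than two adjacent mismatches anywhere: no run of 3+
  runs <- rle(is_mm)
  if (any(runs$values & runs$lengths > 2L)) {
    return(list(accepted = FALSE, reason = "adjacent"))
  }
  # (iii) no adjacent (2+) mismatches within positions 2-12
  idx <- 2:min(12L, L)
  if (length(idx) > 1L) {
    adj <- is_mm[idx[-length(idx)]] & is_mm[idx[-1L]]
    if (any(adj)) {
      return(list(accepted = FALSE, reason = "adjacent_2_12"))
    }
  }
  # (iv) no mismatches at positions 10-11
  pos1011 <- intersect(10:11, seq_len(L))
  if (any(is_mm[pos1011])) {
    return(list(accepted = FALSE, reason = "position_10_11"))
  }
  # (v) weighted mismatches in positions 1-12
  if (sum(weight[seq_len(min(12L, L))]) > max_seed_weighted) {
    return(list(accepted = FALSE, reason = "seed_mismatches"))
  }
  list(accepted = TRUE, reason = "ok")
}

#' Scan transcripts for miRNA target sites
#'
#' Slides each miRNA along every transcript (every window of miRNA length,
#' on the given transcript strand, antisense duplex orientation) and keeps
#' the windows passing [accept_target()].
#'
#' @param mirnas named character vector (or data.frame with `id` and `seq`)
#'   of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences, or a
#'   [Biostrings::DNAStringSet], or a path to a transcript FASTA file.
#' @param ... passed to [accept_target()].
#' @return data.frame with columns mirna, transcript, start, end (1-based
#'   inclusive site coordinates on the transcript), weighted_mismatches,
#'   states (compact string, e.g. `"||o||x||..."`), sorted by (mirna,
#'   transcript, start).
#' @export
scan_transcripts <- function(mirnas, transcripts, ...) {
  if (is.data.frame(mirnas)) {
    mirnas <- stats::setNames(mirnas$seq, mirnas$id)
  }
  if (is.character(transcripts) && length(transcripts) == 1L &&
    file.exists(transcripts)) {
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  }
  tx <- stats::setNames(as.character(transcripts), names(transcripts))
  dots <- list(...)
  max_weighted <- if (is.null(dots$max_weighted)) 4 else dots$max_weighted
  hits <- list()
  for (mid in names(mirnas)) {
    mseq <- as_dna(mirnas[[mid]])
    L <- nchar(mseq)
    for (tid in names(tx)) {
      tseq <- as_dna(tx[[tid]])
      if (nchar(tseq) < L) next
      # cheap criterion-(i) prescreen; full rule evaluation on survivors
      starts <- .target_prefilter_cpp(mseq, tseq, max_weighted)
      for (s in starts) {
        aln <- align_site(mseq, substr(tseq, s, s + L - 1L))
        states <- aln$states
        verdict <- accept_target(aln, ...)
        if (verdict$accepted) {
          hits[[length(hits) + 1L]] <- data.frame(
            mirna = mid, transcript = tid,
            start = s, end = s + L - 1L,
            weighted_mismatches = sum(c("|" = 0, o = 0.5, x = 1)[states]),
            states = paste(states, collapse = ""),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(
      mirna = character(0), transcript = character(0),
      start = integer(0), end = integer(0),
      weighted_mismatches = numeric(0), states = character(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, hits)
  out[order(out$mirna, out$transcript, out$start), , drop = FALSE]
}
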