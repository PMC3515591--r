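# Novel miRNA precursor calling, MIREAP-style: cluster unannotated tag
# alignments into candidate windows, fold them, and accept hairpins in
# which the most-abundant tag (the putative mature) sits on one arm of a
# single dominant stem, with MFE and precursor-length gates.

#' Extract candidate precursor windows from tag alignments
#'
#' Clusters alignments per scaffold (alignments closer than `merge_gap`
#' are merged), extends each cluster by the flanks, and clips to scaffold
#' bounds. The window strand is the read-count-weighted majority strand of
#' its alignments (ties plus).
#'
#' @param alignments data.frame as returned by [map_tags()] (columns
#'   tag_seq, scaffold, start, end, strand); an optional `count` column
#'   weights the strand vote.
#' @param flank_up,flank_down bases added upstream/downstream of the
#'   cluster.
#' @param merge_gap alignments separated by at most this many bases join
#'   one cluster.
#' @param scaffold_lengths named integer vector of scaffold lengths, used
#'   to clip windows.
#' @return data.frame with columns scaffold, start, end, strand (window
#'   coordinates, 1-based inclusive).
#' @export
extract_candidate_loci <- function(alignments, flank_up = 200L,
                                   flank_down = 200L, merge_gap = 30L,
                                   scaffold_lengths = NULL) {
  if (!nrow(alignments)) {
    return(data.frame(
      scaffold = character(0), start = integer(0), end = integer(0),
      strand = character(0), stringsAsFactors = FALSE
    ))
  }
  w <- if ("count" %in% names(alignments)) alignments$count else rep(1L, nrow(alignments))
  out <- list()
  for (sc in sort(unique(alignments$scaffold))) {
    a <- alignments[alignments$scaffold == sc, , drop = FALSE]
    ww <- w[alignments$scaffold == sc]
    ir <- IRanges::IRanges(a$start, a$end)
    red <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
    ov <- IRanges::findOverlaps(ir, red, maxgap = merge_gap)
    for (k in seq_along(red)) {
      members <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == k]
      plus <- sum(ww[members][a$strand[members] == "+"])
      minus <- sum(ww[members][a$strand[members] == "-"])
      lo <- max(1L, BiocGenerics::start(red)[k] - flank_up)
      hi <- BiocGenerics::end(red)[k] + flank_down
      if (!is.null(scaffold_lengths) && sc %in% names(scaffold_lengths)) {
        hi <- min(hi, scaffold_lengths[[sc]])
      }
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, start = lo, end = hi,
        strand = if (minus > plus) "-" else "+",
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# hairpin loops (pairs enclosing no other pair) strictly inside (i, j)
.n_hairpins_inside <- function(pt, i, j) {
  n <- 0L
  for (k in seq_along(pt)) {
    l <- pt[k]
    if (l > k && k > i && l < j) {
      if (nrow(.direct_children(pt, k, l)) == 0L) n <- n + 1L
    }
  }
  n
}

#' Default precursor acceptance criteria
#'
#' @param mature_min_paired minimum paired mature positions (G:U counts as
#'   paired).
#' @param max_unpaired_mature maximum unpaired mature bases in the duplex.
#' @param max_asymmetry maximum difference between the paired mature span
#'   and the star span.
#' @param mfe_max maximum (least negative) precursor MFE, kcal/mol.
#' @param min_len,max_len precursor length bounds (nt).
#' @return named list of criteria, as consumed by [call_precursor()].
#' @export
precursor_criteria <- function(mature_min_paired = 16L,
                               max_unpaired_mature = 4L,
                               max_asymmetry = 2L,
                               mfe_max = -18,
                               min_len = 70L, max_len = 365L) {
  list(
    mature_min_paired = mature_min_paired,
    max_unpaired_mature = max_unpaired_mature,
    max_asymmetry = max_asymmetry,
    mfe_max = mfe_max, min_len = min_len, max_len = max_len
  )
}

.reject <- function(reason) {
  structure(list(accepted = FALSE, reason = reason), class = "precursor_call")
}

#' Call a precursor candidate from one window
#'
#' Selects the mature (the most abundant supporting tag of 18-26 nt found
#' in the window; ties broken by longer sequence, then 5'-most
#' occurrence), folds the window, extracts the stem harbouring the mature
#' (the mature/star span grown outward along enclosing base pairs), refolds
#' that precursor and tests, in order: the mature maps entirely to one arm
#' (`"arm"`); the arm belongs to a single stem ending in exactly one
#' hairpin loop, no multibranch between mature and loop (`"multibranch"`);
#' enough mature positions are paired (`"pairing"`); the mature/star
#' duplex has few unpaired bases and low asymmetry (`"duplex"`); the MFE
#' gate (`"mfe"`); and the precursor length bounds (`"length"`). The first
#' failed criterion is reported.
#'
#' @param window list with `seq` (window sequence, window-strand
#'   orientation) and optionally `scaffold`, `start`, `end`, `strand` for
#'   genomic coordinates (1-based inclusive; for minus-strand windows
#'   `seq` is the reverse complement of the genomic slice).
#' @param tags data.frame with columns `seq` and `count`: the supporting
#'   reads of the window.
#' @param criteria list from [precursor_criteria()].
#' @param id candidate identifier used in the returned record.
#' @return a `precursor_call` list: `accepted`, `reason`, and for accepted
#'   calls the candidate fields (precursor_seq, structure, mfe, locus,
#'   mature_seq, mature_arm, star_seq, read_support).
#' @export
call_precursor <- function(window, tags, criteria = precursor_criteria(),
                           id = NA_character_) {
  wseq <- as_dna(window$seq)
  if (is.null(tags) || !nrow(tags)) {
    return(.reject("no_mature"))
  }
  cand <- tags[nchar(tags$seq) >= 18L & nchar(tags$seq) <= 26L, , drop = FALSE]
  if (!nrow(cand)) {
    return(.reject("no_mature"))
  }
  cand$seq <- as_dna(cand$seq)
  cand$pos <- vapply(cand$seq, function(s) {
    as.integer(regexpr(s, wseq, fixed = TRUE))
  }, integer(1))
  cand <- cand[cand$pos > 0L, , drop = FALSE]
  if (!nrow(cand)) {
    return(.reject("no_mature"))
  }
  cand <- cand[order(-cand$count, -nchar(cand$seq), cand$pos), , drop = FALSE]
  mature <- cand$seq[1L]
  mpos <- cand$pos[1L]
  mlen <- nchar(mature)

  # fold at most 400 nt centred on the mature
  off <- 0L
  if (nchar(wseq) > 400L) {
    lo <- max(1L, mpos + mlen %/% 2L - 200L)
    hi <- min(nchar(wseq), lo + 399L)
    lo <- max(1L, hi - 399L)
    off <- lo - 1L
    wseq <- substr(wseq, lo, hi)
    mpos <- mpos - off
  }
  fw <- fold(wseq)
  pt <- pair_table(fw$structure)
  ms <- mpos
  me <- mpos + mlen - 1L

  span <- .mature_stem_span(pt, ms, me)
  if (is.character(span)) {
    return(.reject(span))
  }

  precursor <- substr(wseq, span$lo, span$hi)
  fp <- fold(precursor)
  ptp <- pair_table(fp$structure)
  pms <- ms - span$lo + 1L
  pme <- me - span$lo + 1L

  paired <- which(ptp[pms:pme] > 0L) + pms - 1L
  if (!length(paired)) {
    return(.reject("pairing"))
  }
  partners <- ptp[paired]
  right <- all(partners > pme)
  left <- all(partners < pms)
  if (!right && !left) {
    return(.reject("arm"))
  }
  # partners must descend as the mature position advances (clean stem) and
  # the stem must end in exactly one hairpin loop
  if (any(diff(partners) >= 0L)) {
    return(.reject("multibranch"))
  }
  inner <- if (right) c(max(paired), ptp[max(paired)]) else c(ptp[min(paired)], min(paired))
  # the stem must run into exactly one terminal hairpin loop (the innermost
  # mature pair may itself close that loop, hence the inclusive bounds)
  if (.n_hairpins_inside(ptp, inner[1L] - 1L, inner[2L] + 1L) != 1L) {
    return(.reject("multibranch"))
  }
  if (length(paired) < criteria$mature_min_paired) {
    return(.reject("pairing"))
  }
  if (mlen - length(paired) > criteria$max_unpaired_mature) {
    return(.reject("duplex"))
  }
  mature_span <- max(paired) - min(paired) + 1L
  star_span <- max(partners) - min(partners) + 1L
  if (abs(mature_span - star_span) > criteria$max_asymmetry) {
    return(.reject("duplex"))
  }
  if (fp$mfe > criteria$mfe_max) {
    return(.reject("mfe"))
  }
  plen <- nchar(precursor)
  if (plen < criteria$min_len || plen > criteria$max_len) {
    return(.reject("length"))
  }

  star_seq <- substr(precursor, min(partners), max(partners))
  # genomic coordinates of the precursor
  locus <- list(scaffold = window$scaffold, start = NA, end = NA, strand = window$strand)
  if (!is.null(window$start) && !is.na(window$start)) {
    glo <- span$lo + off
    ghi <- span$hi + off
    if (identical(window$strand, "-")) {
      locus$start <- window$end - ghi + 1L
      locus$end <- window$end - glo + 1L
    } else {
      locus$start <- window$start + glo - 1L
      locus$end <- window$start + ghi - 1L
    }
  }
  structure(list(
    accepted = TRUE, reason = "ok", id = id,
    precursor_seq = precursor, structure = fp$structure, mfe = fp$mfe,
    locus = locus,
    mature_seq = mature, mature_arm = if (right) "5p" else "3p",
    mature_start = pms, mature_end = pme,
    star_seq = star_seq,
    read_support = cand$count[1L]
  ), class = "precursor_call")
}

# span of the stem harbouring the mature: mature plus partners, grown
# outward along directly-enclosing base pairs (allowing small unpaired
# gaps); returns list(lo, hi) or a rejection reason string
.mature_stem_span <- function(pt, ms, me, gap = 5L) {
  paired <- which(pt[ms:me] > 0L) + ms - 1L
  if (!length(paired)) {
    return("pairing")
  }
  partners <- pt[paired]
  if (!(all(partners > me) || all(partners < ms))) {
    return("arm")
  }
  lo <- min(ms, min(partners))
  hi <- max(me, max(partners))
  repeat {
    ext <- FALSE
    for (p in (lo - 1L):(lo - gap)) {
      if (p < 1L) break
      if (pt[p] > hi && pt[p] - hi <= gap + 1L) {
        lo <- p
        hi <- pt[p]
        ext <- TRUE
        break
      }
    }
    if (!ext) break
  }
  list(lo = lo, hi = hi)
}

#' First-nucleotide composition of accepted matures
#'
#' @param mature_seqs character vector of mature sequences (5'->3').
#' @return named numeric vector of fractions over A, C, G, U summing to
#'   one; `NA` fractions for an empty input.
#' @export
first_nt_bias <- function(mature_seqs) {
  nts <- c("A", "C", "G", "U")
  if (!length(mature_seqs)) {
    return(stats::setNames(rep(NA_real_, 4L), nts))
  }
  first <- substr(as_rna(mature_seqs), 1L, 1L)
  counts <- vapply(nts, function(n) sum(first == n), numeric(1))
  counts / sum(counts)
}

#' Table of accepted precursor candidates
#'
#' Runs [call_precursor()] over a set of windows and collects accepted
#' candidates into a report table with Table-4-like columns.
#'
#' @param windows data.frame from [extract_candidate_loci()].
#' @param genome genome sequences (see [map_tags()]).
#' @param tags_by_window list of supporting-tag data.frames (seq, count),
#'   one per window row.
#' @param criteria list from [precursor_criteria()].
#' @param prefix candidate id prefix.
#' @return list with `candidates` (data.frame: id, mature_seq (RNA),
#'   star_seq, mature_arm, precursor_length, mfe, location
#'   "scaffold:start:end", strand, read_support) and `calls` (all
#'   `precursor_call` objects, including rejections).
#' @export
call_precursors <- function(windows, genome, tags_by_window,
                            criteria = precursor_criteria(), prefix = "m") {
  genome <- .load_genome(genome)
  calls <- vector("list", nrow(windows))
  rows <- list()
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    slice <- as.character(Biostrings::extractAt(
      genome[[w$scaffold]], IRanges::IRanges(w$start, w$end)
    ))
    wseq <- if (w$strand == "-") revcomp(slice) else slice
    id <- sprintf("%s%04d", prefix, k)
    call <- call_precursor(
      list(
        seq = wseq, scaffold = w$scaffold, start = w$start,
        end = w$end, strand = w$strand
      ),
      tags_by_window[[k]], criteria,
      id = id
    )
    calls[[k]] <- call
    if (call$accepted) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = id,
        mature_seq = as_rna(call$mature_seq),
        star_seq = as_rna(call$star_seq),
        mature_arm = call$mature_arm,
        precursor_length = nchar(call$precursor_seq),
        mfe = call$mfe,
        location = sprintf(
          "%s:%d:%d", call$locus$scaffold,
          call$locus$start, call$locus$end
        ),
        strand = call$locus$strand,
        read_support = call$read_support,
        stringsAsFactors = FALSE
      )
    }
  }
  candidates <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      id = character(0), mature_seq = character(0), star_seq = character(0),
      mature_arm = character(0), precursor_length = integer(0),
      mfe = numeric(0), location = character(0), strand = character(0),
      read_support = numeric(0), stringsAsFactors = FALSE
    )
  }
  list(candidates = candidates, calls = calls)
}
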