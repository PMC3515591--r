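# Identification of known mature miRNAs: tags are compared to a
# miRBase-style mature reference allowing up to two substitutions and a
# +/- 2 nt end shift (isomiR-style 5'/3' offsets), and read counts are
# aggregated per mature miRNA and per family.

#' Read a mature miRNA reference FASTA
#'
#' Headers are expected as `>id family species` (whitespace separated;
#' family and species optional). When the family token is absent it is
#' derived from the id (`miR` followed by digits).
#'
#' @param path FASTA file of mature miRNA sequences (RNA or DNA alphabet).
#' @return data.frame with columns id, family, species, seq (DNA
#'   alphabet).
#' @export
read_mature_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  tok <- strsplit(headers, "\\s+")
  id <- vapply(tok, `[`, character(1), 1L)
  fam <- vapply(tok, function(t) if (length(t) >= 2) t[2] else NA_character_, character(1))
  spc <- vapply(tok, function(t) if (length(t) >= 3) t[3] else NA_character_, character(1))
  fam[is.na(fam)] <- vapply(which(is.na(fam)), function(i) {
    m <- regmatches(id[i], regexpr("miR[0-9]+", id[i]))
    if (length(m)) m else id[i]
  }, character(1))
  data.frame(
    id = id, family = fam, species = spc,
    seq = as_dna(as.character(ss)), stringsAsFactors = FALSE
  )
}

#' Match tags against the mature miRNA reference
#'
#' Global comparison over equal-position windows: each tag is slid against
#' each mature sequence by offsets in `-max_shift..max_shift`; end
#' overhangs up to `max_shift` bases on either side are tolerated
#' (isomiR-style shifted ends) and substitutions are counted over the
#' overlap. The best hit has the fewest mismatches, ties broken by the
#' smallest absolute offset, then the lexicographically smallest mature
#' id. U/T are treated as equivalent.
#'
#' @param tags character vector of tag sequences (DNA or RNA).
#' @param mature_db data.frame from [read_mature_fasta()] (columns id,
#'   family, seq).
#' @param max_mm maximum substitutions in the overlap (default 2).
#' @param max_shift maximum end offset in nt (default 2).
#' @return data.frame with one row per tag that found a hit (tag_seq,
#'   mature_id, family, mismatches, offset).
#' @export
match_known_all <- function(tags, mature_db, max_mm = 2L, max_shift = 2L) {
  stopifnot(nrow(mature_db) > 0L)
  ord <- order(mature_db$id)
  db <- mature_db[ord, , drop = FALSE]
  res <- .match_known_cpp(
    as_dna(tags), as_dna(db$seq),
    as.integer(max_mm), as.integer(max_shift)
  )
  hit <- res[, 1L] > 0L
  data.frame(
    tag_seq = as_dna(tags)[hit],
    mature_id = db$id[res[hit, 1L]],
    family = db$family[res[hit, 1L]],
    mismatches = res[hit, 2L],
    offset = res[hit, 3L],
    stringsAsFactors = FALSE
  )
}

#' @rdname match_known_all
#' @param tag a single tag sequence.
#' @return `match_known()`: a one-row data.frame, or `NULL` when nothing
#'   qualifies.
#' @export
match_known <- function(tag, mature_db, max_mm = 2L, max_shift = 2L) {
  out <- match_known_all(tag, mature_db, max_mm = max_mm, max_shift = max_shift)
  if (nrow(out) == 0L) NULL else out
}

#' Per-mature and per-family count tables
#'
#' Each tag's per-library counts are credited to exactly one mature miRNA
#' (its best hit); family counts sum member matures.
#'
#' @param hits data.frame from [match_known_all()].
#' @param tag_table unique-tag count table from [collapse_tags()].
#' @return list with `mature` (mature_id, family, one count column per
#'   library) and `family` (family plus count columns) data.frames.
#' @export
family_counts <- function(hits, tag_table) {
  libs <- setdiff(names(tag_table), "seq")
  idx <- match(hits$tag_seq, tag_table$seq)
  if (anyNA(idx)) stop("hit tag absent from tag table", call. = FALSE)
  cnt <- tag_table[idx, libs, drop = FALSE]
  mature <- stats::aggregate(cnt, by = list(
    mature_id = hits$mature_id,
    family = hits$family
  ), FUN = sum)
  family <- stats::aggregate(mature[, libs, drop = FALSE],
    by = list(family = mature$family), FUN = sum
  )
  list(
    mature = mature[order(mature$mature_id), , drop = FALSE],
    family = family[order(family$family), , drop = FALSE]
  )
}

#' Detection summary per library
#'
#' @param mature_table per-mature count table (from
#'   [family_counts()]`$mature`).
#' @param high_count threshold for the high-abundance tally; the tally
#'   counts matures sequenced strictly more than `high_count` times.
#' @return data.frame with one row per library: `detected` (>= 1 read) and
#'   `high_abundance` (> `high_count` reads).
#' @export
detection_summary <- function(mature_table, high_count = 50L) {
  libs <- setdiff(names(mature_table), c("mature_id", "family"))
  data.frame(
    library = libs,
    detected = vapply(libs, function(l) sum(mature_table[[l]] >= 1L), integer(1)),
    high_abundance = vapply(libs, function(l) sum(mature_table[[l]] > high_count), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
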