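# Read cleaning: quality filter, 3' adapter trimming, poly-A stripping,
# length selection, collapse to unique tags, and the per-library
# read-accounting ledger.

#' Trim the 3' adapter from reads
#'
#' Finds, for each read, the leftmost position at which a prefix of the
#' adapter matches the read suffix (minimum overlap `min_overlap` bases,
#' at most one mismatch per ten bases of overlap) and removes everything
#' from that position on. Reads in which no adapter is found are reported
#' as `NA` (the insert extends past the read end and its 3' boundary is
#' unknown); reads matching the adapter from position one yield an empty
#' insert.
#'
#' @param reads character vector of raw read sequences (DNA alphabet).
#' @param adapter3 the 3' adapter sequence (non-empty DNA string).
#' @param min_overlap minimum read/adapter overlap to call a match.
#' @return character vector of trimmed inserts; `NA` where no adapter was
#'   found.
#' @export
trim_adapter <- function(reads, adapter3, min_overlap = 6L) {
  stopifnot(is.character(adapter3), length(adapter3) == 1L, nzchar(adapter3))
  .trim_adapter_cpp(as_dna(reads), as_dna(adapter3), as.integer(min_overlap))
}

# structural FASTQ validation: four lines per record, '@' header, '+'
# separator, sequence and quality of equal length; reports the index of
# the first offending record
.validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  bad_record <- function(rec) {
    stop("malformed FASTQ '", path, "' at record ", rec, call. = FALSE)
  }
  if (n %% 4L != 0L) bad_record(n %/% 4L + 1L)
  if (n == 0L) {
    return(invisible(TRUE))
  }
  rec_start <- seq(1L, n, by = 4L)
  bad <- !startsWith(lines[rec_start], "@") |
    !startsWith(lines[rec_start + 2L], "+") |
    nchar(lines[rec_start + 1L]) != nchar(lines[rec_start + 3L])
  if (any(bad)) bad_record(which(bad)[1L])
  invisible(TRUE)
}

# trailing poly-A run of >= min_run As is removed (degradation/ligation
# artefact); shorter runs are biological signal and kept
strip_polya <- function(seqs, min_run = 6L) {
  sub(sprintf("A{%d,}$", min_run), "", seqs)
}

#' Clean a small RNA library
#'
#' Runs the cleaning cascade on one FASTQ library: (1) quality filter
#' (mean Phred >= `mean_q`, at most `max_n` ambiguous bases), giving the
#' high-quality read set; (2) 3' adapter trimming, discarding reads without
#' a detectable adapter; (3) trailing poly-A stripping; (4) length
#' selection to `[min_len, max_len]`. Survivors are the clean tags.
#'
#' @param fastq path to a FASTQ file (Phred+33), or a
#'   [Biostrings::QualityScaledDNAStringSet].
#' @param adapter3 3' adapter sequence; `NA` if reads are already trimmed.
#' @param min_len,max_len retained insert length bounds (nt).
#' @param mean_q minimum mean Phred quality.
#' @param max_n maximum number of N bases per read.
#' @param strip_polyA whether to strip trailing poly-A runs (>= 6 As)
#'   before the length test.
#' @return a list with `tags` (character vector of clean read sequences,
#'   one entry per surviving read) and `stats`, a list ledger with
#'   `raw_reads`, `high_quality_reads`, `clean_reads` and the per-reason
#'   removal counts (`removed_low_quality`, `removed_no_adapter`,
#'   `removed_short`, `removed_long`).
#' @export
clean_reads <- function(fastq, adapter3, min_len = 18L, max_len = 30L,
                        mean_q = 20, max_n = 1L, strip_polyA = TRUE) {
  if (is.character(fastq)) {
    .validate_fastq(fastq)
    reads <- withCallingHandlers(
      tryCatch(
        Biostrings::readQualityScaledDNAStringSet(fastq),
        error = function(e) {
          stop("malformed FASTQ '", fastq, "': ", conditionMessage(e),
            call. = FALSE
          )
        }
      ),
      # Biostrings emits a cosmetic note about dropped metadata columns
      # while assembling the quality-scaled set
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  } else {
    reads <- fastq
  }
  n_raw <- length(reads)
  if (n_raw == 0L) {
    stats <- list(
      raw_reads = 0L, high_quality_reads = 0L, clean_reads = 0L,
      removed_low_quality = 0L, removed_no_adapter = 0L,
      removed_short = 0L, removed_long = 0L
    )
    return(list(tags = character(0), stats = stats))
  }

  qm <- methods::as(Biostrings::quality(reads), "IntegerList")
  meanq <- as.numeric(sum(qm)) / lengths(qm)
  ncount <- Biostrings::vcountPattern("N", reads, fixed = TRUE)
  hq <- meanq >= mean_q & ncount <= max_n
  seqs <- as.character(reads[hq])
  n_hq <- length(seqs)

  if (!is.na(adapter3)) {
    inserts <- trim_adapter(seqs, adapter3)
    n_no_adapter <- sum(is.na(inserts))
    inserts <- inserts[!is.na(inserts)]
  } else {
    inserts <- seqs
    n_no_adapter <- 0L
  }
  if (strip_polyA) inserts <- strip_polya(inserts)
  len <- nchar(inserts)
  n_short <- sum(len < min_len)
  n_long <- sum(len > max_len)
  tags <- inserts[len >= min_len & len <= max_len]

  stats <- list(
    raw_reads = n_raw,
    high_quality_reads = n_hq,
    clean_reads = length(tags),
    removed_low_quality = n_raw - n_hq,
    removed_no_adapter = n_no_adapter,
    removed_short = n_short,
    removed_long = n_long
  )
  list(tags = tags, stats = stats)
}

#' Collapse clean reads to unique tags with per-library counts
#'
#' @param tag_lists named list, one character vector of clean read
#'   sequences per library.
#' @return data.frame with column `seq` and one integer count column per
#'   library; rows sorted by sequence. Column sums equal the library clean
#'   read totals.
#' @export
collapse_tags <- function(tag_lists) {
  stopifnot(is.list(tag_lists), !is.null(names(tag_lists)))
  all_seq <- sort(unique(unlist(tag_lists, use.names = FALSE)))
  out <- data.frame(seq = all_seq, stringsAsFactors = FALSE)
  for (lib in names(tag_lists)) {
    tb <- table(tag_lists[[lib]])
    cnt <- integer(length(all_seq))
    idx <- match(names(tb), all_seq)
    cnt[idx] <- as.integer(tb)
    out[[lib]] <- cnt
  }
  out
}

#' Length distribution of unique tags
#'
#' @param tag_table data.frame from [collapse_tags()].
#' @param by `"unique"` weights every distinct sequence once; `"total"`
#'   weights by summed read counts across libraries.
#' @param range lengths reported (nt).
#' @return a list with `freq` (named numeric vector over `range`, summing
#'   to one) and `mode` (length with highest mass, `NA` for an empty
#'   table).
#' @export
length_distribution <- function(tag_table, by = c("unique", "total"),
                                range = 18:30) {
  by <- match.arg(by)
  if (nrow(tag_table) == 0L) {
    return(list(freq = stats::setNames(numeric(length(range)), range), mode = NA))
  }
  len <- nchar(tag_table$seq)
  w <- if (by == "unique") {
    rep(1, nrow(tag_table))
  } else {
    rowSums(tag_table[, setdiff(names(tag_table), "seq"), drop = FALSE])
  }
  mass <- vapply(range, function(l) sum(w[len == l]), numeric(1))
  freq <- stats::setNames(mass / sum(w), range)
  list(freq = freq, mode = range[which.max(mass)])
}
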