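# Genome mapping of unique tags and priority-based category assignment:
# rRNA > tRNA > snRNA > snoRNA > miRNA > exon-sense > exon-antisense >
# intron-sense > intron-antisense > unannotated. Each tag gets exactly one
# category, so the categories partition the tag set (the residual class is
# "unannotated").

CATEGORY_LEVELS <- c(
  "rRNA", "tRNA", "snRNA", "snoRNA", "miRNA",
  "exon_sense", "exon_antisense", "intron_sense", "intron_antisense",
  "unannotated"
)

.load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  } else if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Map unique tags to the genome
#'
#' Reports every ungapped alignment of each tag with at most
#' `max_mismatch` substitutions, on both strands. A minus-strand alignment
#' covers the genomic slice whose reverse complement matches the tag.
#' Alignments are ordered by (scaffold, start, strand), plus before minus.
#'
#' @param tags character vector of tag sequences.
#' @param genome [Biostrings::DNAStringSet], named character vector, or
#'   path to a genome FASTA.
#' @param max_mismatch maximum substitutions (no indels).
#' @return data.frame with columns tag_seq, scaffold, start, end (1-based
#'   inclusive), strand, mismatches.
#' @export
map_tags <- function(tags, genome, max_mismatch = 2L) {
  genome <- .load_genome(genome)
  tags <- as_dna(tags)
  raw <- .map_tags_cpp(tags, as.character(genome), as.integer(max_mismatch))
  if (!nrow(raw)) {
    return(data.frame(
      tag_seq = character(0), scaffold = character(0), start = integer(0),
      end = integer(0), strand = character(0), mismatches = integer(0),
      stringsAsFactors = FALSE
    ))
  }
  res <- data.frame(
    tag_seq = tags[raw$tag],
    scaffold = names(genome)[raw$scaffold],
    start = raw$start,
    end = raw$start + nchar(tags[raw$tag]) - 1L,
    strand = c("+", "-")[raw$strand + 1L],
    mismatches = raw$mm,
    stringsAsFactors = FALSE
  )
  res[order(res$scaffold, res$start, res$strand, res$tag_seq), , drop = FALSE]
}

.validate_annotation <- function(annotation) {
  need <- c("scaffold", "start", "end", "strand", "feature")
  if (!all(need %in% names(annotation))) {
    stop("annotation must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(annotation$start > annotation$end) ||
    any(annotation$start < 1L) ||
    !all(annotation$feature %in% c("exon", "intron")) ||
    !all(annotation$strand %in% c("+", "-"))) {
    stop("invalid annotation intervals", call. = FALSE)
  }
  for (sc in unique(annotation$scaffold)) {
    for (strand in c("+", "-")) {
      a <- annotation[annotation$scaffold == sc & annotation$strand == strand, ]
      if (nrow(a) < 2L) next
      ir <- IRanges::IRanges(a$start, a$end)
      if (any(IRanges::countOverlaps(ir, ir) > 1L)) {
        stop("overlapping annotation intervals on ", sc, strand, call. = FALSE)
      }
    }
  }
  invisible(annotation)
}

#' Assign each unique tag to one annotation category
#'
#' Applies the fixed priority rRNA > tRNA > snRNA > snoRNA > miRNA >
#' exon-sense > exon-antisense > intron-sense > intron-antisense >
#' unannotated. ncRNA membership is an exact substring match (either
#' orientation) against the class reference set; miRNA membership is a
#' [match_known_all()] hit with at most `max_mm` substitutions; the exonic
#' and intronic classes come from genome alignments overlapped with the
#' gene annotation, using each tag's best (fewest-mismatch) alignments,
#' sense meaning tag strand equals gene strand. Tags matching nothing are
#' unannotated.
#'
#' @param tag_table data.frame from [collapse_tags()] (or any data.frame
#'   with a `seq` column).
#' @param ncrna_refs named list (`rRNA`, `tRNA`, `snRNA`, `snoRNA`) of
#'   reference sets ([Biostrings::DNAStringSet], character vectors or
#'   FASTA paths).
#' @param annotation gene annotation data.frame with columns scaffold,
#'   start, end, strand, feature (exon/intron) and optionally gene_id.
#' @param mature_db mature miRNA reference (see [read_mature_fasta()]).
#' @param genome genome sequences (see [map_tags()]).
#' @param max_mismatch substitutions allowed in genome mapping.
#' @param max_mm substitutions allowed in the known-miRNA match.
#' @return data.frame with columns seq, category, evidence; the alignment
#'   table is attached as attribute `alignments`.
#' @export
categorize <- function(tag_table, ncrna_refs, annotation, mature_db, genome,
                       max_mismatch = 2L, max_mm = 2L) {
  .validate_annotation(annotation)
  seqs <- as_dna(tag_table$seq)
  category <- rep("unannotated", length(seqs))
  evidence <- rep(NA_character_, length(seqs))

  refs <- lapply(ncrna_refs, function(r) {
    if (is.character(r) && length(r) == 1L && file.exists(r)) {
      Biostrings::readDNAStringSet(r)
    } else {
      Biostrings::DNAStringSet(as_dna(r))
    }
  })
  nc_classes <- intersect(c("rRNA", "tRNA", "snRNA", "snoRNA"), names(refs))
  if (length(nc_classes)) {
    texts <- vapply(refs[nc_classes], function(r) {
      paste(as.character(r), collapse = "N")
    }, character(1))
    cls_idx <- .ref_class_cpp(seqs, texts)
    hit <- cls_idx > 0L
    category[hit] <- nc_classes[cls_idx[hit]]
    evidence[hit] <- nc_classes[cls_idx[hit]]
  }

  todo <- category == "unannotated"
  if (any(todo) && !is.null(mature_db) && nrow(mature_db)) {
    hits <- match_known_all(seqs[todo], mature_db, max_mm = max_mm)
    idx <- match(hits$tag_seq, seqs)
    category[idx] <- "miRNA"
    evidence[idx] <- hits$mature_id
  }

  aln <- map_tags(seqs, genome, max_mismatch = max_mismatch)
  todo <- which(category == "unannotated")
  if (length(todo) && nrow(annotation) && nrow(aln)) {
    aln_rows <- split(seq_len(nrow(aln)), aln$tag_seq)
    ann_by_sc <- split(annotation, annotation$scaffold)
    for (i in todo) {
      rws <- aln_rows[[seqs[i]]]
      if (is.null(rws)) next
      a <- aln[rws, , drop = FALSE]
      a <- a[a$mismatches == min(a$mismatches), , drop = FALSE]
      cats <- character(0)
      for (r in seq_len(nrow(a))) {
        ann_sc <- ann_by_sc[[a$scaffold[r]]]
        if (is.null(ann_sc)) next
        ov <- which(ann_sc$start <= a$end[r] & ann_sc$end >= a$start[r])
        for (k in ov) {
          sense <- ann_sc$strand[k] == a$strand[r]
          cats <- c(cats, paste0(
            ann_sc$feature[k], "_",
            if (sense) "sense" else "antisense"
          ))
        }
      }
      if (length(cats)) {
        best <- CATEGORY_LEVELS[min(match(cats, CATEGORY_LEVELS))]
        category[i] <- best
        evidence[i] <- best
      }
    }
  }

  out <- data.frame(
    seq = seqs, category = factor(category, levels = CATEGORY_LEVELS),
    evidence = evidence, stringsAsFactors = FALSE
  )
  attr(out, "alignments") <- aln
  out
}

#' Per-library category summary
#'
#' @param assignments data.frame from [categorize()].
#' @param tag_table unique-tag count table from [collapse_tags()].
#' @return data.frame in long format: category, library, unique, total,
#'   unique_pct, total_pct. Per library, `unique` sums to the number of
#'   unique tags and `total` to the clean-read count; percentages sum to
#'   100.
#' @export
summarize_categories <- function(assignments, tag_table) {
  libs <- setdiff(names(tag_table), "seq")
  cat_of <- assignments$category[match(as_dna(tag_table$seq), assignments$seq)]
  rows <- list()
  for (lib in libs) {
    cnt <- tag_table[[lib]]
    present <- cnt > 0L
    uniq <- tapply(as.integer(present), cat_of, sum, default = 0L)
    tot <- tapply(cnt, cat_of, sum, default = 0L)
    rows[[lib]] <- data.frame(
      category = CATEGORY_LEVELS,
      library = lib,
      unique = as.integer(uniq[CATEGORY_LEVELS]),
      total = as.integer(tot[CATEGORY_LEVELS]),
      unique_pct = 100 * uniq[CATEGORY_LEVELS] / max(1L, sum(present)),
      total_pct = 100 * tot[CATEGORY_LEVELS] / max(1L, sum(cnt)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
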