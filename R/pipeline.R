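# End-to-end orchestration: simulate (optional) -> clean -> collapse ->
# map/categorize -> known miRNAs -> novel precursors -> differential
# expression -> targets -> report. Every stage writes its table before the
# next starts; a manifest records input hashes and parameters. All genomic
# coordinates are 1-based inclusive throughout.

#' Build and validate a pipeline configuration
#'
#' Either `simulate = TRUE` (a [simulation_design()] drives the run and
#' all inputs are generated) or explicit input paths must be given. Paths
#' are checked at validation time; unknown keys are rejected.
#'
#' @param outdir output directory for stage tables and the report.
#' @param simulate logical; generate inputs with the synthetic module.
#' @param design [simulation_design()] used when `simulate` is TRUE.
#' @param genome,libraries,ncrna,annotation,mature_db,transcripts input
#'   paths for non-simulated runs: genome FASTA; named character vector of
#'   library FASTQ files; named list of ncRNA FASTA paths; annotation TSV;
#'   mature miRNA FASTA; transcript FASTA.
#' @param adapter3 3' adapter (defaults to the design's adapter).
#' @param contrasts list of c(control, treatment) library-name pairs for
#'   differential expression.
#' @param params stage parameter overrides: `min_len`, `max_len`,
#'   `mean_q`, `max_mismatch`, `max_mm`, `p_cut`, `lfc_cut`,
#'   `criteria` (see [precursor_criteria()]).
#' @param seed integer seed for the simulated inputs.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, simulate = TRUE, design = NULL,
                            genome = NULL, libraries = NULL, ncrna = NULL,
                            annotation = NULL, mature_db = NULL,
                            transcripts = NULL, adapter3 = NULL,
                            contrasts = list(c("LC", "LS"), c("RC", "RS")),
                            params = list(), seed = 1L) {
  known_params <- c(
    "min_len", "max_len", "mean_q", "max_mismatch", "max_mm",
    "p_cut", "lfc_cut", "criteria"
  )
  bad <- setdiff(names(params), known_params)
  if (length(bad)) {
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (simulate) {
    if (is.null(design)) design <- simulation_design(seed = seed)
  } else {
    for (p in c(genome, unlist(libraries), unlist(ncrna), annotation, mature_db)) {
      if (!file.exists(p)) stop("input path not found: ", p, call. = FALSE)
    }
    if (is.null(adapter3)) {
      stop("adapter3 required for non-simulated runs", call. = FALSE)
    }
  }
  structure(list(
    outdir = outdir, simulate = simulate, design = design,
    genome = genome, libraries = libraries, ncrna = ncrna,
    annotation = annotation, mature_db = mature_db,
    transcripts = transcripts, adapter3 = adapter3,
    contrasts = contrasts, params = params, seed = as.integer(seed)
  ), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return invisible list bundle with every stage result and the manifest;
#'   stage tables are written under `config$outdir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[mirseq] ", ...)
  pget <- function(name, default) {
    if (is.null(config$params[[name]])) default else config$params[[name]]
  }

  # --- inputs -------------------------------------------------------------
  if (config$simulate) {
    say("simulating inputs")
    datadir <- file.path(out, "data")
    exp <- simulate_experiment(config$design, outdir = datadir)
    genome <- exp$genome
    ncrna <- exp$ncrna
    annotation <- exp$annotation
    mature_db <- data.frame(
      id = exp$planted$id,
      family = sub("[a-z]$", "", exp$planted$id),
      species = "syn",
      seq = exp$planted$mature_seq, stringsAsFactors = FALSE
    )
    fastqs <- stats::setNames(
      file.path(datadir, paste0(config$design$libraries$name, ".fastq")),
      config$design$libraries$name
    )
    transcripts <- exp$transcriptome$transcripts
    adapter3 <- config$design$adapter3
  } else {
    genome <- .load_genome(config$genome)
    ncrna <- config$ncrna
    annotation <- utils::read.delim(config$annotation, stringsAsFactors = FALSE)
    mature_db <- read_mature_fasta(config$mature_db)
    fastqs <- config$libraries
    transcripts <- config$transcripts
    adapter3 <- config$adapter3
    exp <- NULL
  }

  # --- clean + collapse ---------------------------------------------------
  say("cleaning reads")
  tag_lists <- list()
  stats_ledger <- list()
  for (lib in names(fastqs)) {
    cl <- clean_reads(fastqs[[lib]], adapter3,
      min_len = pget("min_len", 18L), max_len = pget("max_len", 30L),
      mean_q = pget("mean_q", 20)
    )
    tag_lists[[lib]] <- cl$tags
    stats_ledger[[lib]] <- cl$stats
  }
  tag_table <- collapse_tags(tag_lists)
  .write_tsv(tag_table, file.path(out, "tags.tsv"))

  # --- categorize ---------------------------------------------------------
  say("mapping and categorizing ", nrow(tag_table), " unique tags")
  assignments <- categorize(
    tag_table, ncrna, annotation, mature_db, genome,
    max_mismatch = pget("max_mismatch", 2L), max_mm = pget("max_mm", 2L)
  )
  alignments <- attr(assignments, "alignments")
  .write_tsv(assignments, file.path(out, "categories.tsv"))
  category_summary <- summarize_categories(assignments, tag_table)
  .write_tsv(category_summary, file.path(out, "category_summary.tsv"))

  for (lib in names(fastqs)) {
    present <- tag_table[[lib]] > 0L
    mapped <- as_dna(tag_table$seq) %in% alignments$tag_seq
    stats_ledger[[lib]]$unique_tags <- sum(present)
    stats_ledger[[lib]]$mapped_unique <- sum(present & mapped)
    stats_ledger[[lib]]$mapped_total <- sum(tag_table[[lib]][mapped])
  }
  jsonlite::write_json(stats_ledger, file.path(out, "library_stats.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  # --- known miRNAs -------------------------------------------------------
  say("known miRNA identification")
  mir_tags <- assignments$seq[assignments$category == "miRNA"]
  hits <- match_known_all(mir_tags, mature_db, max_mm = pget("max_mm", 2L))
  counts <- family_counts(hits, tag_table)
  .write_tsv(counts$mature, file.path(out, "known_mature_counts.tsv"))
  .write_tsv(counts$family, file.path(out, "known_family_counts.tsv"))
  detection <- detection_summary(counts$mature)
  .write_tsv(detection, file.path(out, "known_detection.tsv"))

  # --- novel precursors ---------------------------------------------------
  say("novel precursor calling")
  un_tags <- assignments$seq[assignments$category == "unannotated"]
  un_aln <- alignments[alignments$tag_seq %in% un_tags, , drop = FALSE]
  un_aln$count <- rowSums(
    tag_table[match(un_aln$tag_seq, as_dna(tag_table$seq)),
      setdiff(names(tag_table), "seq"),
      drop = FALSE
    ]
  )
  windows <- extract_candidate_loci(
    un_aln,
    scaffold_lengths = stats::setNames(Biostrings::width(genome), names(genome))
  )
  tags_by_window <- lapply(seq_len(nrow(windows)), function(k) {
    w <- windows[k, ]
    sel <- un_aln$scaffold == w$scaffold & un_aln$start >= w$start &
      un_aln$end <= w$end
    a <- un_aln[sel, , drop = FALSE]
    s <- a$tag_seq
    neg <- w$strand == "-"
    if (neg) s <- revcomp(s)
    data.frame(seq = s, count = a$count, stringsAsFactors = FALSE)
  })
  novel <- call_precursors(
    windows, genome, tags_by_window,
    criteria = pget("criteria", precursor_criteria())
  )
  .write_tsv(novel$candidates, file.path(out, "novel_candidates.tsv"))
  nt_bias <- first_nt_bias(novel$candidates$mature_seq)

  # --- differential expression -------------------------------------------
  say("differential expression")
  de <- list()
  clean_totals <- vapply(stats_ledger, function(s) s$clean_reads, numeric(1))
  for (ct in config$contrasts) {
    ctrl <- ct[1L]
    trt <- ct[2L]
    if (!all(c(ctrl, trt) %in% names(counts$mature))) next
    rec <- expression_records(
      stats::setNames(
        counts$mature[c("mature_id", ctrl, trt)],
        c("id", ctrl, trt)
      ),
      ctrl, trt,
      N1 = clean_totals[[ctrl]], N2 = clean_totals[[trt]]
    )
    rec <- call_de(rec, p_cut = pget("p_cut", 0.01), lfc_cut = pget("lfc_cut", 1))
    key <- paste0(ctrl, "_vs_", trt)
    de[[key]] <- rec
    .write_tsv(rec, file.path(out, paste0("diffexpr_", key, ".tsv")))
  }

  # --- targets ------------------------------------------------------------
  targets <- NULL
  if (!is.null(transcripts)) {
    say("target scanning")
    targets <- scan_transcripts(
      stats::setNames(mature_db$seq, mature_db$id), transcripts
    )
    .write_tsv(targets, file.path(out, "targets.tsv"))
  }

  bundle <- list(
    config = config, stats = stats_ledger, tag_table = tag_table,
    assignments = assignments, category_summary = category_summary,
    known = counts, detection = detection,
    novel = novel, first_nt_bias = nt_bias,
    de = de, targets = targets, experiment = exp
  )

  # --- report + manifest --------------------------------------------------
  report <- make_report(bundle)
  writeLines(report, file.path(out, "report.md"))
  tsvs <- list.files(out, pattern = "\\.(tsv|json|md)$", full.names = TRUE)
  manifest <- list(
    files = lapply(
      stats::setNames(tsvs, basename(tsvs)),
      function(f) unname(tools::md5sum(f))
    ),
    seed = config$seed,
    params = config$params
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  bundle$manifest <- manifest
  say("done")
  invisible(bundle)
}

#' Render the summary report
#'
#' Assembles the library-statistics, category-partition, known-miRNA,
#' novel-candidate and target tables into a markdown document. Every
#' number is taken from the stage outputs; nothing is recomputed.
#'
#' @param bundle result of [run_pipeline()].
#' @return character vector of report lines.
#' @export
make_report <- function(bundle) {
  fmt_tbl <- function(df, digits = 3) {
    if (is.null(df) || !nrow(df)) {
      return("(none)")
    }
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, digits))
    c(
      paste(names(df), collapse = "\t"),
      apply(df, 1L, paste, collapse = "\t")
    )
  }
  stats_df <- do.call(rbind, lapply(names(bundle$stats), function(lib) {
    s <- bundle$stats[[lib]]
    data.frame(
      library = lib, raw = s$raw_reads, high_quality = s$high_quality_reads,
      clean = s$clean_reads, unique = s$unique_tags,
      mapped_total = s$mapped_total, mapped_unique = s$mapped_unique,
      stringsAsFactors = FALSE
    )
  }))
  c(
    "# small RNA pipeline report",
    "", "## Library statistics", fmt_tbl(stats_df),
    "", "## Category partition", fmt_tbl(bundle$category_summary),
    "", "## Known miRNA counts", fmt_tbl(bundle$known$mature),
    "", "## Detection summary", fmt_tbl(bundle$detection),
    "", "## Novel precursor candidates", fmt_tbl(bundle$novel$candidates),
    "", "## First-nucleotide bias of novel matures",
    paste(names(bundle$first_nt_bias),
      round(bundle$first_nt_bias, 3),
      sep = "=", collapse = "  "
    ),
    "", unlist(lapply(names(bundle$de), function(k) {
      rec <- bundle$de[[k]]
      c(
        paste0("## Differential expression ", k),
        paste0(
          "significant=", attr(rec, "n_significant"),
          " up=", attr(rec, "n_up"), " down=", attr(rec, "n_down")
        ),
        fmt_tbl(rec)
      )
    })),
    "", "## Targets", fmt_tbl(bundle$targets)
  )
}
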