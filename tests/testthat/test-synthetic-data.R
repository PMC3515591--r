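# The synthetic experiment generator: genome construction, hairpin
# planting, library simulation and design bookkeeping.

test_that("zero scaffolds give an empty genome without error", {
  d <- tiny_design()
  d$n_scaffolds <- 0L
  expect_equal(length(generate_genome(d)), 0L)
})

test_that("the genome is deterministic under a fixed seed", {
  d <- tiny_design(seed = 7)
  g1 <- generate_genome(d)
  g2 <- generate_genome(d)
  expect_identical(as.character(g1), as.character(g2))
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(g1, f1)
  Biostrings::writeXStringSet(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("scaffolds have the designed number, length and alphabet", {
  d <- tiny_design()
  d$n_scaffolds <- 2L
  d$scaffold_length <- 50000L
  g <- generate_genome(d)
  expect_equal(length(g), 2L)
  expect_equal(names(g), c("scaffold_1", "scaffold_2"))
  expect_true(all(Biostrings::width(g) == 50000L))
  freq <- Biostrings::alphabetFrequency(g)
  expect_equal(sum(freq[, c("A", "C", "G", "T")]), 100000)
})

test_that("invalid design dimensions are rejected", {
  expect_error(simulation_design(scaffold_length = -5), "positive")
  expect_error(simulation_design(scaffold_length = 1000), "10x")
  expect_error(simulation_design(mirna_fraction = 1.2), "fractions")
})

test_that("planted precursors sit at their stated loci on both strands", {
  d <- tiny_design(seed = 37, n_mirnas = 10)
  g <- generate_genome(d)
  ph <- plant_hairpins(g, d)
  gs <- as.character(ph$genome)
  for (i in seq_len(nrow(ph$planted))) {
    p <- ph$planted[i, ]
    slice <- substr(gs[[p$scaffold]], p$start, p$end)
    if (p$strand == "+") {
      expect_equal(slice, p$precursor_seq)
    } else {
      expect_equal(revcomp(slice), p$precursor_seq)
    }
    expect_true(grepl(p$mature_seq, p$precursor_seq, fixed = TRUE))
    expect_gte(nchar(p$precursor_seq), 70L)
    expect_lte(nchar(p$precursor_seq), 365L)
  }
  # loci non-overlapping
  for (sc in unique(ph$planted$scaffold)) {
    p <- ph$planted[ph$planted$scaffold == sc, ]
    ir <- IRanges::IRanges(p$start, p$end)
    expect_true(all(IRanges::countOverlaps(ir, ir) == 1L))
  }
})

test_that("every planted precursor passes the precursor caller", {
  d <- tiny_design(seed = 41, n_mirnas = 10)
  g <- generate_genome(d)
  ph <- plant_hairpins(g, d)
  ok <- vapply(seq_len(nrow(ph$planted)), function(i) {
    p <- ph$planted[i, ]
    call_precursor(
      list(seq = p$precursor_seq, scaffold = p$scaffold, start = p$start, end = p$end, strand = p$strand),
      data.frame(seq = p$mature_seq, count = 10L)
    )$accepted
  }, logical(1))
  expect_true(all(ok))
})

test_that("expected class proportions sum to one before sampling", {
  d <- tiny_design(seed = 43, n_mirnas = 8)
  g <- generate_genome(d)
  ph <- plant_hairpins(g, d)
  ce <- category_expectations(ph$planted, d)
  expect_true(all(abs(colSums(ce) - 1) < 1e-9))
  expect_true(all(ce >= 0))
})

test_that("a degenerate pure-miRNA mixture yields only the mature sequence", {
  d <- simulation_design(
    n_mirnas = 1L,
    libraries = data.frame(
      name = "L1", condition = "control", tissue = "leaf",
      total_reads = 300, stringsAsFactors = FALSE
    ),
    mirna_fraction = 1,
    contaminant_fraction = c(
      rRNA = 0, tRNA = 0, snRNA = 0, snoRNA = 0, exonic = 0, intronic = 0
    ),
    low_quality_fraction = 0, short_fraction = 0,
    seed = 47
  )
  g <- generate_genome(d)
  ph <- plant_hairpins(g, d)
  sim <- simulate_libraries(ph$planted, d, ph$genome, make_ncrna_refs(d), NULL)
  r <- sim$reads$L1
  qs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(r$seq), Biostrings::PhredQuality(r$qual)
  )
  tags <- clean_reads(qs, d$adapter3)$tags
  expect_gt(length(tags), 0L)
  expect_true(all(tags == ph$planted$mature_seq))
})

test_that("simulated libraries are deterministic and sized to design", {
  d <- tiny_design(seed = 53, n_mirnas = 5, total_reads = 1000)
  e1 <- simulate_experiment(d)
  e2 <- simulate_experiment(d)
  expect_identical(e1$sim$reads$LC$seq, e2$sim$reads$LC$seq)
  expect_identical(e1$sim$reads$LC$qual, e2$sim$reads$LC$qual)
  expect_identical(e1$sim$truth$mirna_counts, e2$sim$truth$mirna_counts)
  n <- length(e1$sim$reads$LC$seq)
  expect_gt(n, 800)
  expect_lt(n, 1200)
})

test_that("miRNA-derived clean reads keep the planted mature length mode", {
  d <- tiny_design(seed = 59, n_mirnas = 8, total_reads = 3000)
  exp <- simulate_experiment(d)
  r <- exp$sim$reads$LC
  qs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(r$seq), Biostrings::PhredQuality(r$qual)
  )
  tags <- clean_reads(qs, d$adapter3)$tags
  mir_tags <- tags[tags %in% exp$planted$mature_seq]
  planted_mode <- as.integer(names(which.max(table(nchar(
    rep(exp$planted$mature_seq, exp$sim$truth$mirna_counts[, "LC"])
  )))))
  got_mode <- as.integer(names(which.max(table(nchar(mir_tags)))))
  expect_equal(got_mode, planted_mode)
})

test_that("the designed fold change is recovered for an abundant miRNA", {
  # one high-abundance miRNA with lfc 1.0 in leaf; Monte-Carlo over seeds
  errs <- vapply(1:20, function(s) {
    d <- tiny_design(seed = 600 + s, n_mirnas = 4, total_reads = 1e5)
    g <- generate_genome(d)
    ph <- plant_hairpins(g, d)
    ph$planted$tpm_control[1] <- 5000
    ph$planted$lfc_leaf[1] <- 1.0
    tpm_mat <- design_tpm_matrix(ph$planted, d)
    set.seed(6000 + s)
    x <- rpois(1, tpm_mat[1, "LC"] * 1e5 / 1e6)
    y <- rpois(1, tpm_mat[1, "LS"] * 1e5 / 1e6)
    log2fc(tpm(y, 1e5), tpm(x, 1e5)) - 1.0
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.2)
})

test_that("planted target sites reproduce their mismatch plans", {
  d <- tiny_design(seed = 61, n_mirnas = 4)
  g <- generate_genome(d)
  ph <- plant_hairpins(g, d)
  plan <- data.frame(
    total_mm = c(0, 1, 4), n_gu = c(0, 0, 2),
    positions = c("", "10", "1,5,15,20"), stringsAsFactors = FALSE
  )
  tx <- make_transcriptome(ph$planted, n_targets = 6, mismatch_plan = plan, seed = 71)
  for (k in seq_len(nrow(tx$truth))) {
    tr <- tx$truth[k, ]
    win <- substr(as.character(tx$transcripts[[tr$transcript]]), tr$start, tr$end)
    aln <- align_site(tr$mature_seq, win)
    expect_equal(paste(aln$states, collapse = ""), tr$states)
  }
  # plan row 1: exact reverse complement
  tr1 <- tx$truth[1, ]
  win1 <- substr(as.character(tx$transcripts[[tr1$transcript]]), tr1$start, tr1$end)
  expect_equal(win1, revcomp(as_dna(tr1$mature_seq)))
  # plan row 2: single mismatch at position 10 must be rejected
  tr2 <- tx$truth[2, ]
  expect_equal(accept_target(seq_chars(tr2$states))$reason, "position_10_11")
})
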