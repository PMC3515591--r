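# Candidate window extraction and hairpin precursor calling.

test_that("a single alignment expands to a flanked window", {
  aln <- data.frame(
    tag_seq = strrep("A", 21), scaffold = "scaffold_1",
    start = 1000L, end = 1020L, strand = "+", mismatches = 0L,
    stringsAsFactors = FALSE
  )
  w <- extract_candidate_loci(aln)
  expect_equal(nrow(w), 1L)
  expect_equal(w$start, 800L)
  expect_equal(w$end, 1220L)
  expect_equal(w$strand, "+")
})

test_that("nearby alignments merge into one window", {
  aln <- data.frame(
    tag_seq = c(strrep("A", 21), strrep("C", 21)), scaffold = "scaffold_1",
    start = c(1000L, 1031L), end = c(1020L, 1051L),
    strand = c("+", "+"), mismatches = 0L, stringsAsFactors = FALSE
  )
  w <- extract_candidate_loci(aln, merge_gap = 30L)
  expect_equal(nrow(w), 1L)
  expect_equal(w$start, 800L)
  expect_equal(w$end, 1251L)
  # beyond the merge gap: two windows
  aln$start[2] <- 1100L
  aln$end[2] <- 1120L
  w2 <- extract_candidate_loci(aln, merge_gap = 30L)
  expect_equal(nrow(w2), 2L)
})

test_that("windows are clipped at scaffold bounds", {
  aln <- data.frame(
    tag_seq = strrep("A", 21), scaffold = "scaffold_1",
    start = 50L, end = 70L, strand = "+", mismatches = 0L,
    stringsAsFactors = FALSE
  )
  w <- extract_candidate_loci(aln, scaffold_lengths = c(scaffold_1 = 150L))
  expect_equal(w$start, 1L)
  expect_equal(w$end, 150L)
})

test_that("window strand follows the weighted majority of its alignments", {
  aln <- data.frame(
    tag_seq = c(strrep("A", 21), strrep("C", 21)), scaffold = "scaffold_1",
    start = c(1000L, 1010L), end = c(1020L, 1030L),
    strand = c("+", "-"), mismatches = 0L,
    count = c(2L, 10L), stringsAsFactors = FALSE
  )
  expect_equal(extract_candidate_loci(aln)$strand, "-")
})

test_that("planted hairpins are accepted with loci matching the truth", {
  d <- tiny_design(seed = 23, n_mirnas = 12)
  g <- generate_genome(d)
  ph <- plant_hairpins(g, d)
  gs <- as.character(ph$genome)
  for (i in seq_len(nrow(ph$planted))) {
    p <- ph$planted[i, ]
    ws <- max(1L, p$start - 200L)
    we <- min(nchar(gs[[p$scaffold]]), p$end + 200L)
    slice <- substr(gs[[p$scaffold]], ws, we)
    wseq <- if (p$strand == "-") revcomp(slice) else slice
    call <- call_precursor(
      list(seq = wseq, scaffold = p$scaffold, start = ws, we = we, end = we, strand = p$strand),
      data.frame(seq = p$mature_seq, count = 50L)
    )
    expect_true(call$accepted)
    ov <- min(call$locus$end, p$end) - max(call$locus$start, p$start) + 1L
    expect_gt(ov / (p$end - p$start + 1L), 0.8)
    expect_true(call$mature_seq == p$mature_seq)
    expect_lte(call$mfe, -18)
    expect_gte(nchar(call$precursor_seq), 70L)
  }
})

test_that("random windows are overwhelmingly rejected", {
  set.seed(77)
  rejected <- 0L
  n <- 40L
  for (i in seq_len(n)) {
    w <- random_rna(440, c("A", "C", "G", "T"))
    tag <- substr(w, 210, 230)
    call <- call_precursor(
      list(seq = w, scaffold = "s", start = 1L, end = 440L, strand = "+"),
      data.frame(seq = tag, count = 10L)
    )
    if (!call$accepted) rejected <- rejected + 1L
  }
  expect_gte(rejected / n, 0.95)
})

test_that("an accepted candidate satisfies every criterion when re-checked", {
  d <- tiny_design(seed = 29, n_mirnas = 6)
  g <- generate_genome(d)
  ph <- plant_hairpins(g, d)
  crit <- precursor_criteria()
  for (i in seq_len(nrow(ph$planted))) {
    p <- ph$planted[i, ]
    call <- call_precursor(
      list(seq = p$precursor_seq, scaffold = p$scaffold, start = p$start, end = p$end, strand = p$strand),
      data.frame(seq = p$mature_seq, count = 9L)
    )
    expect_true(call$accepted)
    # independent re-check from the reported structure
    pt <- pair_table(call$structure)
    idx <- call$mature_start:call$mature_end
    paired <- idx[pt[idx] > 0]
    expect_gte(length(paired), crit$mature_min_paired)
    expect_lte(length(idx) - length(paired), crit$max_unpaired_mature)
    expect_true(all(pt[paired] > max(idx)) || all(pt[paired] < min(idx)))
    expect_lte(structure_energy(call$precursor_seq, call$structure), crit$mfe_max)
    expect_true(nchar(call$precursor_seq) >= crit$min_len &&
      nchar(call$precursor_seq) <= crit$max_len)
  }
})

test_that("a sub-70-nt hairpin is rejected for length", {
  # perfect 25-bp stem with a 12-nt loop: 62 nt, structurally ideal
  stem <- "GCAGCGAAGCGAGACGAAGCGGAGC"
  loop <- "AACCAAUUCCAA"
  hp <- paste0(stem, loop, revcomp(stem))
  expect_lt(nchar(hp), 70)
  call <- call_precursor(
    list(seq = hp, scaffold = "s", start = 1L, end = nchar(hp), strand = "+"),
    data.frame(seq = substr(hp, 1, 21), count = 5L)
  )
  expect_false(call$accepted)
  expect_equal(call$reason, "length")
})

test_that("a window with no usable supporting tag reports no_mature", {
  call <- call_precursor(
    list(seq = random_rna(200), scaffold = "s", start = 1L, end = 200L, strand = "+"),
    data.frame(seq = character(0), count = integer(0))
  )
  expect_equal(call$reason, "no_mature")
  call2 <- call_precursor(
    list(seq = strrep("A", 200), scaffold = "s", start = 1L, end = 200L, strand = "+"),
    data.frame(seq = strrep("C", 21), count = 3L) # tag absent from window
  )
  expect_equal(call2$reason, "no_mature")
})

test_that("first-nucleotide bias fractions are well-formed", {
  expect_equal(unname(first_nt_bias(c("UAG", "UUA", "UGC"))[["U"]]), 1)
  mix <- c(rep("UAAGG", 47), rep("AUUCC", 53))
  fr <- first_nt_bias(mix)
  expect_equal(unname(fr[["U"]]), 0.47)
  expect_equal(sum(fr), 1)
  expect_true(all(is.na(first_nt_bias(character(0)))))
})
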