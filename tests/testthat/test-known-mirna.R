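# Known miRNA identification and per-family counting.

# a small miRBase-style reference; miR156 carries its canonical mature
# sequence
.mature_db <- function() {
  data.frame(
    id = c(
      "miR156", "miR159", "miR166", "miR168", "miR172",
      "miR390", "miR395", "miR408", "miR444", "miR535"
    ),
    family = c(
      "miR156", "miR159", "miR166", "miR168", "miR172",
      "miR390", "miR395", "miR408", "miR444", "miR535"
    ),
    species = "ppe",
    seq = as_dna(c(
      "UGACAGAAGAGAGUGAGCAC", "UUUGGAUUGAAGGGAGCUCUA",
      "UCGGACCAGGCUUCAUUCCCC", "UCGCUUGGUGCAGGUCGGGAA",
      "AGAAUCUUGAUGAUGCUGCAU", "AAGCUCAGGAGGGAUAGCGCC",
      "CUGAAGUGUUUGGGGGAACUC", "ACAGGGAACAGGUAGAGCAUG",
      "GGUUGUCUCAAGAUUGUCUCC", "UGACGACGAGAGAGAGCACGC"
    )),
    stringsAsFactors = FALSE
  )
}

test_that("the canonical miR156 mature sequence is an exact hit", {
  hit <- match_known("UGACAGAAGAGAGUGAGCAC", .mature_db())
  expect_equal(hit$mature_id, "miR156")
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$offset, 0L)
})

test_that("a tag with three substitutions against every entry finds nothing", {
  tag <- as_dna("UGACAGAAGAGAGUGAGCAC")
  tc <- strsplit(tag, "")[[1]]
  tc[c(2, 9, 16)] <- c("C", "C", "G") # three substitutions vs miR156
  mutated <- paste(tc, collapse = "")
  # ensure it is also far from every other entry, then expect no hit
  hit <- match_known(mutated, .mature_db()[1, , drop = FALSE])
  expect_null(hit)
})

test_that("match_known equals an exhaustive offset-scan oracle", {
  db <- .mature_db()
  oracle <- function(tag, max_mm = 2L, max_shift = 2L) {
    best <- NULL
    tc <- strsplit(as_dna(tag), "")[[1]]
    for (r in seq_len(nrow(db))) {
      mc <- strsplit(db$seq[r], "")[[1]]
      for (o in (-max_shift):max_shift) {
        idx <- seq_along(tc)
        keep <- idx + o >= 1 & idx + o <= length(mc)
        if (!any(keep)) next
        if (abs(o) > max_shift || abs(length(mc) - o - length(tc)) > max_shift) next
        mm <- sum(tc[keep] != mc[idx[keep] + o])
        if (mm > max_mm) next
        cand <- list(id = db$id[r], mm = mm, o = o)
        if (is.null(best) || cand$mm < best$mm ||
          (cand$mm == best$mm && abs(cand$o) < abs(best$o)) ||
          (cand$mm == best$mm && abs(cand$o) == abs(best$o) && cand$id < best$id)) {
          best <- cand
        }
      }
    }
    best
  }
  set.seed(51)
  for (i in 1:60) {
    base <- db$seq[sample(nrow(db), 1)]
    tc <- strsplit(base, "")[[1]]
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      p <- sample(length(tc), nmut)
      tc[p] <- sample(c("A", "C", "G", "T"), nmut, TRUE)
    }
    # random end shifts
    tag <- paste(tc, collapse = "")
    if (i %% 3 == 0) tag <- substr(tag, 2, nchar(tag))
    if (i %% 5 == 0) tag <- paste0(tag, sample(c("A", "C", "G", "T"), 1))
    got <- match_known(tag, db)
    want <- oracle(tag)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$mature_id, want$id)
      expect_equal(got$mismatches, want$mm)
      expect_equal(got$offset, want$o)
    }
  }
})

test_that("family counts credit each tag once and sum over members", {
  db <- data.frame(
    id = c("miR9001a", "miR9001b", "miR9002"),
    family = c("miR9001", "miR9001", "miR9002"),
    species = "syn",
    seq = c(strrep("AC", 10), paste0(strrep("AC", 9), "GT"), strrep("GT", 10)),
    stringsAsFactors = FALSE
  )
  tag_table <- data.frame(
    seq = c(db$seq[1], db$seq[2], db$seq[3]),
    LC = c(10L, 5L, 2L), LS = c(0L, 1L, 7L), stringsAsFactors = FALSE
  )
  hits <- match_known_all(tag_table$seq, db, max_mm = 0L)
  fc <- family_counts(hits, tag_table)
  expect_equal(sum(fc$mature$LC), sum(tag_table$LC))
  expect_equal(fc$family$LC[fc$family$family == "miR9001"], 15L)
  expect_equal(fc$family$LS[fc$family$family == "miR9001"], 1L)
  expect_equal(fc$family$LS[fc$family$family == "miR9002"], 7L)
})

test_that("recovered per-mature counts track the generator truth", {
  d <- tiny_design(seed = 13, n_mirnas = 5, total_reads = 4000)
  exp <- simulate_experiment(d)
  db <- data.frame(
    id = exp$planted$id, family = exp$planted$id, species = "syn",
    seq = exp$planted$mature_seq, stringsAsFactors = FALSE
  )
  tl <- list()
  for (lib in c("LC", "LS")) {
    r <- exp$sim$reads[[lib]]
    qs <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(r$seq), Biostrings::PhredQuality(r$qual)
    )
    tl[[lib]] <- clean_reads(qs, d$adapter3)$tags
  }
  tab <- collapse_tags(tl)
  hits <- match_known_all(tab$seq, db)
  fc <- family_counts(hits, tab)
  truth <- exp$sim$truth$mirna_counts
  for (lib in c("LC", "LS")) {
    got <- fc$mature[[lib]][match(rownames(truth), fc$mature$mature_id)]
    got[is.na(got)] <- 0L
    # recovered counts within Poisson noise of the sampled truth
    expect_true(all(abs(got - truth[, lib]) <= 4 * sqrt(truth[, lib] + 1) + 3))
  }
})

test_that("detection summary applies the strict >50 threshold", {
  tab <- data.frame(
    mature_id = c("a", "b", "c"), family = c("a", "b", "c"),
    LC = c(60L, 50L, 1L), stringsAsFactors = FALSE
  )
  ds <- detection_summary(tab)
  expect_equal(ds$detected, 3L)
  expect_equal(ds$high_abundance, 1L)
  # invariant to row order
  ds2 <- detection_summary(tab[c(3, 1, 2), ])
  expect_equal(ds2$detected, ds$detected)
  expect_equal(ds2$high_abundance, ds$high_abundance)
})

test_that("an all-zero count table summarises to zero", {
  tab <- data.frame(
    mature_id = "a", family = "a", LC = 0L, LS = 0L,
    stringsAsFactors = FALSE
  )
  ds <- detection_summary(tab)
  expect_equal(ds$detected, c(0L, 0L))
  expect_equal(ds$high_abundance, c(0L, 0L))
})
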