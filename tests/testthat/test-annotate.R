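# Genome mapping and category assignment.

test_that("a tag equal to a genome slice maps exactly on the plus strand", {
  set.seed(21)
  g <- Biostrings::DNAStringSet(c(scaffold_1 = random_rna(500, c("A", "C", "G", "T"))))
  tag <- substr(as.character(g[[1]]), 101, 121)
  m <- map_tags(tag, g, max_mismatch = 0)
  expect_true(any(m$start == 101 & m$strand == "+" & m$mismatches == 0))
})

test_that("a tag matching the reverse complement maps on the minus strand over the slice", {
  set.seed(22)
  g <- Biostrings::DNAStringSet(c(scaffold_1 = random_rna(500, c("A", "C", "G", "T"))))
  slice <- substr(as.character(g[[1]]), 201, 222)
  m <- map_tags(revcomp(slice), g, max_mismatch = 0)
  hit <- m[m$strand == "-", ]
  expect_true(any(hit$start == 201 & hit$end == 222))
})

test_that("map_tags equals the brute-force sliding-window scan", {
  set.seed(23)
  gseq <- random_rna(1000, c("A", "C", "G", "T"))
  g <- Biostrings::DNAStringSet(c(scaffold_1 = gseq))
  gch <- strsplit(gseq, "")[[1]]
  brute <- function(tag, maxmm) {
    L <- nchar(tag)
    out <- list()
    for (strand in c("+", "-")) {
      pc <- strsplit(if (strand == "+") tag else revcomp(tag), "")[[1]]
      for (s in 1:(1000 - L + 1)) {
        mm <- sum(gch[s:(s + L - 1)] != pc)
        if (mm <= maxmm) {
          out[[length(out) + 1]] <- data.frame(start = s, strand = strand, mm = mm)
        }
      }
    }
    if (!length(out)) {
      return(data.frame(start = integer(0), strand = character(0), mm = integer(0)))
    }
    b <- do.call(rbind, out)
    b[order(b$start, b$strand), ]
  }
  for (i in 1:20) {
    st <- sample(970, 1)
    tag <- substr(gseq, st, st + 20)
    if (i %% 2 == 0) {
      tc <- strsplit(tag, "")[[1]]
      p <- sample(21, sample(1:2, 1))
      tc[p] <- sample(c("A", "C", "G", "T"), length(p), TRUE)
      tag <- paste(tc, collapse = "")
    }
    m <- map_tags(tag, g, max_mismatch = 2)
    b <- brute(tag, 2)
    expect_equal(nrow(m), nrow(b))
    expect_equal(m$start, b$start)
    expect_equal(m$strand, b$strand)
    expect_equal(m$mismatches, b$mm)
  }
})

# shared fixture: tiny genome with one gene and references
.fixture <- function() {
  set.seed(31)
  gseq <- random_rna(2000, c("A", "C", "G", "T"))
  exon <- substr(gseq, 1001, 1200)
  intron <- substr(gseq, 1201, 1400)
  ann <- data.frame(
    scaffold = "scaffold_1",
    start = c(1001L, 1201L, 1401L), end = c(1200L, 1400L, 1600L),
    strand = "+", feature = c("exon", "intron", "exon"),
    gene_id = "g1", stringsAsFactors = FALSE
  )
  mature <- random_rna(21, c("A", "C", "G", "T"))
  list(
    genome = Biostrings::DNAStringSet(c(scaffold_1 = gseq)),
    ann = ann,
    ncrna = list(
      rRNA = paste0(random_rna(100, c("A", "C", "G", "T")), mature,
        random_rna(100, c("A", "C", "G", "T"))),
      tRNA = random_rna(75, c("A", "C", "G", "T")),
      snRNA = random_rna(150, c("A", "C", "G", "T")),
      snoRNA = random_rna(100, c("A", "C", "G", "T"))
    ),
    mature_db = data.frame(
      id = "syn-miR001", family = "miR001", species = "syn",
      seq = mature, stringsAsFactors = FALSE
    ),
    exon = exon, intron = intron
  )
}

test_that("a tag matching both rRNA and a mature miRNA is assigned rRNA", {
  fx <- .fixture()
  tags <- data.frame(seq = fx$mature_db$seq, stringsAsFactors = FALSE)
  out <- categorize(tags, fx$ncrna, fx$ann, fx$mature_db, fx$genome)
  expect_equal(as.character(out$category), "rRNA")
})

test_that("a tag overlapping an exon on the opposite strand is exon-antisense", {
  fx <- .fixture()
  tag <- revcomp(substr(fx$exon, 50, 71)) # antisense of a + strand exon
  out <- categorize(
    data.frame(seq = tag), fx$ncrna, fx$ann,
    fx$mature_db[0, ], fx$genome
  )
  expect_equal(as.character(out$category), "exon_antisense")
  tag_s <- substr(fx$intron, 50, 71)
  out2 <- categorize(
    data.frame(seq = tag_s), fx$ncrna, fx$ann,
    fx$mature_db[0, ], fx$genome
  )
  expect_equal(as.character(out2$category), "intron_sense")
})

test_that("invalid or overlapping annotation intervals raise an error", {
  fx <- .fixture()
  bad <- fx$ann
  bad$start[2] <- 1100L # overlaps the first exon
  expect_error(
    categorize(data.frame(seq = strrep("A", 20)), fx$ncrna, bad,
      fx$mature_db, fx$genome),
    "overlapping"
  )
  bad2 <- fx$ann
  bad2$end[1] <- 900L
  expect_error(
    categorize(data.frame(seq = strrep("A", 20)), fx$ncrna, bad2,
      fx$mature_db, fx$genome),
    "invalid"
  )
})

test_that("planted mature tags are categorized miRNA against the truth table", {
  d <- tiny_design(seed = 8, n_mirnas = 10)
  g <- generate_genome(d)
  ph <- plant_hairpins(g, d)
  mature_db <- data.frame(
    id = ph$planted$id, family = ph$planted$id, species = "syn",
    seq = ph$planted$mature_seq, stringsAsFactors = FALSE
  )
  ncrna <- make_ncrna_refs(d)
  ann <- make_annotation(ph$genome, ph$planted, d)
  out <- categorize(
    data.frame(seq = ph$planted$mature_seq), ncrna, ann,
    mature_db, ph$genome
  )
  expect_gte(mean(out$category == "miRNA"), 0.99)
})

test_that("category summary partitions unique and total counts", {
  fx <- .fixture()
  tag_mir <- fx$mature_db$seq
  tag_ex <- substr(fx$exon, 10, 31)
  tag_in <- revcomp(substr(fx$intron, 10, 31))
  tag_un <- random_rna(21, c("A", "C", "G", "T"))
  tag_tr <- substr(fx$ncrna$tRNA, 20, 41)
  tab <- data.frame(
    seq = c(tag_mir, tag_ex, tag_in, tag_un, tag_tr),
    L1 = c(5L, 3L, 2L, 1L, 4L), L2 = c(0L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  out <- categorize(tab, fx$ncrna, fx$ann, fx$mature_db, fx$genome)
  sm <- summarize_categories(out, tab)
  for (lib in c("L1", "L2")) {
    s <- sm[sm$library == lib, ]
    expect_equal(sum(s$unique), sum(tab[[lib]] > 0))
    expect_equal(sum(s$total), sum(tab[[lib]]))
    expect_equal(sum(s$unique_pct), 100, tolerance = 0.01)
    expect_equal(sum(s$total_pct), 100, tolerance = 0.01)
  }
  # hand computation for L1: rRNA 5, tRNA 4, exon_sense 3, intron_antisense 2,
  # unannotated 1 (the mature tag is inside the rRNA reference => rRNA)
  s1 <- sm[sm$library == "L1", ]
  expect_equal(s1$total[s1$category == "rRNA"], 5L)
  expect_equal(s1$total[s1$category == "tRNA"], 4L)
  expect_equal(s1$total[s1$category == "exon_sense"], 3L)
  expect_equal(s1$total[s1$category == "intron_antisense"], 2L)
  expect_equal(s1$total[s1$category == "unannotated"], 1L)
})
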