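# Synthetic small RNA experiment generator: a toy genome with planted
# miRNA hairpins, four libraries (leaf/root x control/stress) with
# designed per-miRNA abundances and condition effects, ncRNA contaminant
# fragments, adapter-ligated reads with injected low-quality and short
# reads, a toy gene annotation, and a toy transcriptome with planted
# target sites. Every downstream stage is scoreable against the returned
# truth tables.

#' Construct a simulation design
#'
#' Defaults emulate a four-library drought experiment: two conditions by
#' two tissues, a 24-nt-dominant background length distribution, a small
#' panel of planted miRNA hairpins spanning three decades of abundance,
#' and contaminant fractions loosely shaped like a typical plant sRNA
#' library (rRNA dominating the ncRNA classes, most reads unannotated).
#'
#' @param n_mirnas number of planted miRNA hairpins.
#' @param n_scaffolds,scaffold_length toy genome dimensions (nt).
#' @param libraries data.frame with columns name, condition
#'   (control/stress), tissue (leaf/root), total_reads.
#' @param mirna_fraction expected fraction of clean reads that are miRNA
#'   in a control library (sets the total design TPM mass).
#' @param contaminant_fraction named fractions for rRNA, tRNA, snRNA,
#'   snoRNA, exonic, intronic read classes; the unannotated genomic class
#'   absorbs the remainder.
#' @param low_quality_fraction,short_fraction fractions of raw reads
#'   injected as low-quality (mean Phred < 10) and as sub-18-nt inserts,
#'   to exercise cleaning.
#' @param length_noise probabilities over fragment lengths 18-30 for
#'   background classes (default peaks at 24 nt).
#' @param adapter3 3' adapter ligated to every insert.
#' @param read_length sequencer read length (nt).
#' @param error_rate uniform substitution rate applied to inserts.
#' @param overdispersion NULL for Poisson counts (default), or a
#'   negative-binomial size parameter for overdispersed counts.
#' @param lfc_choices candidate per-tissue designed log2 fold changes,
#'   sampled per miRNA; `prob` gives their weights.
#' @param lfc_prob sampling weights for `lfc_choices`.
#' @param seed integer master seed; fixed seed gives byte-identical
#'   outputs.
#' @return a `simulation_design` list.
#' @export
simulation_design <- function(n_mirnas = 20L,
                              n_scaffolds = 2L,
                              scaffold_length = 50000L,
                              libraries = data.frame(
                                name = c("LC", "LS", "RC", "RS"),
                                condition = c("control", "stress", "control", "stress"),
                                tissue = c("leaf", "leaf", "root", "root"),
                                total_reads = 1e5,
                                stringsAsFactors = FALSE
                              ),
                              mirna_fraction = 0.13,
                              contaminant_fraction = c(
                                rRNA = 0.06, tRNA = 0.02, snRNA = 0.003,
                                snoRNA = 0.002, exonic = 0.03, intronic = 0.03
                              ),
                              low_quality_fraction = 0.002,
                              short_fraction = 0.005,
                              length_noise = NULL,
                              adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                              read_length = 36L,
                              error_rate = 0,
                              overdispersion = NULL,
                              lfc_choices = c(-1.5, 0, 0, 0, 0, 1.5),
                              lfc_prob = NULL,
                              seed = 1L) {
  if (n_scaffolds < 0L || (n_scaffolds > 0L && scaffold_length <= 0L)) {
    stop("scaffold dimensions must be positive", call. = FALSE)
  }
  if (n_scaffolds > 0L && scaffold_length < 10L * 365L) {
    stop("scaffold_length must be at least 10x the maximum precursor length",
      call. = FALSE
    )
  }
  fr <- c(contaminant_fraction, low_quality_fraction, short_fraction, mirna_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("fractions must lie in [0,1] and sum to at most 1", call. = FALSE)
  }
  if (any(libraries$total_reads <= 0)) {
    stop("total_reads must be positive", call. = FALSE)
  }
  if (is.null(length_noise)) {
    length_noise <- stats::setNames(
      c(2, 3, 5, 12, 10, 8, 30, 10, 7, 5, 4, 2, 2), 18:30
    )
    length_noise <- length_noise / sum(length_noise)
  }
  structure(list(
    n_mirnas = as.integer(n_mirnas),
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_length = as.integer(scaffold_length),
    libraries = libraries,
    mirna_fraction = mirna_fraction,
    contaminant_fraction = contaminant_fraction,
    low_quality_fraction = low_quality_fraction,
    short_fraction = short_fraction,
    length_noise = length_noise,
    adapter3 = as_dna(adapter3),
    read_length = as.integer(read_length),
    error_rate = error_rate,
    overdispersion = overdispersion,
    lfc_choices = lfc_choices,
    lfc_prob = lfc_prob,
    seed = as.integer(seed)
  ), class = "simulation_design")
}

#' Generate the toy genome
#'
#' @param design a [simulation_design()].
#' @return [Biostrings::DNAStringSet] of scaffolds named
#'   `scaffold_1..n`; empty set for zero scaffolds.
#' @export
generate_genome <- function(design) {
  set.seed(design$seed)
  if (design$n_scaffolds == 0L) {
    return(Biostrings::DNAStringSet())
  }
  seqs <- random_dna(rep(design$scaffold_length, design$n_scaffolds))
  names(seqs) <- paste0("scaffold_", seq_len(design$n_scaffolds))
  Biostrings::DNAStringSet(seqs)
}

# near-reverse-complement with n_wobble G:U positions (star side changed
# C->T opposite a mature G, or A->G opposite a mature T)
.make_star <- function(mature, n_wobble) {
  star <- seq_chars(revcomp(mature))
  cand <- which(star %in% c("C", "A"))
  n <- min(n_wobble, length(cand))
  if (n > 0L) {
    at <- sample(cand, n)
    star[at] <- ifelse(star[at] == "C", "T", "G")
  }
  paste(star, collapse = "")
}

# build one hairpin precursor; stem extends beyond the mature:star duplex
# through near-complementary flanks, so the whole planted locus folds as
# one dominant stem of length >= 70 nt
.build_hairpin <- function(mlen) {
  first <- sample(c("T", "A", "C", "G"), 1L, prob = c(0.5, 0.2, 0.15, 0.15))
  mature <- paste0(first, random_dna(mlen - 1L))
  loop <- random_dna(sample(8:20, 1L))
  star <- .make_star(mature, sample(0:2, 1L))
  ext5 <- random_dna(sample(15:40, 1L))
  ext3 <- .make_star(ext5, sample(0:2, 1L))
  arm <- sample(c("5p", "3p"), 1L)
  precursor <- if (arm == "5p") {
    paste0(ext5, mature, loop, star, ext3)
  } else {
    paste0(ext5, star, loop, mature, ext3)
  }
  list(mature = mature, star = star, precursor = precursor, arm = arm)
}

#' Plant miRNA hairpins into the genome
#'
#' Constructs `n_mirnas` hairpin precursors (mature + loop +
#' near-reverse-complement star, stem extended by near-complementary
#' flanks) and writes each into the genome at a random non-overlapping
#' locus (minimum separation 600 nt), on a random strand: a minus-strand
#' precursor is written as its reverse complement, so the reverse
#' complement of the genomic slice equals the precursor. Per-miRNA design
#' abundances span roughly three decades and each tissue gets a designed
#' log2 fold change sampled from `design$lfc_choices`.
#'
#' @param genome [Biostrings::DNAStringSet] from [generate_genome()].
#' @param design a [simulation_design()].
#' @return list with `genome` (modified) and `planted`, a data.frame with
#'   id, mature_seq, star_seq, precursor_seq, arm, scaffold, start, end
#'   (1-based inclusive), strand, tpm_control, lfc_leaf, lfc_root.
#' @export
plant_hairpins <- function(genome, design) {
  set.seed(design$seed + 1L)
  n <- design$n_mirnas
  if (n == 0L) {
    return(list(genome = genome, planted = NULL))
  }
  glen <- Biostrings::width(genome)
  if (sum(glen) < n * (365L + 600L)) {
    stop("insufficient room to place hairpins", call. = FALSE)
  }
  mlens <- sample(c(20L, 21L, 22L, 24L), n, replace = TRUE, prob = c(0.15, 0.55, 0.15, 0.15))
  # abundance mass: log-uniform weights normalised to the design miRNA TPM
  wt <- 10^stats::runif(n, 0, 3)
  tpm_control <- wt / sum(wt) * design$mirna_fraction * 1e6
  lfc_leaf <- sample(design$lfc_choices, n, replace = TRUE, prob = design$lfc_prob)
  lfc_root <- sample(design$lfc_choices, n, replace = TRUE, prob = design$lfc_prob)

  occupied <- stats::setNames(
    rep(list(IRanges::IRanges()), length(genome)), names(genome)
  )
  rows <- list()
  gseqs <- as.character(genome)
  for (i in seq_len(n)) {
    hp <- .build_hairpin(mlens[i])
    plen <- nchar(hp$precursor)
    placed <- FALSE
    for (try in 1:1000) {
      sc <- sample(length(genome), 1L)
      start <- sample(glen[sc] - plen + 1L, 1L)
      rng <- IRanges::IRanges(start, start + plen - 1L)
      if (!length(IRanges::findOverlaps(rng, occupied[[sc]], maxgap = 600L))) {
        occupied[[sc]] <- c(occupied[[sc]], rng)
        strand <- sample(c("+", "-"), 1L)
        written <- if (strand == "-") revcomp(hp$precursor) else hp$precursor
        substr(gseqs[sc], start, start + plen - 1L) <- written
        rows[[i]] <- data.frame(
          id = sprintf("syn-miR%03d", i),
          mature_seq = hp$mature, star_seq = hp$star,
          precursor_seq = hp$precursor, arm = hp$arm,
          scaffold = names(genome)[sc],
          start = start, end = start + plen - 1L, strand = strand,
          tpm_control = tpm_control[i],
          lfc_leaf = lfc_leaf[i], lfc_root = lfc_root[i],
          stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("insufficient room to place hairpins", call. = FALSE)
  }
  list(
    genome = Biostrings::DNAStringSet(stats::setNames(gseqs, names(genome))),
    planted = do.call(rbind, rows)
  )
}

#' Expected TPM of each planted miRNA in each library
#'
#' Control libraries express `tpm_control`; stress libraries express
#' `tpm_control * 2^lfc` for the library's tissue.
#'
#' @param planted data.frame from [plant_hairpins()].
#' @param design a [simulation_design()].
#' @return numeric matrix, miRNAs x libraries.
#' @export
design_tpm_matrix <- function(planted, design) {
  libs <- design$libraries
  out <- matrix(0, nrow(planted), nrow(libs),
    dimnames = list(planted$id, libs$name)
  )
  for (k in seq_len(nrow(libs))) {
    lfc <- if (libs$tissue[k] == "leaf") planted$lfc_leaf else planted$lfc_root
    out[, k] <- planted$tpm_control *
      if (libs$condition[k] == "stress") 2^lfc else 1
  }
  out
}

#' Expected read-class proportions per library, before sampling
#'
#' @param planted data.frame from [plant_hairpins()].
#' @param design a [simulation_design()].
#' @return matrix of proportions (classes x libraries); each column sums
#'   to one: the designed miRNA mass, the contaminant classes, the
#'   injected low-quality and short classes, and the residual unannotated
#'   genomic class.
#' @export
category_expectations <- function(planted, design) {
  tpm <- design_tpm_matrix(planted, design)
  libs <- design$libraries$name
  classes <- c(
    "miRNA", names(design$contaminant_fraction),
    "low_quality", "short", "genomic"
  )
  out <- matrix(0, length(classes), length(libs), dimnames = list(classes, libs))
  for (lib in libs) {
    mir <- sum(tpm[, lib]) / 1e6
    fixed <- c(
      design$contaminant_fraction,
      low_quality = design$low_quality_fraction,
      short = design$short_fraction
    )
    resid <- 1 - mir - sum(fixed)
    if (resid < 0) stop("designed fractions exceed 1", call. = FALSE)
    out[, lib] <- c(mir, fixed, resid)
  }
  out
}

#' Generate toy non-coding RNA reference sets
#'
#' @param design a [simulation_design()].
#' @return named list of [Biostrings::DNAStringSet]: rRNA, tRNA, snRNA,
#'   snoRNA.
#' @export
make_ncrna_refs <- function(design) {
  set.seed(design$seed + 2L)
  mk <- function(prefix, n, len) {
    s <- random_dna(rep(len, n))
    names(s) <- paste0(prefix, "_", seq_len(n))
    Biostrings::DNAStringSet(s)
  }
  list(
    rRNA = mk("rRNA", 2L, 800L),
    tRNA = mk("tRNA", 5L, 75L),
    snRNA = mk("snRNA", 3L, 150L),
    snoRNA = mk("snoRNA", 3L, 100L)
  )
}

#' Generate a toy gene annotation
#'
#' Lays genes (three exons, two introns each) on the genome, avoiding the
#' planted hairpin loci by at least 600 nt.
#'
#' @param genome the (planted) genome.
#' @param planted data.frame from [plant_hairpins()] (may be NULL).
#' @param design a [simulation_design()].
#' @param genes_per_scaffold number of genes attempted per scaffold.
#' @return annotation data.frame: scaffold, start, end, strand, feature,
#'   gene_id.
#' @export
make_annotation <- function(genome, planted, design, genes_per_scaffold = 3L) {
  set.seed(design$seed + 3L)
  rows <- list()
  for (sc in names(genome)) {
    glen <- Biostrings::width(genome)[match(sc, names(genome))]
    occupied <- if (!is.null(planted)) {
      p <- planted[planted$scaffold == sc, , drop = FALSE]
      IRanges::IRanges(p$start, p$end)
    } else {
      IRanges::IRanges()
    }
    placed <- IRanges::IRanges()
    for (g in seq_len(genes_per_scaffold)) {
      exl <- sample(150:400, 3L, replace = TRUE)
      inl <- sample(80:300, 2L, replace = TRUE)
      tot <- sum(exl) + sum(inl)
      for (try in 1:200) {
        start <- sample(glen - tot + 1L, 1L)
        rng <- IRanges::IRanges(start, start + tot - 1L)
        if (length(IRanges::findOverlaps(rng, occupied, maxgap = 600L)) ||
          length(IRanges::findOverlaps(rng, placed, maxgap = 10L))) {
          next
        }
        placed <- c(placed, rng)
        strand <- sample(c("+", "-"), 1L)
        gid <- sprintf("%s_g%d", sc, g)
        pos <- start
        feats <- c("exon", "intron", "exon", "intron", "exon")
        lens <- c(exl[1], inl[1], exl[2], inl[2], exl[3])
        for (f in seq_along(feats)) {
          rows[[length(rows) + 1L]] <- data.frame(
            scaffold = sc, start = pos, end = pos + lens[f] - 1L,
            strand = strand, feature = feats[f], gene_id = gid,
            stringsAsFactors = FALSE
          )
          pos <- pos + lens[f]
        }
        break
      }
    }
  }
  do.call(rbind, rows)
}

# random fragment of a reference sequence set, length drawn from the
# design length-noise distribution (clipped to the sequence)
.sample_fragments <- function(n, refs, len_prob) {
  if (n == 0L) {
    return(character(0))
  }
  lens <- as.integer(sample(names(len_prob), n, replace = TRUE, prob = len_prob))
  src <- sample(length(refs), n, replace = TRUE)
  seqs <- as.character(refs)
  vapply(seq_len(n), function(k) {
    s <- seqs[src[k]]
    L <- min(lens[k], nchar(s))
    p <- sample(nchar(s) - L + 1L, 1L)
    substr(s, p, p + L - 1L)
  }, character(1))
}

.apply_errors <- function(seqs, rate) {
  if (rate <= 0) {
    return(seqs)
  }
  vapply(seqs, function(s) {
    ch <- seq_chars(s)
    hit <- stats::runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# inserts -> fixed-length adapter-ligated reads + Phred+33 qualities
.ligate_reads <- function(inserts, adapter, read_length, quality = "high") {
  n <- length(inserts)
  if (n == 0L) {
    return(list(seq = character(0), qual = character(0)))
  }
  full <- paste0(inserts, adapter)
  pad <- pmax(0L, read_length - nchar(full))
  full <- paste0(full, random_dna(pad))
  reads <- substr(full, 1L, read_length)
  qchars <- if (quality == "high") {
    33L + 28L:40L # Phred 28-40
  } else {
    33L + 2L:12L # Phred 2-12, mean < 10
  }
  qual <- vapply(seq_len(n), function(k) {
    intToUtf8(sample(qchars, read_length, replace = TRUE))
  }, character(1))
  list(seq = reads, qual = qual)
}

#' Simulate the small RNA libraries
#'
#' Per library: miRNA read counts are drawn Poisson with mean
#' `design TPM x total_reads / 1e6` (negative binomial when
#' `design$overdispersion` is set); contaminant classes (ncRNA fragments,
#' exon/intron fragments, unannotated genomic fragments) are drawn Poisson
#' around their designed fractions; low-quality and short reads are
#' injected to exercise cleaning. Every insert is ligated to the 3'
#' adapter and cut to `read_length` with Phred+33 qualities.
#'
#' @param planted data.frame from [plant_hairpins()].
#' @param design a [simulation_design()].
#' @param genome the planted genome.
#' @param ncrna named list from [make_ncrna_refs()].
#' @param annotation data.frame from [make_annotation()].
#' @return list with `reads` (per library: list(seq, qual)), and `truth`:
#'   `mirna_counts` (matrix miRNA x library of sampled read counts) and
#'   `class_counts` (matrix class x library).
#' @export
simulate_libraries <- function(planted, design, genome, ncrna, annotation) {
  libs <- design$libraries
  tpmmat <- design_tpm_matrix(planted, design)
  nm <- nrow(planted)
  mirna_counts <- matrix(0L, nm, nrow(libs), dimnames = list(planted$id, libs$name))
  classes <- c(
    names(design$contaminant_fraction), "low_quality", "short", "genomic"
  )
  class_counts <- matrix(0L, length(classes), nrow(libs),
    dimnames = list(classes, libs$name)
  )
  reads <- list()
  exon_refs <- NULL
  intron_refs <- NULL
  if (!is.null(annotation) && nrow(annotation)) {
    gs <- as.character(genome)
    grab <- function(feat) {
      a <- annotation[annotation$feature == feat, , drop = FALSE]
      frag <- substr(gs[a$scaffold], a$start, a$end)
      neg <- a$strand == "-"
      frag[neg] <- revcomp(frag[neg])
      Biostrings::DNAStringSet(frag)
    }
    exon_refs <- grab("exon")
    intron_refs <- grab("intron")
  }

  for (k in seq_len(nrow(libs))) {
    set.seed(design$seed + 10L + k)
    total <- libs$total_reads[k]
    mu <- tpmmat[, k] * total / 1e6
    cnt <- if (is.null(design$overdispersion)) {
      stats::rpois(nm, mu)
    } else {
      stats::rnbinom(nm, size = design$overdispersion, mu = mu)
    }
    mirna_counts[, k] <- cnt
    inserts <- rep(planted$mature_seq, cnt)

    frac <- design$contaminant_fraction
    add_class <- function(class_seqs) inserts <<- c(inserts, class_seqs)
    for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
      ncls <- stats::rpois(1L, frac[[cls]] * total)
      class_counts[cls, k] <- ncls
      add_class(.sample_fragments(ncls, ncrna[[cls]], design$length_noise))
    }
    nex <- stats::rpois(1L, frac[["exonic"]] * total)
    class_counts["exonic", k] <- nex
    if (!is.null(exon_refs)) {
      fr <- .sample_fragments(nex, exon_refs, design$length_noise)
      anti <- stats::runif(nex) < 0.3
      fr[anti] <- revcomp(fr[anti])
      add_class(fr)
    }
    nin <- stats::rpois(1L, frac[["intronic"]] * total)
    class_counts["intronic", k] <- nin
    if (!is.null(intron_refs)) {
      fr <- .sample_fragments(nin, intron_refs, design$length_noise)
      anti <- stats::runif(nin) < 0.3
      fr[anti] <- revcomp(fr[anti])
      add_class(fr)
    }
    exp_used <- sum(tpmmat[, k]) / 1e6 + sum(frac) +
      design$low_quality_fraction + design$short_fraction
    ngen <- stats::rpois(1L, max(0, 1 - exp_used) * total)
    class_counts["genomic", k] <- ngen
    gfr <- .sample_fragments(ngen, genome, design$length_noise)
    anti <- stats::runif(ngen) < 0.5
    gfr[anti] <- revcomp(gfr[anti])
    add_class(gfr)

    nshort <- stats::rpois(1L, design$short_fraction * total)
    class_counts["short", k] <- nshort
    short_len <- stats::setNames(rep(1 / 8, 8L), 10:17)
    add_class(.sample_fragments(nshort, genome, short_len))

    inserts <- .apply_errors(inserts, design$error_rate)
    good <- .ligate_reads(inserts, design$adapter3, design$read_length, "high")

    nlq <- stats::rpois(1L, design$low_quality_fraction * total)
    class_counts["low_quality", k] <- nlq
    lq <- .ligate_reads(
      random_dna(sample(18:30, nlq, replace = TRUE)),
      design$adapter3, design$read_length, "low"
    )
    seqs <- c(good$seq, lq$seq)
    quals <- c(good$qual, lq$qual)
    ord <- sample(length(seqs))
    reads[[libs$name[k]]] <- list(seq = seqs[ord], qual = quals[ord])
  }
  list(
    reads = reads,
    truth = list(mirna_counts = mirna_counts, class_counts = class_counts)
  )
}

#' Write simulated libraries to FASTQ
#'
#' @param sim result of [simulate_libraries()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths.
#' @export
write_library_fastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (lib in names(sim$reads)) {
    r <- sim$reads[[lib]]
    path <- file.path(dir, paste0(lib, ".fastq"))
    ids <- sprintf("%s_read_%d", lib, seq_along(r$seq))
    lines <- character(4L * length(r$seq))
    lines[seq(1, by = 4, length.out = length(r$seq))] <- paste0("@", ids)
    lines[seq(2, by = 4, length.out = length(r$seq))] <- r$seq
    lines[seq(3, by = 4, length.out = length(r$seq))] <- "+"
    lines[seq(4, by = 4, length.out = length(r$seq))] <- r$qual
    writeLines(lines, path)
    out[lib] <- path
  }
  out
}

#' Generate a toy transcriptome with planted miRNA target sites
#'
#' Each target transcript embeds one site built from the reverse
#' complement of a planted mature sequence, mutated according to a
#' per-site mismatch plan (total mismatches, how many of them are G:U
#' wobbles, and the miRNA positions affected, counted from the miRNA 5'
#' end). Wobble positions are only drawn where the mature has G or U.
#'
#' @param planted data.frame from [plant_hairpins()].
#' @param n_targets number of target transcripts.
#' @param mismatch_plan optional data.frame with columns `total_mm`
#'   (including wobbles), `n_gu`, and optionally `positions`
#'   (comma-separated miRNA positions; sampled when absent). Recycled over
#'   targets. Default mixes clean, lightly-mismatched and rule-violating
#'   sites.
#' @param seed integer seed.
#' @param decoys number of additional transcripts without planted sites.
#' @return list with `transcripts` ([Biostrings::DNAStringSet]) and
#'   `truth` data.frame: transcript, mirna, site start/end, planned
#'   positions and states.
#' @export
make_transcriptome <- function(planted, n_targets = 10L, mismatch_plan = NULL,
                               seed = 99L, decoys = 3L) {
  set.seed(seed)
  if (is.null(mismatch_plan)) {
    mismatch_plan <- data.frame(
      total_mm = c(0, 1, 2, 4, 5, 1),
      n_gu = c(0, 1, 0, 2, 0, 0),
      positions = c("", "3", "1,20", "1,5,15,20", "2,5,8,14,18", "10"),
      stringsAsFactors = FALSE
    )
  }
  rows <- list()
  txs <- character(0)
  for (j in seq_len(n_targets)) {
    mi <- ((j - 1L) %% nrow(planted)) + 1L
    plan <- mismatch_plan[((j - 1L) %% nrow(mismatch_plan)) + 1L, ]
    mature <- planted$mature_seq[mi]
    L <- nchar(mature)
    mch <- seq_chars(mature)
    total_mm <- plan$total_mm
    n_gu <- min(plan$n_gu, total_mm)
    if (!is.null(plan$positions) && nzchar(plan$positions)) {
      pos <- as.integer(strsplit(plan$positions, ",")[[1L]])
    } else {
      pos <- sort(sample(L, total_mm))
    }
    if (length(pos) != total_mm) {
      stop("mismatch plan positions do not match total_mm", call. = FALSE)
    }
    if (any(pos > L)) stop("plan position beyond site length", call. = FALSE)
    # assign wobbles to planned positions where the mature has G or U
    wobble_ok <- pos[mch[pos] %in% c("G", "T")]
    gu_pos <- utils::head(wobble_ok, n_gu)
    mm_pos <- setdiff(pos, gu_pos)

    site <- seq_chars(revcomp(mature)) # window read 5'->3' on transcript
    for (p in gu_pos) {
      # G:U wobble at miRNA position p: mature G faces T, mature T faces G
      site[L - p + 1L] <- if (mch[p] == "G") "T" else "G"
    }
    wc <- c(A = "T", C = "G", G = "C", T = "A")
    for (p in mm_pos) {
      bad <- setdiff(c("A", "C", "G", "T"), c(
        wc[[mch[p]]],
        if (mch[p] == "G") "T" else if (mch[p] == "T") "G" else NULL
      ))
      site[L - p + 1L] <- sample(bad, 1L)
    }
    site <- paste(site, collapse = "")
    flank5 <- random_dna(sample(100:300, 1L))
    flank3 <- random_dna(sample(100:300, 1L))
    tx <- paste0(flank5, site, flank3)
    tid <- sprintf("tx_%03d", j)
    txs[tid] <- tx
    states <- rep("|", L)
    states[gu_pos] <- "o"
    states[mm_pos] <- "x"
    rows[[j]] <- data.frame(
      transcript = tid, mirna = planted$id[mi],
      mature_seq = mature,
      start = nchar(flank5) + 1L, end = nchar(flank5) + L,
      total_mm = total_mm, n_gu = length(gu_pos),
      positions = paste(pos, collapse = ","),
      states = paste(states, collapse = ""),
      stringsAsFactors = FALSE
    )
  }
  for (d in seq_len(decoys)) {
    txs[sprintf("decoy_%03d", d)] <- random_dna(sample(300:600, 1L))
  }
  list(
    transcripts = Biostrings::DNAStringSet(txs),
    truth = do.call(rbind, rows)
  )
}

#' Simulate a complete experiment
#'
#' Convenience wrapper: genome, planted hairpins, ncRNA references, gene
#' annotation, libraries, transcriptome.
#'
#' @param design a [simulation_design()].
#' @param outdir optional directory; when given, genome/reference FASTA,
#'   library FASTQ, annotation and truth TSV files are written there.
#' @return list with genome, planted, ncrna, annotation, sim (reads +
#'   truth), transcriptome.
#' @export
simulate_experiment <- function(design = simulation_design(), outdir = NULL) {
  genome0 <- generate_genome(design)
  ph <- plant_hairpins(genome0, design)
  ncrna <- make_ncrna_refs(design)
  ann <- make_annotation(ph$genome, ph$planted, design)
  sim <- simulate_libraries(ph$planted, design, ph$genome, ncrna, ann)
  tx <- make_transcriptome(ph$planted, seed = design$seed + 50L)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(ph$genome, file.path(outdir, "genome.fasta"))
    for (cls in names(ncrna)) {
      Biostrings::writeXStringSet(
        ncrna[[cls]], file.path(outdir, paste0(cls, ".fasta"))
      )
    }
    Biostrings::writeXStringSet(
      tx$transcripts, file.path(outdir, "transcripts.fasta")
    )
    utils::write.table(ann, file.path(outdir, "annotation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(ph$planted, file.path(outdir, "planted_mirnas.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(tx$truth, file.path(outdir, "target_truth.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_library_fastq(sim, outdir)
    yaml::write_yaml(
      design[setdiff(names(design), c("libraries", "length_noise"))],
      file.path(outdir, "design.yaml")
    )
  }
  list(
    genome = ph$genome, planted = ph$planted, ncrna = ncrna,
    annotation = ann, sim = sim, transcriptome = tx
  )
}
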