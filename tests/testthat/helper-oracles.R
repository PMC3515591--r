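# Independent oracles used across the suite. These re-derive expected
# results by brute force / direct evaluation, separately from the code
# paths they check.

# --- RNA folding: exhaustive enumeration of nested structures -----------

.can_pair <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
}

# all dot-bracket structures of chars ch[i..j] (canonical pairs, hairpin
# loops >= 3 unpaired)
enumerate_structures <- function(ch, i = 1L, j = length(ch)) {
  if (j < i) {
    return("")
  }
  if (j == i) {
    return(".")
  }
  out <- paste0(".", enumerate_structures(ch, i + 1L, j))
  for (k in (i + 4L):j) {
    if (k > j) break
    if (!.can_pair(ch[i], ch[k])) next
    inner <- enumerate_structures(ch, i + 1L, k - 1L)
    rest <- if (k == j) "" else enumerate_structures(ch, k + 1L, j)
    out <- c(out, as.vector(outer(
      paste0("(", inner, ")"), rest, paste0
    )))
  }
  out
}

# minimum energy over all nested structures, evaluated independently with
# structure_energy()
enumerate_mfe <- function(seq) {
  ch <- strsplit(mirseq::as_dna(seq), "")[[1]]
  structs <- enumerate_structures(ch)
  energies <- vapply(structs, function(s) structure_energy(seq, s), numeric(1))
  list(mfe = min(energies), structure = structs[which.min(energies)])
}

# --- target rules: direct criteria evaluation on a state vector ---------

# literal re-evaluation of the five acceptance criteria, written with
# different primitives than accept_target()
target_rules_oracle <- function(states, strict_wobble = FALSE) {
  L <- length(states)
  w <- ifelse(states == "x", 1, ifelse(states == "o", if (strict_wobble) 1 else 0.5, 0))
  mm <- if (strict_wobble) states != "|" else states == "x"
  if (sum(w) > 4) {
    return(FALSE)
  }
  # run of three or more mismatches anywhere
  for (i in seq_len(max(0L, L - 2L))) {
    if (mm[i] && mm[i + 1L] && mm[i + 2L]) {
      return(FALSE)
    }
  }
  # adjacent mismatch pair fully inside positions 2-12
  for (i in 2:min(11L, L - 1L)) {
    if (mm[i] && mm[i + 1L]) {
      return(FALSE)
    }
  }
  if ((L >= 10L && mm[10L]) || (L >= 11L && mm[11L])) {
    return(FALSE)
  }
  if (sum(w[1:min(12L, L)]) > 2.5) {
    return(FALSE)
  }
  TRUE
}

# --- Audic-Claverie: direct tail summation without log-space ------------

# pmf by multiplicative recurrence: f(0) = (1/(1+r))^x,
# f(y+1) = f(y) * r * (x+y+1) / ((y+1)(1+r)), r = N2/N1
ac_tail_direct <- function(x, y, N1, N2) {
  r <- N2 / N1
  f <- (1 / (1 + r))^x
  total <- f
  if (y > 0) {
    for (yy in 0:(y - 1)) {
      f <- f * r * (x + yy + 1) / ((yy + 1) * (1 + r))
      total <- total + f
    }
  }
  total
}

ac_pvalue_oracle <- function(x, y, N1, N2) {
  down <- ac_tail_direct(x, y, N1, N2)
  up <- ac_tail_direct(y, x, N2, N1)
  min(1, 2 * min(down, up))
}

# --- small simulation designs used across tests -------------------------

tiny_design <- function(seed = 5L, n_mirnas = 6L, total_reads = 2000) {
  simulation_design(
    n_mirnas = n_mirnas,
    libraries = data.frame(
      name = c("LC", "LS", "RC", "RS"),
      condition = c("control", "stress", "control", "stress"),
      tissue = c("leaf", "leaf", "root", "root"),
      total_reads = total_reads,
      stringsAsFactors = FALSE
    ),
    seed = seed
  )
}

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# in-memory FASTQ construction for preprocess tests
make_fastq <- function(seqs, quals, path) {
  ids <- sprintf("read_%d", seq_along(seqs))
  writeLines(
    as.vector(rbind(paste0("@", ids), seqs, "+", quals)),
    path
  )
  path
}

qual_string <- function(len, q) strrep(intToUtf8(33L + q), len)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
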