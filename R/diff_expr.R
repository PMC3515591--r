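# TPM normalisation, log2 fold changes and the Audic-Claverie Poisson-model
# test for comparing one miRNA's counts between two libraries sequenced to
# different depths (no replicates; the libraries are pooled biological
# material, so the Poisson sampling model is the unit of inference).

#' Transcripts-per-million normalisation
#'
#' @param count read count(s) for a miRNA.
#' @param N library clean-read total.
#' @return `count / N * 1e6`.
#' @export
tpm <- function(count, N) {
  if (!is.numeric(N) || any(N <= 0)) stop("N must be positive", call. = FALSE)
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  count / N * 1e6
}

#' Log2 fold change of TPM values with a zero floor
#'
#' Both TPM values are floored at `floor` before the ratio so that zero
#' counts give a large but finite fold change.
#'
#' @param tpm_treatment,tpm_control TPM values.
#' @param floor positive TPM floor applied before the log ratio.
#' @return `log2(pmax(tpm_treatment, floor) / pmax(tpm_control, floor))`.
#' @export
log2fc <- function(tpm_treatment, tpm_control, floor = 0.01) {
  stopifnot(floor > 0)
  log2(pmax(tpm_treatment, floor) / pmax(tpm_control, floor))
}

# log of the Audic-Claverie conditional mass p(y | x) for libraries of
# sizes N1 (where x was seen) and N2 (where y was seen):
#   p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y))
.ac_log_pmf <- function(y, x, N1, N2) {
  logr <- log(N2) - log(N1)
  log1pr <- log1p(N2 / N1)
  y * logr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y) * log1pr
}

# numerically stable log(sum(exp(v)))
.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Audic-Claverie significance of a count difference
#'
#' Tests whether observing `x` reads in a library of `N1` clean reads and
#' `y` reads in a library of `N2` clean reads is compatible with equal
#' relative abundance, using the conditional Poisson-model mass
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y}}.}
#' The down-regulation tail accumulates \eqn{p(y' \mid x)} over
#' \eqn{y' \le y}; the up-regulation tail is the same accumulation with the
#' roles of the two libraries swapped, \eqn{p(x' \mid y)} over
#' \eqn{x' \le x}. Both are finite sums, computed in log space. The
#' two-sided p-value is twice the smaller tail, capped at one; this form is
#' exactly symmetric under exchanging (x, N1) with (y, N2).
#'
#' @param x,y non-negative integer counts (control, treatment).
#' @param N1,N2 positive library totals for `x` and `y` respectively.
#' @param sided `"two"` (default), or the one-sided `"down"` /
#'   `"up"` tails (treatment depleted / enriched relative to control).
#' @return p-value in (0, 1].
#' @export
ac_pvalue <- function(x, y, N1, N2, sided = c("two", "down", "up")) {
  sided <- match.arg(sided)
  stopifnot(x >= 0, y >= 0, x == floor(x), y == floor(y), N1 > 0, N2 > 0)
  down <- exp(.logsumexp(.ac_log_pmf(0:y, x, N1, N2)))
  up <- exp(.logsumexp(.ac_log_pmf(0:x, y, N2, N1)))
  p <- switch(sided,
    two = 2 * min(down, up),
    down = down,
    up = up
  )
  min(p, 1)
}

#' Build an expression record table for one control/treatment contrast
#'
#' @param counts data.frame or matrix with rownames (or an `id` column) and
#'   the two count columns named in `control` and `treatment`.
#' @param control,treatment library (column) names.
#' @param N1,N2 clean-read totals of the control and treatment libraries.
#' @param floor TPM floor for [log2fc()].
#' @return data.frame with id, counts, TPM values, log2fc and p_value.
#' @export
expression_records <- function(counts, control, treatment, N1, N2,
                               floor = 0.01) {
  ids <- if ("id" %in% names(counts)) counts$id else rownames(counts)
  x <- counts[[control]]
  y <- counts[[treatment]]
  tc <- tpm(x, N1)
  tt <- tpm(y, N2)
  p <- mapply(ac_pvalue, x, y, MoreArgs = list(N1 = N1, N2 = N2))
  data.frame(
    id = ids,
    count_control = x, count_treatment = y,
    tpm_control = tc, tpm_treatment = tt,
    log2fc = log2fc(tt, tc, floor = floor),
    p_value = p,
    stringsAsFactors = FALSE
  )
}

#' Call differentially expressed miRNAs
#'
#' A miRNA is called significant when its p-value is below `p_cut` and the
#' absolute log2 fold change exceeds `lfc_cut`. Optionally the p-values are
#' Benjamini-Hochberg adjusted first (off by default; the raw
#' Audic-Claverie p-value is the primary statistic).
#'
#' @param records data.frame from [expression_records()].
#' @param p_cut p-value threshold (default 0.01).
#' @param lfc_cut absolute log2 fold-change threshold (default 1).
#' @param adjust apply Benjamini-Hochberg adjustment before thresholding.
#' @return the records with added `significant` and `direction` columns,
#'   plus attributes `n_significant`, `n_up`, `n_down`.
#' @export
call_de <- function(records, p_cut = 0.01, lfc_cut = 1.0, adjust = FALSE) {
  p <- if (adjust) stats::p.adjust(records$p_value, "BH") else records$p_value
  sig <- p < p_cut & abs(records$log2fc) > lfc_cut
  records$significant <- sig
  records$direction <- ifelse(!sig, "ns", ifelse(records$log2fc > 0, "up", "down"))
  attr(records, "n_significant") <- sum(sig)
  attr(records, "n_up") <- sum(sig & records$log2fc > 0)
  attr(records, "n_down") <- sum(sig & records$log2fc < 0)
  records
}
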