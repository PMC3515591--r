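# RNA secondary structure prediction under an embedded nearest-neighbour
# energy model. The same parameter set drives both the C++ dynamic program
# (fold) and the pure-R loop-decomposition evaluator (structure_energy), so
# a predicted structure's evaluated energy always equals the reported MFE.

#' Energy parameters of the folding model
#'
#' Returns the nearest-neighbour parameter set used by [fold()] and
#' [structure_energy()]: a Turner-style 6x6 stacking matrix over the pair
#' types CG, GC, GU, UG, AU, UA (kcal/mol, 37 C), logarithmic hairpin,
#' bulge and internal-loop penalties, and an affine multiloop term
#' (`ml_close` per closed multiloop, `ml_branch` per helix including the
#' closing one, zero per unpaired multiloop base). The model has no dangling
#' ends, coaxial stacks or terminal-AU penalties; interior loops are bounded
#' at `maxloop` unpaired bases during the search; hairpin loops have at
#' least `min_hairpin` = 3 unpaired bases; G:U is canonical.
#'
#' @return a list with elements `stack` (6x6 numeric matrix) and the scalar
#'   loop parameters.
#' @export
fold_params <- function() {
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  stack <- matrix(c(
    # inner:  CG    GC    GU    UG    AU    UA      outer:
    -3.3, -3.4, -2.1, -1.4, -2.1, -2.4, # CG
    -2.4, -3.3, -2.5, -1.5, -2.2, -2.1, # GC
    -1.4, -2.5, -0.5, 0.3, -0.6, -1.0, # GU
    -2.1, -2.1, 0.3, -0.5, -1.4, -1.0, # UG
    -2.1, -2.2, -1.4, -0.6, -0.9, -1.3, # AU
    -2.4, -2.1, -1.0, -1.0, -1.3, -0.9 # UA
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  rt175 <- 1.75 * 0.0019872 * 310.15 # 1.75 RT at 37 C, Jacobson-Stockmayer slope
  list(
    stack = stack,
    hairpin_a = 5.4, hairpin_b = rt175,
    bulge1 = 3.8, bulge_a = 2.8, bulge_b = rt175,
    internal_a = 2.0, internal_b = rt175,
    internal_asym = 0.5, internal_asym_max = 3.0,
    ml_close = 3.4, ml_branch = 0.4,
    maxloop = 30L, min_hairpin = 3L
  )
}

.pair_type_map <- c(
  CG = 1L, GC = 2L, GT = 3L, TG = 4L, AT = 5L, TA = 6L
)

# pair type index (1..6) of two DNA-alphabet bases, 0 if non-canonical
pair_type <- function(a, b) {
  t <- .pair_type_map[paste0(a, b)]
  ifelse(is.na(t), 0L, t)
}

#' Fold an RNA sequence to its minimum-free-energy structure
#'
#' Computes the minimum-free-energy secondary structure (no pseudoknots)
#' under the embedded nearest-neighbour model described in [fold_params()].
#' The empty structure has energy zero, so the reported MFE is never
#' positive; a sequence with no canonical pairs (e.g. poly-A) folds to all
#' dots with MFE 0.
#'
#' @param sequence a single RNA or DNA string (U and T equivalent), length
#'   at most `max_len`.
#' @param max_len maximum accepted length (the search is O(n^3)).
#' @return an object of class `fold_result`: list with `sequence` (as
#'   given), `structure` (dot-bracket string) and `mfe` (kcal/mol).
#' @examples
#' fold("GGGGAAAACCCC")
#' @export
fold <- function(sequence, max_len = 400L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  check_alphabet(sequence, "fold() input")
  if (nchar(sequence) > max_len) {
    stop("sequence longer than max_len (", max_len, ")", call. = FALSE)
  }
  dna <- as_dna(sequence)
  p <- fold_params()
  res <- .rnafold_cpp(dna, p$stack, p[-1L])
  structure(
    list(sequence = sequence, structure = res$structure, mfe = res$mfe),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", sprintf("%.2f", x$mfe),
    " kcal/mol)\n",
    sep = ""
  )
  invisible(x)
}

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string (only `.`, `(`, `)`).
#' @return integer vector `pt` with `pt[i]` the 1-based partner of position
#'   i, or 0 if unpaired.
#' @export
pair_table <- function(structure) {
  ch <- seq_chars(structure)
  if (any(!ch %in% c(".", "(", ")"))) {
    stop("structure may only contain '.', '(' and ')'", call. = FALSE)
  }
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced brackets", call. = FALSE)
  pt
}

# Direct children (base pairs immediately inside pair/region), given a pair
# table. Returns matrix with columns k, l.
.direct_children <- function(pt, i, j) {
  ks <- integer(0)
  ls <- integer(0)
  k <- i + 1L
  while (k <= j - 1L) {
    if (pt[k] > k) {
      ks <- c(ks, k)
      ls <- c(ls, pt[k])
      k <- pt[k] + 1L
    } else {
      k <- k + 1L
    }
  }
  cbind(k = ks, l = ls)
}

#' Free energy of a given structure on a given sequence
#'
#' Evaluates the nearest-neighbour energy of an explicit secondary structure
#' by loop decomposition, independently of the dynamic program in [fold()].
#' All base pairs must be canonical (G:U allowed) and hairpin loops must
#' have at least three unpaired bases.
#'
#' @param sequence RNA or DNA string.
#' @param structure dot-bracket string of the same length.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(sequence, structure) {
  dna <- as_dna(sequence)
  if (nchar(dna) != nchar(structure)) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  pt <- pair_table(structure)
  ch <- seq_chars(dna)
  p <- fold_params()
  lg <- function(n, ref) 1.75 * 0.0019872 * 310.15 * log(n / ref)
  energy <- 0
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (j <= i) next
    t_out <- pair_type(ch[i], ch[j])
    if (t_out == 0L) {
      stop("non-canonical pair at ", i, "-", j, call. = FALSE)
    }
    kids <- .direct_children(pt, i, j)
    nb <- nrow(kids)
    if (nb == 0L) {
      n <- j - i - 1L
      if (n < p$min_hairpin) stop("hairpin loop shorter than 3", call. = FALSE)
      energy <- energy + p$hairpin_a + lg(n, 3)
    } else if (nb == 1L) {
      k <- kids[1L, "k"]
      l <- kids[1L, "l"]
      n1 <- k - i - 1L
      n2 <- j - l - 1L
      t_in <- pair_type(ch[k], ch[l])
      if (n1 == 0L && n2 == 0L) {
        energy <- energy + p$stack[t_out, t_in]
      } else if (n1 == 0L || n2 == 0L) {
        n <- n1 + n2
        energy <- energy + if (n == 1L) p$bulge1 else p$bulge_a + lg(n, 2)
      } else {
        energy <- energy + p$internal_a + lg(n1 + n2, 2) +
          min(p$internal_asym_max, p$internal_asym * abs(n1 - n2))
      }
    } else {
      energy <- energy + p$ml_close + p$ml_branch * (nb + 1L)
    }
  }
  unname(energy)
}
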