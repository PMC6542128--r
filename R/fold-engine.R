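#' Exhaustively enumerate admissible secondary structures
#'
#' Generates every nested structure whose pairs are admissible under the
#' model (complementarity, GU only if allowed, `j - i > theta`), including
#' the empty structure. Intended as a testing oracle for the dynamic
#' programming routines; the interval decomposition (rightmost position
#' either unpaired or paired with some `k`) produces each structure exactly
#' once.
#'
#' @param seq an `rna_sequence` or string, at most 18 nt (the structure count
#'   explodes combinatorially beyond that).
#' @param model an [energy_model()].
#' @return A list of `pair_table`s.
#' @examples
#' length(enumerate_structures("GAAAC"))  # empty structure + (1,5)
#' @export
enumerate_structures <- function(seq, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  if (seq$length > 18) {
    stop("refusing to enumerate structures for sequences longer than 18 nt",
         call. = FALSE)
  }
  en <- energy_matrix(seq, model)
  adm <- is.finite(en)
  theta <- model$theta
  memo <- new.env(parent = emptyenv())
  empty <- matrix(integer(0), 0, 2)
  rec <- function(i, j) {
    if (j - i < theta + 1) return(list(empty))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i, j - 1)                       # j unpaired
    for (k in i:(j - theta - 1)) {             # j paired with k
      if (!adm[k, j]) next
      left <- if (k - 1 >= i) rec(i, k - 1) else list(empty)
      right <- rec(k + 1, j - 1)
      for (L in left) {
        for (R in right) {
          out <- c(out, list(rbind(L, R, c(k, j))))
        }
      }
    }
    memo[[key]] <- out
    out
  }
  structs <- if (seq$length >= 2) rec(1L, seq$length) else list(empty)
  lapply(structs, function(m) pair_table(m[, 1], m[, 2]))
}

#' Minimum-free-energy structure by interval dynamic programming
#'
#' Computes the structure minimising the sum of pair energies under the
#' simplified model, with a deterministic traceback: pairing is preferred
#' over leaving a position unpaired when both attain the optimum, and the
#' smallest pairing partner wins ties.
#'
#' @inheritParams enumerate_structures
#' @return A list with `structure` (a `pair_table`) and `energy` (model
#'   units, `<= 0`).
#' @examples
#' nussinov_mfe("GGGAAACCC")
#' @export
nussinov_mfe <- function(seq, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  res <- nussinov_cpp(energy_matrix(seq, model))
  list(structure = pair_table(res$i, res$j), energy = res$energy)
}

#' Partition function and base-pair probabilities
#'
#' McCaskill-style inside and outside recursions over the simplified model:
#' the partition function `Q` sums the Boltzmann weight (product of pair
#' weights) of every admissible structure, and `bpp` holds, for each
#' admissible pair, the total weight of structures containing it divided by
#' `Q`.
#'
#' For the input sizes this package accepts (at most 200 nt) the computation
#' is safe in plain double precision: the largest attainable weight is far
#' below overflow, and an explicit guard errors if `Q` ever becomes
#' non-finite.
#'
#' @inheritParams enumerate_structures
#' @param drop_below entries with probability below this are not stored.
#' @return A list with `Q` (partition function) and `bpp`, a tibble with
#'   columns `i`, `j`, `p` and attribute `n` (sequence length). Absent pairs
#'   have probability 0; per-position probability sums never exceed 1.
#' @examples
#' mccaskill("GAAAC")$bpp
#' @export
mccaskill <- function(seq, model = energy_model(), drop_below = 1e-12) {
  seq <- as_rna_sequence(seq)
  res <- mccaskill_cpp(weight_matrix(seq, model))
  bpp <- tibble(i = res$i, j = res$j, p = pmin(res$p, 1))
  bpp <- bpp[bpp$p >= drop_below, ]
  bpp <- bpp[order(bpp$i, bpp$j), ]
  attr(bpp, "n") <- seq$length
  list(Q = res$Q, bpp = bpp)
}

#' Look up one entry of a base-pair probability table
#'
#' @param bpp tibble with columns `i`, `j`, `p` (as returned in
#'   [mccaskill()]'s `bpp`).
#' @param i,j positions, any order.
#' @return The stored probability, or 0 if the pair is absent.
#' @export
bpp_lookup <- function(bpp, i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  hit <- match(paste(lo, hi, sep = ":"), paste(bpp$i, bpp$j, sep = ":"))
  ifelse(is.na(hit), 0, bpp$p[hit])
}

# per-position sum of pair probabilities (length n)
bpp_row_sums <- function(bpp, n) {
  s <- numeric(n)
  if (nrow(bpp) > 0) {
    t1 <- tapply(bpp$p, bpp$i, sum)
    t2 <- tapply(bpp$p, bpp$j, sum)
    s[as.integer(names(t1))] <- s[as.integer(names(t1))] + t1
    s[as.integer(names(t2))] <- s[as.integer(names(t2))] + t2
  }
  s
}
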