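#' Secondary structures as base-pair tables
#'
#' A secondary structure is represented as a tibble with integer columns `i`
#' and `j` (1-based, `i < j`), one row per base pair, sorted by `i`. The
#' structure must be nested (pseudoknot-free), each position may pair at most
#' once, and every pair must enclose more than `theta` unpaired hairpin
#' positions.
#'
#' @param i,j integer vectors of paired positions (`i < j` pairwise).
#' @return A tibble of class `pair_table`.
#' @export
pair_table <- function(i = integer(0), j = integer(0)) {
  stopifnot(length(i) == length(j))
  out <- tibble(i = as.integer(i), j = as.integer(j))
  out <- out[order(out$i), ]
  class(out) <- c("pair_table", class(out))
  out
}

#' Validate a secondary structure
#'
#' Checks the pair-table invariants: indices in range, `i < j`, no position in
#' two pairs, no crossing (pseudoknotted) pairs, and minimum hairpin size.
#'
#' @param pairs a `pair_table` (or tibble with `i`, `j`).
#' @param n sequence length.
#' @param theta minimum number of unpaired positions a pair must enclose.
#' @return `pairs`, invisibly, if valid; otherwise an error.
#' @export
validate_structure <- function(pairs, n, theta = 3) {
  i <- pairs$i; j <- pairs$j
  if (any(i < 1 | j > n)) stop("pair index out of range", call. = FALSE)
  if (any(i >= j)) stop("pairs must satisfy i < j", call. = FALSE)
  if (anyDuplicated(c(i, j)) > 0) {
    stop("a position occurs in more than one pair", call. = FALSE)
  }
  if (any(j - i <= theta)) {
    stop(sprintf("pair violates minimum hairpin size theta = %d", theta),
         call. = FALSE)
  }
  if (length(i) > 1) {
    for (a in seq_along(i)) {
      crossing <- i < i[a] & j > i[a] & j < j[a] | i > i[a] & i < j[a] & j > j[a]
      if (any(crossing)) stop("crossing base pairs (pseudoknot)", call. = FALSE)
    }
  }
  invisible(pairs)
}

#' Convert a pair table to dot-bracket notation
#'
#' @param pairs a `pair_table`.
#' @param n sequence length (number of characters in the output).
#' @return A dot-bracket string: `(` and `)` for paired positions, `.` for
#'   unpaired ones.
#' @examples
#' pairs_to_db(pair_table(c(1, 2, 3), c(9, 8, 7)), 9)
#' @export
pairs_to_db <- function(pairs, n) {
  validate_structure(pairs, n, theta = 0)
  ch <- rep(".", n)
  ch[pairs$i] <- "("
  ch[pairs$j] <- ")"
  paste(ch, collapse = "")
}

#' Parse dot-bracket notation into a pair table
#'
#' Matches brackets with the usual stack discipline. An unmatched closing
#' bracket, or an opening bracket left unmatched at the end, raises an error
#' naming its position.
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return A `pair_table`.
#' @examples
#' db_to_pairs("(((...)))")
#' @export
db_to_pairs <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  stack <- integer(0)
  pi <- integer(0); pj <- integer(0)
  for (pos in seq_along(ch)) {
    c0 <- ch[pos]
    if (c0 == "(") {
      stack <- c(stack, pos)
    } else if (c0 == ")") {
      if (length(stack) == 0L) {
        stop(sprintf("unbalanced at position %d", pos), call. = FALSE)
      }
      pi <- c(pi, stack[length(stack)])
      pj <- c(pj, pos)
      stack <- stack[-length(stack)]
    } else if (c0 != ".") {
      stop(sprintf("invalid character '%s' at position %d", c0, pos),
           call. = FALSE)
    }
  }
  if (length(stack) > 0L) {
    stop(sprintf("unbalanced at position %d", stack[length(stack)]),
         call. = FALSE)
  }
  pair_table(pi, pj)
}

# "i:j" keys for fast membership tests
pair_keys <- function(pairs) paste(pairs$i, pairs$j, sep = ":")
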