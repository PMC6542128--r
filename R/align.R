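#' Alignment scoring scheme
#'
#' Linear-gap scoring for pairwise local alignment. The defaults (+2 match,
#' -1 mismatch, -2 per gap position) are chosen to be hand-checkable; the
#' alignment is used to transfer difference highlights between two sequences,
#' not for its absolute score.
#'
#' @param match score per identical column (must be positive).
#' @param mismatch score per substitution column (non-positive).
#' @param gap score per gap position (negative, linear).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap = -2) {
  stopifnot(match > 0, mismatch <= 0, gap < 0)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_scheme")
}

#' Smith-Waterman local alignment
#'
#' Maximum-scoring local alignment of two sequences under a linear-gap
#' scheme, with a fully deterministic traceback: the best cell is the first
#' maximum in row-major order, and at each step ties are broken diagonal,
#' then up (gap in `b`), then left (gap in `a`). A score of 0 yields the
#' empty alignment.
#'
#' @param a,b `rna_sequence`s or nucleotide strings.
#' @param scheme a [scoring_scheme()].
#' @return An object of class `local_alignment`: list with `columns` (tibble
#'   of `a_pos`, `b_pos`; `NA` marks a gap), `score`, `a_span`, `b_span`
#'   (1-based closed intervals, `NA` for the empty alignment) and the two
#'   sequences.
#' @examples
#' smith_waterman("GGACGUGG", "UUACGUUU")$score
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  a <- as_rna_sequence(a, "a"); b <- as_rna_sequence(b, "b")
  A <- seq_chars(a); B <- seq_chars(b)
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    si <- ifelse(A[i] == B, scheme$match, scheme$mismatch)
    for (j in seq_len(m)) {
      h <- max(0, H[i, j] + si[j], H[i, j + 1] + scheme$gap,
               H[i + 1, j] + scheme$gap)
      H[i + 1, j + 1] <- h
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  a_pos <- integer(0); b_pos <- integer(0)
  i <- bi; j <- bj
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    h <- H[i + 1, j + 1]
    s <- if (A[i] == B[j]) scheme$match else scheme$mismatch
    if (h == H[i, j] + s) {
      a_pos <- c(i, a_pos); b_pos <- c(j, b_pos); i <- i - 1; j <- j - 1
    } else if (h == H[i, j + 1] + scheme$gap) {
      a_pos <- c(i, a_pos); b_pos <- c(NA_integer_, b_pos); i <- i - 1
    } else {
      a_pos <- c(NA_integer_, a_pos); b_pos <- c(j, b_pos); j <- j - 1
    }
  }
  columns <- tibble(a_pos = a_pos, b_pos = b_pos)
  span <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) c(NA_integer_, NA_integer_) else range(x)
  }
  structure(
    list(columns = columns, score = best,
         a_span = span(a_pos), b_span = span(b_pos), a = a, b = b,
         scheme = scheme),
    class = "local_alignment"
  )
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("<local_alignment> score %g, %d columns\n", x$score,
              nrow(x$columns)))
  cat(format_alignment_text(x), sep = "\n")
  invisible(x)
}

#' @rdname smith_waterman
#' @param x a `local_alignment`.
#' @param ... unused.
#' @method tidy local_alignment
#' @export
tidy.local_alignment <- function(x, ...) {
  A <- seq_chars(x$a); B <- seq_chars(x$b)
  mutate(x$columns,
         a_res = ifelse(is.na(.data$a_pos), "-", A[.data$a_pos]),
         b_res = ifelse(is.na(.data$b_pos), "-", B[.data$b_pos]),
         match = !is.na(.data$a_pos) & !is.na(.data$b_pos) &
           .data$a_res == .data$b_res)
}

#' @rdname smith_waterman
#' @method glance local_alignment
#' @export
glance.local_alignment <- function(x, ...) {
  tibble(score = x$score, n_columns = nrow(x$columns),
         a_start = x$a_span[1], a_end = x$a_span[2],
         b_start = x$b_span[1], b_end = x$b_span[2])
}

#' Infer the positions to highlight between two aligned sequences
#'
#' A position is flagged as a difference when it (i) sits in a mismatch
#' column of the alignment, (ii) sits opposite a gap, or (iii) lies outside
#' the locally aligned span of its own sequence. Identical sequences yield
#' empty sets.
#'
#' @param aln a [smith_waterman()] alignment of `a` and `b`.
#' @param a,b the aligned sequences (default: those stored in `aln`).
#' @return An object of class `difference_set`: list with sorted integer
#'   vectors `a_positions`, `b_positions`.
#' @export
infer_differences <- function(aln, a = aln$a, b = aln$b) {
  a <- as_rna_sequence(a, "a"); b <- as_rna_sequence(b, "b")
  A <- seq_chars(a); B <- seq_chars(b)
  cols <- aln$columns
  if (nrow(cols) > 0 &&
      (max(cols$a_pos, na.rm = TRUE) > a$length ||
       max(cols$b_pos, na.rm = TRUE) > b$length)) {
    stop("alignment indexes positions beyond the sequences it was given",
         call. = FALSE)
  }
  both <- !is.na(cols$a_pos) & !is.na(cols$b_pos)
  mism <- both & A[ifelse(both, cols$a_pos, 1)] != B[ifelse(both, cols$b_pos, 1)]
  a_diff <- c(cols$a_pos[mism], cols$a_pos[!is.na(cols$a_pos) & is.na(cols$b_pos)])
  b_diff <- c(cols$b_pos[mism], cols$b_pos[!is.na(cols$b_pos) & is.na(cols$a_pos)])
  a_out <- if (anyNA(aln$a_span)) seq_len(a$length) else
    setdiff(seq_len(a$length), seq(aln$a_span[1], aln$a_span[2]))
  b_out <- if (anyNA(aln$b_span)) seq_len(b$length) else
    setdiff(seq_len(b$length), seq(aln$b_span[1], aln$b_span[2]))
  structure(
    list(a_positions = sort(unique(c(a_diff, a_out))),
         b_positions = sort(unique(c(b_diff, b_out)))),
    class = "difference_set"
  )
}

#' Count shared and differing base pairs between two structures
#'
#' A pair `(i, j)` of the first structure counts as shared when the alignment
#' maps both `i` and `j` onto non-gap positions `(i', j')` and `(i', j')` is a
#' pair of the second structure. Mapping through the alignment (rather than
#' comparing raw indices) is what lets sequences of unequal length be
#' compared.
#'
#' @param sa,sb `pair_table`s of the two aligned sequences.
#' @param aln the [smith_waterman()] alignment used for the mapping.
#' @return A list with `n_shared`, `n_diff_a` (`= |sa| - n_shared`) and
#'   `n_diff_b`.
#' @export
compare_basepairs <- function(sa, sb, aln) {
  cols <- aln$columns
  both <- !is.na(cols$a_pos) & !is.na(cols$b_pos)
  map <- rep(NA_integer_, aln$a$length)
  map[cols$a_pos[both]] <- cols$b_pos[both]
  shared <- 0L
  if (nrow(sa) > 0) {
    mi <- map[sa$i]; mj <- map[sa$j]
    ok <- !is.na(mi) & !is.na(mj)
    if (any(ok)) {
      keys_b <- pair_keys(sb)
      shared <- sum(paste(pmin(mi[ok], mj[ok]), pmax(mi[ok], mj[ok]),
                          sep = ":") %in% keys_b)
    }
  }
  list(n_shared = shared,
       n_diff_a = nrow(sa) - shared,
       n_diff_b = nrow(sb) - shared)
}

#' Format an alignment as ClustalW-style text
#'
#' Two name-prefixed gapped sequence rows plus a `*` match line, chunked at a
#' fixed width -- the display format of pairwise alignment blocks.
#'
#' @param aln a `local_alignment`.
#' @param width residues per block.
#' @return Character vector of text lines.
#' @export
format_alignment_text <- function(aln, width = 60) {
  td <- tidy(aln)
  if (nrow(td) == 0) {
    return(c(sprintf("%-16s(empty alignment, score %g)", "", aln$score)))
  }
  a_row <- paste(td$a_res, collapse = "")
  b_row <- paste(td$b_res, collapse = "")
  m_row <- paste(ifelse(td$match, "*", " "), collapse = "")
  lines <- character(0)
  starts <- seq(1, nchar(a_row), by = width)
  for (s in starts) {
    e <- min(s + width - 1, nchar(a_row))
    lines <- c(lines,
               sprintf("%-16s%s", aln$a$id, substr(a_row, s, e)),
               sprintf("%-16s%s", aln$b$id, substr(b_row, s, e)),
               sprintf("%-16s%s", "", substr(m_row, s, e)),
               "")
  }
  lines[-length(lines)]
}
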