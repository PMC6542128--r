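#' Create an RNA sequence object
#'
#' Normalises a nucleotide string to the RNA alphabet: whitespace is stripped,
#' case is folded to upper, and `T` is rewritten to `U` (the record is flagged
#' as DNA when any `T` was present, so downstream reports can label base
#' content as AT rather than AU). Any residue outside `A`, `C`, `G`, `U`
#' after normalisation is an error naming the offending position.
#'
#' @param residues single string of nucleotides (RNA or DNA, any case).
#' @param id text label for the sequence.
#' @return An object of class `rna_sequence`: a list with elements `id`,
#'   `residues` (normalised string), `length` and `is_dna`.
#' @examples
#' rna_sequence("gattaca", id = "probe")$residues
#' @export
rna_sequence <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  raw <- toupper(gsub("[[:space:]]", "", residues))
  is_dna <- grepl("T", raw, fixed = TRUE)
  norm <- chartr("T", "U", raw)
  if (nchar(norm) < 1L) {
    stop(sprintf("sequence '%s' is empty", id), call. = FALSE)
  }
  bad <- regexpr("[^ACGU]", norm)
  if (bad > 0L) {
    stop(sprintf("invalid residue '%s' at position %d in sequence '%s'",
                 substr(norm, bad, bad), as.integer(bad), id),
         call. = FALSE)
  }
  structure(
    list(id = id, residues = norm, length = nchar(norm), is_dna = is_dna),
    class = "rna_sequence"
  )
}

#' Coerce to an RNA sequence
#'
#' @param x an `rna_sequence` or a single nucleotide string.
#' @param id label used when `x` is a bare string.
#' @return An `rna_sequence`.
#' @export
as_rna_sequence <- function(x, id = "seq") {
  if (inherits(x, "rna_sequence")) return(x)
  rna_sequence(x, id = id)
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt%s)\n%s\n",
              x$id, x$length, if (x$is_dna) ", DNA input" else "",
              x$residues))
  invisible(x)
}

# residues as a character vector, one base per element
seq_chars <- function(seq) {
  strsplit(seq$residues, "", fixed = TRUE)[[1]]
}

#' Base composition of a sequence
#'
#' Counts and percentages of each base, plus the combined AU (AT for DNA
#' input) and GC content -- the per-sequence descriptive statistics shown in
#' comparison reports.
#'
#' @param seq an `rna_sequence` or nucleotide string.
#' @return A one-row tibble with columns `id`, `length`, `n_A` ... `n_U`,
#'   `pct_A` ... `pct_U`, `au_pct`, `gc_pct`, `is_dna`. Base percentages sum
#'   to 100.
#' @examples
#' composition_stats("ACGU")
#' @export
composition_stats <- function(seq) {
  seq <- as_rna_sequence(seq)
  ch <- seq_chars(seq)
  n <- seq$length
  cnt <- vapply(c("A", "C", "G", "U"), function(b) sum(ch == b), integer(1))
  pct <- 100 * cnt / n
  tibble(
    id = seq$id, length = n,
    n_A = cnt[["A"]], n_C = cnt[["C"]], n_G = cnt[["G"]], n_U = cnt[["U"]],
    pct_A = pct[["A"]], pct_C = pct[["C"]], pct_G = pct[["G"]],
    pct_U = pct[["U"]],
    au_pct = pct[["A"]] + pct[["U"]],
    gc_pct = pct[["G"]] + pct[["C"]],
    is_dna = seq$is_dna
  )
}
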