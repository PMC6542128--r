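#' Read sequences from FASTA
#'
#' Reads up to 10 RNA or DNA records of at most 200 bases each. Multi-line
#' sequences are joined, case is ignored, and DNA is normalised to the RNA
#' alphabet (`T` to `U`) with the record flagged as DNA so reports can label
#' AT rather than AU content. Ambiguity codes (including `N`) are rejected --
#' a wrong plot is worse than no plot.
#'
#' @param x path to a FASTA file, or the FASTA text itself (anything
#'   containing a newline or starting with `>` is treated as text).
#' @return A tibble with one row per record: `id`, `residues` (normalised),
#'   `length`, `is_dna`, in file order.
#' @examples
#' read_fasta(">x\nGGGAAACCC\n")
#' @export
read_fasta <- function(x) {
  stopifnot(is.character(x), length(x) >= 1)
  is_text <- length(x) > 1 || grepl("\n", x, fixed = TRUE) ||
    startsWith(x[1], ">") || !nzchar(x[1])
  if (!is_text && !file.exists(x)) {
    stop(sprintf("no such file: %s", x), call. = FALSE)
  }
  if (is_text) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(x, "\n", fixed = TRUE)), path)
  } else {
    path <- x
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no sequences found in FASTA input", call. = FALSE)
  if (length(set) > 10) {
    stop(sprintf("more than 10 sequences (%d): the pipeline accepts at most 10",
                 length(set)), call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- unname(as.character(set))
  recs <- vector("list", length(set))
  for (k in seq_along(set)) {
    if (nchar(gsub("[[:space:]]", "", seqs[k])) > 200) {
      stop(sprintf("sequence '%s' is longer than 200 bases (%d)",
                   ids[k], nchar(seqs[k])), call. = FALSE)
    }
    s <- rna_sequence(seqs[k], id = ids[k])
    recs[[k]] <- tibble(id = s$id, residues = s$residues, length = s$length,
                        is_dna = s$is_dna)
  }
  bind_rows(recs)
}
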