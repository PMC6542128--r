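#' Build a pairwise comparison report
#'
#' Assembles the descriptive statistics block for two folded sequences:
#' per-sequence length, base content (single bases, AU/AT and GC), MFE value,
#' number of MFE base pairs and dot-bracket string; jointly, the number of
#' shared and differing base pairs (through the alignment mapping), the
#' alignment score and the number of highlighted positions.
#'
#' @param fa,fb [fold()] results for the two sequences.
#' @param aln their [smith_waterman()] alignment.
#' @param diffs the [infer_differences()] set (computed from `aln` if
#'   omitted).
#' @return An object of class `comparison_report`: list with `sequences`
#'   (two-row tibble), `joint` (one-row tibble), `alignment`, `differences`.
#' @export
build_report <- function(fa, fb, aln, diffs = infer_differences(aln)) {
  per_seq <- function(f) {
    comp <- composition_stats(f$sequence)
    mutate(comp,
           mfe = f$mfe_value, mfe_unit = f$mfe_unit,
           n_mfe_pairs = nrow(f$mfe_structure),
           dot_bracket = pairs_to_db(f$mfe_structure, f$sequence$length))
  }
  cmp <- compare_basepairs(fa$mfe_structure, fb$mfe_structure, aln)
  joint <- tibble(
    n_shared_pairs = cmp$n_shared,
    n_diff_pairs_a = cmp$n_diff_a,
    n_diff_pairs_b = cmp$n_diff_b,
    alignment_score = aln$score,
    n_highlighted_a = length(diffs$a_positions),
    n_highlighted_b = length(diffs$b_positions)
  )
  structure(
    list(sequences = bind_rows(per_seq(fa), per_seq(fb)), joint = joint,
         alignment = aln, differences = diffs),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.comparison_report <- function(x, ...) {
  s <- x$sequences
  lines <- c("Pairwise comparison report", "==========================", "")
  for (k in 1:2) {
    r <- s[k, ]
    ax <- if (r$is_dna) "AT" else "AU"
    lines <- c(lines,
      sprintf("Sequence: %s", r$id),
      sprintf("  length: %d nt", r$length),
      sprintf("  base content: A %d (%.1f%%)  C %d (%.1f%%)  G %d (%.1f%%)  U %d (%.1f%%)",
              r$n_A, r$pct_A, r$n_C, r$pct_C, r$n_G, r$pct_G, r$n_U, r$pct_U),
      sprintf("  %s content: %.1f%%   GC content: %.1f%%", ax, r$au_pct, r$gc_pct),
      sprintf("  MFE: %.2f %s   MFE base pairs: %d", r$mfe, r$mfe_unit,
              r$n_mfe_pairs),
      sprintf("  structure: %s", r$dot_bracket),
      "")
  }
  j <- x$joint
  c(lines,
    "Joint statistics",
    sprintf("  shared base pairs: %d", j$n_shared_pairs),
    sprintf("  base pairs only in %s: %d", s$id[1], j$n_diff_pairs_a),
    sprintf("  base pairs only in %s: %d", s$id[2], j$n_diff_pairs_b),
    sprintf("  local alignment score: %g", j$alignment_score),
    sprintf("  highlighted positions: %d in %s, %d in %s",
            j$n_highlighted_a, s$id[1], j$n_highlighted_b, s$id[2]),
    "",
    "Local alignment",
    format_alignment_text(x$alignment))
}

#' @rdname build_report
#' @param x a `comparison_report`.
#' @param ... unused.
#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) x$sequences

#' @rdname build_report
#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) x$joint

#' Serialise a comparison report to files
#'
#' Writes the human-readable plain-text report and a structured key-value
#' (TSV) version of the same statistics.
#'
#' @param report a `comparison_report`.
#' @param txt_path,kv_path output paths; `NULL` skips that format.
#' @return Invisibly, a named list of the key-value pairs.
#' @export
write_report <- function(report, txt_path = NULL, kv_path = NULL) {
  if (!is.null(txt_path)) writeLines(format(report), txt_path)
  s <- report$sequences
  kv <- list()
  for (k in 1:2) {
    pre <- sprintf("seq%d", k)
    r <- s[k, ]
    kv[[paste0(pre, ".id")]] <- r$id
    kv[[paste0(pre, ".length")]] <- r$length
    for (b in c("A", "C", "G", "U")) {
      kv[[sprintf("%s.n_%s", pre, b)]] <- r[[paste0("n_", b)]]
      kv[[sprintf("%s.pct_%s", pre, b)]] <- sprintf("%.4f", r[[paste0("pct_", b)]])
    }
    kv[[paste0(pre, ".au_pct")]] <- sprintf("%.4f", r$au_pct)
    kv[[paste0(pre, ".gc_pct")]] <- sprintf("%.4f", r$gc_pct)
    kv[[paste0(pre, ".mfe")]] <- sprintf("%.4f", r$mfe)
    kv[[paste0(pre, ".mfe_unit")]] <- r$mfe_unit
    kv[[paste0(pre, ".n_mfe_pairs")]] <- r$n_mfe_pairs
    kv[[paste0(pre, ".dot_bracket")]] <- r$dot_bracket
  }
  j <- report$joint
  for (nm in names(j)) kv[[paste0("joint.", nm)]] <- j[[nm]]
  if (!is.null(kv_path)) {
    writeLines(sprintf("%s\t%s", names(kv),
                       vapply(kv, function(v) as.character(v), character(1))),
               kv_path)
  }
  invisible(kv)
}
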