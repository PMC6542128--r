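#' Fold one sequence
#'
#' Produces a `fold_result`: the MFE secondary structure, the MFE value and
#' the base-pair probability matrix for a sequence, computed either by the
#' self-contained simplified engine ([nussinov_mfe()] + [mccaskill()], model
#' units) or by an external ViennaRNA-style folder discovered on the PATH
#' (kcal/mol).
#'
#' The internal engine does not model G-quadruplexes or circular molecules;
#' requesting either with `backend = "internal"` is an error rather than a
#' silent approximation. `no_lonely_pairs` and `no_closing_gu` are honoured
#' by the internal engine as post-hoc filters on the MFE structure only (the
#' probability matrix is unaffected); the external backend passes all flags
#' through to the folder.
#'
#' @param seq an `rna_sequence` or nucleotide string.
#' @param backend `"internal"` or `"external"`.
#' @param temperature_c folding temperature, degrees Celsius.
#' @param gquad,circular G-quadruplex / circular-molecule flags (external
#'   backend only).
#' @param no_lonely_pairs forbid helices of a single pair.
#' @param no_gu forbid GU wobble pairs everywhere.
#' @param no_closing_gu forbid GU pairs at helix ends.
#' @param dangles dangling-end treatment, passed through to the external
#'   folder; the internal model has no dangle concept.
#' @param model energy model for the internal backend; defaults to
#'   [energy_model()] at `temperature_c` with GU admissibility from `no_gu`.
#' @param probability_cutoff probabilities below this are not stored.
#' @return An object of class `fold_result`: list with `sequence`,
#'   `mfe_structure` (`pair_table`), `mfe_value`, `mfe_unit`, `bpp`,
#'   `backend_id`, `temperature_c`.
#' @examples
#' fold("GGGAAACCC")
#' @export
fold <- function(seq, backend = c("internal", "external"),
                 temperature_c = 37, gquad = FALSE, circular = FALSE,
                 no_lonely_pairs = FALSE, no_gu = FALSE,
                 no_closing_gu = FALSE, dangles = 2, model = NULL,
                 probability_cutoff = 1e-12) {
  seq <- as_rna_sequence(seq)
  backend <- match.arg(backend)
  if (backend == "internal") {
    if (gquad || circular) {
      stop("gquad/circular folding is unsupported by the internal engine; use backend = \"external\"",
           call. = FALSE)
    }
    model <- model %||% energy_model(temperature_c = temperature_c,
                                     allow_gu = !no_gu)
    mfe <- nussinov_mfe(seq, model)
    pf <- mccaskill(seq, model, drop_below = probability_cutoff)
    structure_pairs <- mfe$structure
    if (no_lonely_pairs) structure_pairs <- remove_lonely_pairs(structure_pairs)
    if (no_closing_gu) {
      structure_pairs <- remove_closing_gu(structure_pairs, seq)
    }
    res <- list(sequence = seq, mfe_structure = structure_pairs,
                mfe_value = mfe$energy, mfe_unit = "model units",
                bpp = pf$bpp, Q = pf$Q, backend_id = "internal",
                temperature_c = temperature_c)
  } else {
    ext <- fold_external(seq, temperature_c = temperature_c, gquad = gquad,
                         circular = circular,
                         no_lonely_pairs = no_lonely_pairs, no_gu = no_gu,
                         no_closing_gu = no_closing_gu, dangles = dangles)
    res <- list(sequence = seq, mfe_structure = ext$structure,
                mfe_value = ext$mfe, mfe_unit = "kcal/mol",
                bpp = ext$bpp, Q = NA_real_, backend_id = ext$backend_id,
                temperature_c = temperature_c)
  }
  class(res) <- "fold_result"
  res
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %s (%d nt, %s backend, T = %g C)\n",
              x$sequence$id, x$sequence$length, x$backend_id,
              x$temperature_c))
  cat(x$sequence$residues, "\n")
  cat(sprintf("%s (%0.2f %s)\n",
              pairs_to_db(x$mfe_structure, x$sequence$length),
              x$mfe_value, x$mfe_unit))
  cat(sprintf("%d MFE pairs, %d base-pair probability entries\n",
              nrow(x$mfe_structure), nrow(x$bpp)))
  invisible(x)
}

#' @rdname fold
#' @param x a `fold_result`.
#' @param ... unused.
#' @method tidy fold_result
#' @export
tidy.fold_result <- function(x, ...) {
  mfe_keys <- pair_keys(x$mfe_structure)
  out <- x$bpp
  out$is_mfe <- pair_keys(out) %in% mfe_keys
  # MFE pairs missing from the stored probabilities (external backend with a
  # truncated dot plot) are kept with their stored probability 0
  missing <- !(mfe_keys %in% pair_keys(out))
  if (any(missing)) {
    add <- x$mfe_structure[missing, ]
    out <- bind_rows(out, tibble(i = add$i, j = add$j, p = 0, is_mfe = TRUE))
  }
  out <- out[order(out$i, out$j), ]
  as_tibble(out)
}

#' @rdname fold
#' @method glance fold_result
#' @export
glance.fold_result <- function(x, ...) {
  comp <- composition_stats(x$sequence)
  tibble(id = x$sequence$id, length = x$sequence$length,
         mfe = x$mfe_value, mfe_unit = x$mfe_unit,
         n_mfe_pairs = nrow(x$mfe_structure),
         n_bpp_entries = nrow(x$bpp),
         gc_pct = comp$gc_pct, au_pct = comp$au_pct,
         backend = x$backend_id, temperature_c = x$temperature_c)
}

# drop pairs with no stacked neighbour, repeatedly (removal can orphan others)
remove_lonely_pairs <- function(pairs) {
  repeat {
    if (nrow(pairs) == 0) return(pairs)
    keys <- pair_keys(pairs)
    inner <- paste(pairs$i + 1, pairs$j - 1, sep = ":") %in% keys
    outer <- paste(pairs$i - 1, pairs$j + 1, sep = ":") %in% keys
    keep <- inner | outer
    if (all(keep)) return(pairs)
    pairs <- pairs[keep, ]
  }
}

# drop GU/UG pairs sitting at a helix end, repeatedly
remove_closing_gu <- function(pairs, seq) {
  ch <- seq_chars(seq)
  repeat {
    if (nrow(pairs) == 0) return(pairs)
    keys <- pair_keys(pairs)
    inner <- paste(pairs$i + 1, pairs$j - 1, sep = ":") %in% keys
    outer <- paste(pairs$i - 1, pairs$j + 1, sep = ":") %in% keys
    at_end <- !(inner & outer)
    gu <- !is.na(pair_type(ch[pairs$i], ch[pairs$j])) &
      pair_type(ch[pairs$i], ch[pairs$j]) == "GU"
    drop <- gu & at_end
    if (!any(drop)) return(pairs)
    pairs <- pairs[!drop, ]
  }
}
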