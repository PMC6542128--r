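#' Parse RNAfold-style text output
#'
#' Reads the folder's stdout dialect: an optional `>id` header, the sequence
#' line, then a line holding the dot-bracket MFE structure followed by the
#' MFE in parentheses, e.g. `(((...))) ( -5.40)`. Any further lines (ensemble
#' free energy, frequency notes) are ignored.
#'
#' @param text the folder output as a single string or character vector of
#'   lines.
#' @return A list with `sequence` (an `rna_sequence`), `structure` (a
#'   `pair_table`) and `mfe` (kcal/mol).
#' @examples
#' parse_rnafold_text("GGGAAACCC\n(((...))) ( -5.40)")
#' @export
parse_rnafold_text <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("expected a sequence line and a structure line",
                              call. = FALSE)
  id <- "seq"
  if (startsWith(lines[1], ">")) {
    id <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  seq <- rna_sequence(trimws(lines[1]), id = id)
  if (length(lines) < 2) stop("missing structure line", call. = FALSE)
  m <- regmatches(lines[2],
                  regexec("^\\s*([.()]+)\\s*\\(\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\)\\s*$",
                          lines[2]))[[1]]
  if (length(m) != 3) {
    stop("malformed structure line: expected 'DOTBRACKET ( MFE)'",
         call. = FALSE)
  }
  db <- m[2]
  if (nchar(db) != seq$length) {
    stop(sprintf("structure length %d does not match sequence length %d",
                 nchar(db), seq$length), call. = FALSE)
  }
  list(sequence = seq, structure = db_to_pairs(db), mfe = as.numeric(m[3]))
}

#' Parse an RNAfold PostScript dot plot
#'
#' Extracts the upper-triangle probability records from the folder's
#' PostScript dot-plot dialect. Each record `i j v ubox` stores the square
#' root of the pair probability (so that box side is proportional to
#' `sqrt(p)` and box area to `p`); the parser squares `v`. Records ending in
#' anything else (e.g. the `lbox` MFE boxes) are ignored.
#'
#' @param text file content as a single string or character vector of lines.
#' @param drop_below entries with squared value below this are dropped.
#' @return A tibble with columns `i`, `j`, `p` (1-based indices as in the
#'   file), sorted by `i`, `j`.
#' @examples
#' parse_dotplot_ps("3 10 0.5000000 ubox")
#' @export
parse_dotplot_ps <- function(text, drop_below = 1e-6) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  is_ubox <- grepl("ubox\\s*$", lines) & !grepl("^\\s*[%/]", lines)
  ii <- integer(0); jj <- integer(0); pp <- numeric(0)
  for (ln in which(is_ubox)) {
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) != 4 || fields[4] != "ubox") next
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (anyNA(vals)) {
      stop(sprintf("non-numeric field in ubox record at line %d", ln),
           call. = FALSE)
    }
    p <- vals[3]^2
    if (p < drop_below) next
    ii <- c(ii, as.integer(vals[1]))
    jj <- c(jj, as.integer(vals[2]))
    pp <- c(pp, p)
  }
  out <- tibble(i = pmin(ii, jj), j = pmax(ii, jj), p = pp)
  out[order(out$i, out$j), ]
}

#' Write a fold result as dot-bracket text
#'
#' Mirrors the folder's text layout: a `>id` header, the sequence, and the
#' dot-bracket structure with the MFE in parentheses.
#'
#' @param fold a [fold()] result.
#' @param path file to write; omit to return the lines.
#' @return The character lines, invisibly when `path` is given.
#' @export
write_dotbracket <- function(fold, path = NULL) {
  lines <- c(paste0(">", fold$sequence$id),
             fold$sequence$residues,
             sprintf("%s (%6.2f)",
                     pairs_to_db(fold$mfe_structure, fold$sequence$length),
                     fold$mfe_value))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# run an external ViennaRNA-style folder (RNAfold) with partition function on
fold_external <- function(seq, temperature_c = 37, gquad = FALSE,
                          circular = FALSE, no_lonely_pairs = FALSE,
                          no_gu = FALSE, no_closing_gu = FALSE, dangles = 2) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    stop(paste("external backend unavailable: RNAfold not found on PATH;",
               "fall back to backend = \"internal\""), call. = FALSE)
  }
  wd <- tempfile("rnafold-")
  dir.create(wd)
  old <- setwd(wd)
  on.exit({ setwd(old); unlink(wd, recursive = TRUE) }, add = TRUE)
  writeLines(c(">q", seq$residues), "in.fa")
  args <- c("-p", sprintf("--temp=%g", temperature_c),
            sprintf("--dangles=%d", dangles),
            if (gquad) "--gquad", if (circular) "--circ",
            if (no_lonely_pairs) "--noLP", if (no_gu) "--noGU",
            if (no_closing_gu) "--noClosingGU",
            "--infile=in.fa")
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop(sprintf("external folder failed (exit %d): %s", status,
                 paste(out, collapse = " / ")), call. = FALSE)
  }
  parsed <- parse_rnafold_text(out)
  dp <- "q_dp.ps"
  if (!file.exists(dp)) stop("external folder produced no dot plot", call. = FALSE)
  bpp <- parse_dotplot_ps(readLines(dp))
  attr(bpp, "n") <- seq$length
  list(structure = parsed$structure, mfe = parsed$mfe, bpp = bpp,
       backend_id = paste("RNAfold", rnafold_version()))
}

rnafold_version <- function() {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) return(NA_character_)
  v <- suppressWarnings(system2(exe, "--version", stdout = TRUE, stderr = TRUE))
  sub("^RNAfold\\s+", "", v[1])
}
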