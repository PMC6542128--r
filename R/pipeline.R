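#' Pipeline configuration
#'
#' Folding and comparison parameters for [run_pipeline()], mirroring the
#' adjustable web-form parameters: temperature, molecule linearity,
#' G-quadruplex incorporation, forbidden lonely pairs, and forbidden GU pairs
#' (everywhere or at helix ends).
#'
#' @param temperature_c folding temperature in degrees Celsius, within
#'   `[0, 100]`.
#' @param molecule `"linear"` or `"circular"` (circular requires the external
#'   backend).
#' @param gquad incorporate G-quadruplexes (external backend only).
#' @param no_lonely_pairs,no_gu,no_closing_gu see [fold()].
#' @param backend `"internal"` or `"external"`.
#' @param select the two records to compare: a pair of ids or 1-based
#'   indices; default the first two records.
#' @param probability_cutoff minimum probability for a drawn arc.
#' @param output_dir where the bundle is written (default: a fresh temporary
#'   directory).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(temperature_c = 37,
                            molecule = c("linear", "circular"),
                            gquad = FALSE, no_lonely_pairs = FALSE,
                            no_gu = FALSE, no_closing_gu = FALSE,
                            backend = c("internal", "external"),
                            select = NULL, probability_cutoff = 0.01,
                            output_dir = NULL) {
  molecule <- match.arg(molecule)
  backend <- match.arg(backend)
  if (temperature_c < 0 || temperature_c > 100) {
    stop("temperature must lie within [0, 100] degrees Celsius", call. = FALSE)
  }
  if (!is.null(select) && (length(select) != 2 || select[1] == select[2])) {
    stop("select must name two distinct records", call. = FALSE)
  }
  structure(
    list(temperature_c = temperature_c, molecule = molecule, gquad = gquad,
         no_lonely_pairs = no_lonely_pairs, no_gu = no_gu,
         no_closing_gu = no_closing_gu, backend = backend, select = select,
         probability_cutoff = probability_cutoff, output_dir = output_dir),
    class = "pipeline_config"
  )
}

# one info line per pipeline stage
log_stage <- function(...) message("[rnachord] ", sprintf(...))

#' Run the FASTA-to-bundle pipeline
#'
#' End-to-end flow: read the FASTA input, fold every record at the configured
#' temperature, select two records, align them locally, infer the difference
#' highlights, build the comparison report, render one chord plot per
#' sequence plus the two-panel comparative figure, and write everything --
#' fold files, SVGs, plain-text and key-value reports, alignment text -- into
#' an output directory together with a ZIP archive of all files. Re-running
#' with the same input and configuration reproduces the bundle byte for byte.
#'
#' @param fasta FASTA path or text (see [read_fasta()]).
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage log messages.
#' @return An object of class `output_bundle`: list with `dir`, `files`
#'   (named vector of emitted files, relative to `dir`), `zip`, `report`,
#'   `alignment`, `differences`, `folds` and the record table.
#' @examples
#' \donttest{
#' bundle <- run_pipeline(make_fixture_fasta(2, seed = 1), quiet = TRUE)
#' glance(bundle$report)
#' }
#' @export
run_pipeline <- function(fasta, config = pipeline_config(), quiet = FALSE) {
  say <- if (quiet) function(...) invisible() else log_stage
  say("reading FASTA input")
  records <- read_fasta(fasta)
  if (config$molecule == "circular" && config$backend == "internal") {
    stop("circular folding is unsupported by the internal engine; use backend = \"external\"",
         call. = FALSE)
  }
  say("folding %d record(s) at %g C (%s backend)", nrow(records),
      config$temperature_c, config$backend)
  folds <- purrr::map(seq_len(nrow(records)), function(k) {
    fold(rna_sequence(records$residues[k], id = records$id[k]),
         backend = config$backend, temperature_c = config$temperature_c,
         gquad = config$gquad,
         circular = config$molecule == "circular",
         no_lonely_pairs = config$no_lonely_pairs, no_gu = config$no_gu,
         no_closing_gu = config$no_closing_gu)
  })
  names(folds) <- records$id

  sel <- config$select %||% c(1L, 2L)
  if (is.character(sel)) {
    idx <- match(sel, records$id)
    if (anyNA(idx)) {
      stop(sprintf("selected record(s) not present: %s",
                   paste(sel[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
  } else {
    idx <- as.integer(sel)
    if (any(idx < 1 | idx > nrow(records))) {
      stop("selected record index out of range", call. = FALSE)
    }
  }
  if (nrow(records) < 2 && is.null(config$select)) {
    stop("the comparison needs at least two records (or an explicit select)",
         call. = FALSE)
  }
  fa <- folds[[idx[1]]]; fb <- folds[[idx[2]]]
  say("aligning '%s' and '%s'", fa$sequence$id, fb$sequence$id)
  aln <- smith_waterman(fa$sequence, fb$sequence)
  diffs <- infer_differences(aln)
  say("building comparison report")
  report <- build_report(fa, fb, aln, diffs)

  dir <- config$output_dir %||% tempfile("rnachord-bundle-")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  opts <- plot_options(probability_cutoff = config$probability_cutoff)
  files <- character(0)
  say("writing fold files and chord plots")
  safe_names <- make.unique(safe_name(records$id), sep = "_")
  for (k in seq_along(folds)) {
    safe <- safe_names[k]
    f1 <- sprintf("%s.fold.txt", safe)
    write_dotbracket(folds[[k]], file.path(dir, f1))
    f2 <- sprintf("%s.svg", safe)
    write_svg(render_chordplot(folds[[k]], opts), file.path(dir, f2))
    files <- c(files, f1, f2)
  }
  say("rendering comparison figure")
  write_svg(render_comparison(fa, fb, diffs, opts),
            file.path(dir, "comparison.svg"))
  write_report(report, file.path(dir, "report.txt"),
               file.path(dir, "report.tsv"))
  writeLines(format_alignment_text(aln), file.path(dir, "alignment.txt"))
  files <- c(files, "comparison.svg", "report.txt", "report.tsv",
             "alignment.txt")
  say("archiving bundle")
  zip_path <- file.path(dir, "bundle.zip")
  write_zip(zip_path, file.path(dir, files), files)
  structure(
    list(dir = dir, files = files, zip = zip_path, records = records,
         folds = folds, report = report, alignment = aln,
         differences = diffs, config = config),
    class = "output_bundle"
  )
}

#' @export
print.output_bundle <- function(x, ...) {
  cat(sprintf("<output_bundle> %d files in %s\n", length(x$files), x$dir))
  cat(paste0("  ", c(x$files, basename(x$zip)), collapse = "\n"), "\n")
  invisible(x)
}

# filesystem-safe record name
safe_name <- function(id) gsub("[^A-Za-z0-9_.-]", "_", id)
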