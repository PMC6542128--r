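#' Generate a synthetic hairpin-biased FASTA fixture
#'
#' Deterministic test-data generator. Each record carries a planted stem-loop
#' -- a random stem of 4 to 8 complementary pairs (GC-biased, occasional GU),
#' a loop of at least 4 unpaired bases, and random flanks padding the record
#' to its target length -- so that every fixture folds non-trivially while the
#' flanks contribute realistic spurious pairing. Output is reproducible for a
#' given seed.
#'
#' @param n_records number of records, at most 10.
#' @param length_range integer range the record lengths are drawn from
#'   (lengths are capped at 200).
#' @param seed RNG seed.
#' @return FASTA text as a single string.
#' @examples
#' cat(make_fixture_fasta(2, c(30, 40), seed = 1))
#' @export
make_fixture_fasta <- function(n_records = 4, length_range = c(40, 60),
                               seed = 42) {
  if (n_records > 10) {
    stop("at most 10 records: the pipeline input limit", call. = FALSE)
  }
  stopifnot(length(length_range) == 2, length_range[1] >= 20,
            length_range[2] <= 200, length_range[1] <= length_range[2])
  complement <- c(G = "C", C = "G", A = "U", U = "A")
  withr::with_seed(seed, {
    recs <- vapply(seq_len(n_records), function(k) {
      target <- sample(length_range[1]:length_range[2], 1)
      stem_len <- sample(4:8, 1)
      loop_len <- sample(4:8, 1)
      left <- sample(c("G", "C", "A", "U"), stem_len, replace = TRUE,
                     prob = c(0.4, 0.3, 0.15, 0.15))
      right <- rev(complement[left])
      # occasional wobble: flip a complement C->U under a paired G
      wob <- right == "C" & stats::runif(stem_len) < 0.1
      right[wob] <- "U"
      loop <- sample(c("A", "C", "U"), loop_len, replace = TRUE)
      core <- c(left, loop, right)
      pad <- max(0, target - length(core))
      n5 <- pad %/% 2
      flank5 <- sample(c("A", "C", "G", "U"), n5, replace = TRUE)
      flank3 <- sample(c("A", "C", "G", "U"), pad - n5, replace = TRUE)
      sprintf(">fixture_%02d\n%s", k,
              paste(c(flank5, core, flank3), collapse = ""))
    }, character(1))
    paste0(paste(recs, collapse = "\n"), "\n")
  })
}
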