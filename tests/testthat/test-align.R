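test_that("local alignment matches hand-checkable cases", {
  aln <- smith_waterman("ACGU", "ACGU")
  expect_equal(aln$score, 8)
  expect_equal(nrow(aln$columns), 4)
  expect_equal(aln$a_span, c(1, 4))
  expect_equal(aln$b_span, c(1, 4))

  empty <- smith_waterman("AAAA", "CCCC")
  expect_equal(empty$score, 0)
  expect_equal(nrow(empty$columns), 0)

  aln <- smith_waterman("GGACGUGG", "UUACGUUU")
  expect_equal(aln$score, 8)
  td <- tidy(aln)
  expect_equal(paste(td$a_res, collapse = ""), "ACGU")
  expect_equal(paste(td$b_res, collapse = ""), "ACGU")
  expect_equal(aln$score, bf_local_score("GGACGUGG", "UUACGUUU"))
})

test_that("alignment score equals the brute-force and Biostrings optima", {
  scheme <- scoring_scheme()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = scheme$match,
                                                  mismatch = scheme$mismatch,
                                                  baseOnly = TRUE)
  withr::with_seed(55, {
    for (k in 1:30) {
      a <- random_rna(sample(2:8, 1))
      b <- random_rna(sample(2:8, 1))
      got <- smith_waterman(a, b, scheme)$score
      expect_equal(got, bf_local_score(a, b, scheme))
      # independent dynamic-programming implementation (linear gap =
      # zero opening cost, -2 extension)
      bs <- Biostrings::pairwiseAlignment(
        chartr("U", "T", a), chartr("U", "T", b), type = "local",
        substitutionMatrix = mat,
        gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
      expect_equal(got, max(0, bs))
    }
  })
})

test_that("alignment score is symmetric under operand swap", {
  withr::with_seed(56, {
    for (k in 1:20) {
      a <- random_rna(sample(4:12, 1)); b <- random_rna(sample(4:12, 1))
      expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
    }
  })
})

test_that("difference inference applies the mismatch, gap and out-of-span rules", {
  a <- "ACGU"; same <- infer_differences(smith_waterman(a, a))
  expect_length(same$a_positions, 0)
  expect_length(same$b_positions, 0)

  # substitution at the last position: the optimal local alignment is the
  # 3-column exact block ACG/ACG (score 6 beats the 4-column score 5), and
  # position 4 is flagged in both sequences by the out-of-span rule
  aln <- smith_waterman("ACGU", "ACGA")
  expect_equal(aln$score, 6)
  d <- infer_differences(aln)
  expect_equal(d$a_positions, 4)
  expect_equal(d$b_positions, 4)

  # deletion: positions opposite a gap are flagged on the longer side
  aln <- smith_waterman("ACGUACGU", "ACGACGU")
  d <- infer_differences(aln)
  td <- tidy(aln)
  gap_cols <- td$a_pos[is.na(td$b_pos)]
  expect_true(all(gap_cols %in% d$a_positions))
  expect_length(d$b_positions, 0)
})

test_that("base-pair sharing maps through the alignment and is order-invariant", {
  a <- "GGGAAACCC"
  sa <- pair_table(c(1, 2), c(9, 8))
  sb <- pair_table(c(1, 3), c(9, 7))
  aln <- smith_waterman(a, a)
  cmp <- compare_basepairs(sa, sb, aln)
  expect_equal(cmp$n_shared, 1)
  expect_equal(cmp$n_diff_a, 1)
  expect_equal(cmp$n_diff_b, 1)
  # computed from the other side, the shared count is identical
  swapped <- compare_basepairs(sb, sa, smith_waterman(a, a))
  expect_equal(swapped$n_shared, cmp$n_shared)
  # empty structure on one side
  cmp0 <- compare_basepairs(sa, pair_table(), aln)
  expect_equal(cmp0$n_shared, 0)
  expect_equal(cmp0$n_diff_a, 2)
  # unequal lengths: pairs carried through a gapped alignment still match
  b <- "GGGAAACCCAA"
  alnu <- smith_waterman(a, b)
  cmpu <- compare_basepairs(pair_table(c(1, 2), c(9, 8)),
                            pair_table(c(1, 2), c(9, 8)), alnu)
  expect_equal(cmpu$n_shared, 2)
})

test_that("comparison report assembles consistent statistics", {
  fa <- fold("GGGAAACCC"); fb <- fold("GGGAAACCC")
  aln <- smith_waterman(fa$sequence, fb$sequence)
  rep <- build_report(fa, fb, aln)
  expect_equal(glance(rep)$n_shared_pairs, 3)
  expect_equal(glance(rep)$n_diff_pairs_a, 0)
  expect_equal(glance(rep)$n_highlighted_a, 0)
  td <- tidy(rep)
  expect_equal(nrow(td), 2)
  expect_equal(td$dot_bracket, rep("(((...)))", 2))
  expect_true(all(abs(td$pct_A + td$pct_C + td$pct_G + td$pct_U - 100) < 0.1))
  # report invariants on a non-trivial pair
  fb2 <- fold("GCGCAAAAGCGC")
  aln2 <- smith_waterman(fa$sequence, fb2$sequence)
  rep2 <- build_report(fa, fb2, aln2)
  j <- glance(rep2)
  expect_lte(j$n_shared_pairs, min(tidy(rep2)$n_mfe_pairs))
  expect_equal(j$n_diff_pairs_a, tidy(rep2)$n_mfe_pairs[1] - j$n_shared_pairs)
  expect_equal(j$n_diff_pairs_b, tidy(rep2)$n_mfe_pairs[2] - j$n_shared_pairs)
  txt <- format(rep2)
  expect_true(any(grepl("shared base pairs", txt)))
  kv <- write_report(rep2)
  expect_equal(kv[["joint.n_shared_pairs"]], j$n_shared_pairs)
})

test_that("alignment text block prints name-prefixed rows with a match line", {
  aln <- smith_waterman(rna_sequence("GGACGUGG", "x"),
                        rna_sequence("UUACGUUU", "y"))
  lines <- format_alignment_text(aln)
  expect_match(lines[1], "^x\\s+ACGU$")
  expect_match(lines[2], "^y\\s+ACGU$")
  expect_match(lines[3], "\\*\\*\\*\\*")
})
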