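test_that("internal fold dispatch reproduces the DP routines and contracts", {
  f <- fold("GGGAAACCC", backend = "internal", temperature_c = 37)
  expect_equal(structure_key(f$mfe_structure), "1:9,2:8,3:7")
  expect_equal(f$mfe_value, nussinov_mfe("GGGAAACCC")$energy)
  expect_equal(f$backend_id, "internal")
  expect_equal(f$temperature_c, 37)
  # every MFE pair carries positive ensemble probability from the same backend
  expect_true(all(bpp_lookup(f$bpp, f$mfe_structure$i, f$mfe_structure$j) > 0))

  f0 <- fold("AAAA")
  expect_equal(nrow(f0$mfe_structure), 0)
  expect_equal(nrow(f0$bpp), 0)
  expect_equal(f0$mfe_value, 0)

  expect_error(fold("GGGAAACCC", gquad = TRUE), "unsupported by the internal")
  expect_error(fold("GGGAAACCC", circular = TRUE), "unsupported by the internal")
})

test_that("lonely-pair filter removes unstacked pairs from the MFE structure only", {
  # helix of 3 plus an isolated pair far away
  pairs <- pair_table(c(1, 2, 3, 12), c(30, 29, 28, 20))
  kept <- rnachord:::remove_lonely_pairs(pairs)
  expect_equal(structure_key(kept), "1:30,2:29,3:28")
  # cascading removal: two pairs that only stack on each other survive
  pairs2 <- pair_table(c(1, 2), c(30, 29))
  expect_equal(nrow(rnachord:::remove_lonely_pairs(pairs2)), 2)
  f <- fold("GAAACAAAAA", no_lonely_pairs = TRUE)
  expect_equal(nrow(f$mfe_structure), 0)       # the lone GC pair is filtered
  expect_true(nrow(f$bpp) > 0)                 # the ensemble is untouched
})

test_that("tidy and glance expose the fold as tables", {
  f <- fold("GGGAAACCC")
  td <- tidy(f)
  expect_true(all(c("i", "j", "p", "is_mfe") %in% names(td)))
  expect_equal(sum(td$is_mfe), 3)
  gl <- glance(f)
  expect_equal(gl$n_mfe_pairs, 3)
  expect_equal(gl$mfe, -9)
  expect_equal(gl$length, 9)
})

test_that("external backend folds through the system RNAfold and honours contracts", {
  f <- fold("GGGGAAAACCCC", backend = "external", temperature_c = 37)
  expect_equal(f$mfe_unit, "kcal/mol")
  expect_match(f$backend_id, "RNAfold")
  expect_lt(f$mfe_value, 0)
  expect_gt(nrow(f$mfe_structure), 0)
  validate_structure(f$mfe_structure, f$sequence$length)
  expect_true(all(f$bpp$p > 0 & f$bpp$p <= 1 + 1e-9))
  expect_true(all(rnachord:::bpp_row_sums(f$bpp, f$sequence$length) <= 1 + 1e-6))
  # unpairable sequence: empty structure (MFE may be slightly positive)
  f0 <- fold("AAAAAAAA", backend = "external")
  expect_equal(nrow(f0$mfe_structure), 0)
})
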