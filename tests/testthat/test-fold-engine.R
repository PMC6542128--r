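test_that("enumeration produces exactly the admissible structure set", {
  # no complementary pair at all
  e1 <- enumerate_structures("AAAA")
  expect_length(e1, 1)
  expect_equal(nrow(e1[[1]]), 0)
  # one admissible pair
  e2 <- enumerate_structures("GAAAC")
  expect_setequal(vapply(e2, structure_key, character(1)), c("", "1:5"))
  # cross-check against an enumerator with a different interval decomposition
  for (s in c("GGGAAACCC", "GCAUCGAUGC", "ACGUACGUACGU")) {
    pkg <- sort(vapply(enumerate_structures(s), structure_key, character(1)))
    ind <- sort(unlist(enum_leftmost(s)))
    expect_identical(pkg, ind)
    expect_false(any(duplicated(pkg)))
    expect_true("" %in% pkg)  # empty structure always present
  }
  expect_error(enumerate_structures(strrep("GC", 10)), "longer than 18")
})

test_that("Nussinov energy and traceback match the enumerated optimum", {
  nm <- nussinov_mfe("AAAA")
  expect_equal(nm$energy, 0)
  expect_equal(nrow(nm$structure), 0)
  nm <- nussinov_mfe("GAAAC")
  expect_equal(nm$energy, -3)
  expect_equal(structure_key(nm$structure), "1:5")
  nm <- nussinov_mfe("GGGAAACCC")
  expect_equal(structure_key(nm$structure), "1:9,2:8,3:7")
  orc <- boltzmann_oracle("GGGAAACCC")
  expect_equal(nm$energy, orc$min_energy)
  expect_equal(nm$energy, -9)
  withr::with_seed(31, {
    for (k in 1:30) {
      s <- random_rna(sample(5:12, 1))
      orc <- boltzmann_oracle(s)
      got <- nussinov_mfe(s)
      expect_identical(got$energy, orc$min_energy)
      # traceback must return a structure that actually attains the optimum
      expect_true(structure_key(got$structure) %in%
                    vapply(orc$structures[orc$energies == orc$min_energy],
                           structure_key, character(1)))
    }
  })
})

test_that("partition function and pair probabilities match enumeration", {
  mc <- mccaskill("AAAA")
  expect_equal(mc$Q, 1)
  expect_equal(nrow(mc$bpp), 0)
  # two structures: empty and the single GC pair
  mc <- mccaskill("GAAAC")
  expect_equal(mc$Q, 1 + exp(3), tolerance = 1e-12)
  expect_equal(bpp_lookup(mc$bpp, 1, 5), exp(3) / (1 + exp(3)),
               tolerance = 1e-12)
  withr::with_seed(32, {
    for (k in 1:30) {
      s <- random_rna(sample(5:12, 1))
      orc <- boltzmann_oracle(s)
      mc <- mccaskill(s)
      expect_equal(mc$Q, orc$Q, tolerance = 1e-12)
      if (nrow(mc$bpp) > 0) {
        for (r in seq_len(nrow(mc$bpp))) {
          expect_equal(mc$bpp$p[r], orc$p_of(mc$bpp$i[r], mc$bpp$j[r]),
                       tolerance = 1e-9)
        }
      }
      # no oracle pair missing from the computed table
      for (key in orc$pair_keys) {
        ij <- as.integer(strsplit(key, ":")[[1]])
        expect_equal(bpp_lookup(mc$bpp, ij[1], ij[2]), orc$p_of(ij[1], ij[2]),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("per-position probability sums never exceed one", {
  withr::with_seed(33, {
    for (k in 1:20) {
      s <- random_rna(sample(10, 1) + 20)
      mc <- mccaskill(s)
      expect_true(all(rnachord:::bpp_row_sums(mc$bpp, nchar(s)) <= 1 + 1e-9))
    }
  })
})

test_that("forbidding GU removes wobble pairs from structure and ensemble", {
  s <- "GGGAAAUUU"  # only GU-dependent pairing at the stem top
  base_chars <- strsplit(s, "")[[1]]
  model <- energy_model(allow_gu = FALSE)
  mc <- mccaskill(s, model)
  nm <- nussinov_mfe(s, model)
  is_gu <- function(i, j) paste0(base_chars[i], base_chars[j]) %in% c("GU", "UG")
  if (nrow(mc$bpp) > 0) {
    expect_false(any(mapply(is_gu, mc$bpp$i, mc$bpp$j)))
  }
  if (nrow(nm$structure) > 0) {
    expect_false(any(mapply(is_gu, nm$structure$i, nm$structure$j)))
  }
  # with wobble allowed the same sequence does form GU pairs
  mc2 <- mccaskill(s, energy_model(allow_gu = TRUE))
  expect_true(any(mapply(is_gu, mc2$bpp$i, mc2$bpp$j)))
})

test_that("single-pair probability follows the closed form and melts with temperature", {
  # GAAAC admits exactly one structure besides the empty one
  for (temp in c(25, 37, 50, 75)) {
    w <- exp(3 * (273.15 + 37) / (273.15 + temp))
    mc <- mccaskill("GAAAC", energy_model(temperature_c = temp))
    expect_equal(bpp_lookup(mc$bpp, 1, 5), w / (1 + w), tolerance = 1e-12)
  }
  temps <- seq(25, 75, by = 5)
  probs <- vapply(temps, function(tc) {
    bpp_lookup(mccaskill("GAAAC", energy_model(temperature_c = tc))$bpp, 1, 5)
  }, numeric(1))
  expect_true(all(diff(probs) < 0))
})
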