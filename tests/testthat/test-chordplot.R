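test_that("probability binning follows the 0.2-unit intervals and thickness rule", {
  boundary_p <- c(0, 0.2 - 1e-9, 0.2, 0.4, 0.6, 0.8, 1.0)
  expected_bin <- c(0, 0, 1, 2, 3, 4, 4)
  st <- bin_probability(boundary_p)
  expect_equal(st$bin, expected_bin)
  expect_equal(st$thickness, 2 * expected_bin + 1)
  opts <- plot_options()
  expect_equal(st$color, opts$palette[expected_bin + 1])
  # MFE arcs keep the thickness but take the dark-red colour
  stm <- bin_probability(0.95, is_mfe = TRUE)
  expect_equal(stm$thickness, 9)
  expect_equal(stm$color, opts$mfe_color)
  expect_error(bin_probability(1.2), "within")
  expect_error(bin_probability(-0.1), "within")
})

test_that("binning and thickness are monotone in probability", {
  p <- sort(runif(200))
  st <- bin_probability(p)
  expect_true(all(diff(st$bin) >= 0))
  expect_true(all(diff(st$thickness) >= 0))
})

test_that("ring layout spaces blocks evenly and angles increase with position", {
  lay <- ring_layout(4, gap_angle = 0)
  expect_equal(position_angle(1:4, lay), c(45, 135, 225, 315))
  lay20 <- ring_layout(100, gap_angle = 20)
  expect_equal(position_angle(1, lay20), 10 + lay20$block_width / 2)
  lay118 <- ring_layout(118)
  expect_true(all(diff(position_angle(1:118, lay118)) > 0))
  # blocks tile the circle minus the gap exactly
  expect_equal(lay118$block_width * 118, 360 - lay118$gap_angle)
  expect_error(position_angle(0, lay), "range")
  expect_error(position_angle(5, lay), "range")
})

test_that("chord control points interpolate between rim and centre by span", {
  lay <- ring_layout(100, radius = 100, gap_angle = 0)
  near <- chord_path(10, 14, lay)
  mid_near <- c((near$x1 + near$x2) / 2, (near$y1 + near$y2) / 2)
  expect_lt(sqrt((near$cx - mid_near[1])^2 + (near$cy - mid_near[2])^2), 5)
  far <- chord_path(1, 51, lay)
  expect_lt(sqrt(far$cx^2 + far$cy^2), 1e-6)  # diametral pair: centre
  # endpoint symmetry under (i, j) swap
  ab <- chord_path(3, 40, lay); ba <- chord_path(40, 3, lay)
  expect_equal(c(ab$x1, ab$y1, ab$x2, ab$y2), c(ba$x2, ba$y2, ba$x1, ba$y1))
  expect_equal(c(ab$cx, ab$cy), c(ba$cx, ba$cy))
  expect_error(chord_path(5, 5, lay), "differ")
})

test_that("rendered document contains blocks, arcs, legend and correct z-order", {
  f <- fold("GGGAAACCC")
  svg <- render_chordplot(f)
  doc <- read_svg(svg)
  blocks <- xml2::xml_find_all(doc, "//path[@class='base-block']")
  expect_length(blocks, 9)
  labels <- xml2::xml_text(xml2::xml_find_all(doc, "//text[starts-with(@class,'base-label')]"))
  expect_equal(paste(labels, collapse = ""), "GGGAAACCC")
  arcs <- xml2::xml_find_all(doc, "//path[@class='bpp-arc']")
  n_expected <- sum(f$bpp$p >= 0.01)
  expect_length(arcs, n_expected)
  expect_gte(length(arcs), 3)
  mfe_arcs <- xml2::xml_find_all(doc, "//path[@class='mfe-arc']")
  expect_length(mfe_arcs, 3)
  # z-order: every probability arc precedes every MFE arc in document order
  all_arcs <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//path[@class='bpp-arc' or @class='mfe-arc']"),
    "class")
  expect_identical(all_arcs, sort(all_arcs))
  # probability arcs are sorted ascending in p
  ps <- as.numeric(xml2::xml_attr(arcs, "data-p"))
  expect_true(all(diff(ps) >= 0))
  # legend lists the five ranges plus the MFE entry
  expect_length(xml2::xml_find_all(doc, "//g[@class='legend']"), 1)
  leg <- xml2::xml_text(xml2::xml_find_all(doc, "//text[@class='legend-label']"))
  expect_length(leg, 6)
  expect_true(all(c("[0.0, 0.2)", "[0.8, 1.0]") %in% leg))
  # title carries id, MFE and temperature
  title <- xml2::xml_text(xml2::xml_find_all(doc, "//text[@class='plot-title']"))
  expect_match(title, "MFE = -9.00")
  expect_match(title, "T = 37")
})

test_that("arc endpoints lie on the inner rim circle", {
  f <- fold("GGGGAAAACCCC")
  doc <- read_svg(render_chordplot(f))
  cx <- plot_options()$panel_size / 2; cy <- 310  # panel centre
  for (d in xml2::xml_attr(xml2::xml_find_all(doc, "//path[@class='bpp-arc']"), "d")) {
    v <- as.numeric(strsplit(d, "[ MQ]+")[[1]][-1])
    r1 <- sqrt((v[1] - cx)^2 + (v[2] - cy)^2)
    r2 <- sqrt((v[5] - cx)^2 + (v[6] - cy)^2)
    expect_equal(r1, 190, tolerance = 1e-6)
    expect_equal(r2, 190, tolerance = 1e-6)
  }
})

test_that("empty fold renders ring and legend with zero arcs", {
  f <- fold("AAAAAAAA")
  doc <- read_svg(render_chordplot(f))
  expect_length(xml2::xml_find_all(doc, "//path[@class='bpp-arc']"), 0)
  expect_length(xml2::xml_find_all(doc, "//path[@class='mfe-arc']"), 0)
  expect_length(xml2::xml_find_all(doc, "//path[@class='base-block']"), 8)
  expect_length(xml2::xml_find_all(doc, "//g[@class='legend']"), 1)
})

test_that("rendering is deterministic and bold positions mark differences", {
  f <- fold("GGGAAACCC")
  expect_identical(unclass(render_chordplot(f)), unclass(render_chordplot(f)))
  svg <- render_chordplot(f, bold_positions = c(2, 5))
  doc <- read_svg(svg)
  bold <- xml2::xml_find_all(doc, "//text[@class='base-label bold']")
  expect_length(bold, 2)
  expect_equal(xml2::xml_attr(bold, "font-weight"), rep("bold", 2))
})

test_that("comparison figure has two panels, one legend, per-side bolding", {
  fa <- fold("GGGAAACCCA")
  fb <- fold("GGGAAACCCU")
  aln <- smith_waterman(fa$sequence, fb$sequence)
  diffs <- infer_differences(aln)
  doc <- read_svg(render_comparison(fa, fb, diffs))
  expect_length(xml2::xml_find_all(doc, "//g[@class='panel']"), 2)
  expect_length(xml2::xml_find_all(doc, "//g[@class='legend']"), 1)
  bold <- xml2::xml_find_all(doc, "//text[@class='base-label bold']")
  expect_length(bold, length(diffs$a_positions) + length(diffs$b_positions))
  # identical inputs: no bold residues at all
  same <- infer_differences(smith_waterman(fa$sequence, fa$sequence))
  doc2 <- read_svg(render_comparison(fa, fa, same))
  expect_length(xml2::xml_find_all(doc2, "//text[@class='base-label bold']"), 0)
})

test_that("autoplot returns a ggplot without error", {
  p <- ggplot2::autoplot(fold("GGGAAACCC"))
  expect_s3_class(p, "ggplot")
})
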