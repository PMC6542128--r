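# Deterministic SVG generation: fixed element ordering and fixed-precision
# coordinates make identical inputs render to byte-identical documents.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_tag <- function(name, attrs = character(0), content = NULL) {
  a <- if (length(attrs)) {
    paste0(" ", paste(sprintf('%s="%s"', names(attrs), unname(attrs)),
                      collapse = " "))
  } else ""
  if (is.null(content)) {
    sprintf("<%s%s/>", name, a)
  } else {
    sprintf("<%s%s>%s</%s>", name, a, content, name)
  }
}

# annular wedge (one backbone block) from angle a0 to a1, radii r0 < r1
wedge_path <- function(a0, a1, r0, r1, cx, cy) {
  o0 <- angle_xy(a0, r1, cx, cy); o1 <- angle_xy(a1, r1, cx, cy)
  i0 <- angle_xy(a0, r0, cx, cy); i1 <- angle_xy(a1, r0, cx, cy)
  sprintf("M %s %s A %s %s 0 0 1 %s %s L %s %s A %s %s 0 0 0 %s %s Z",
          fmt_num(o0$x), fmt_num(o0$y), fmt_num(r1), fmt_num(r1),
          fmt_num(o1$x), fmt_num(o1$y), fmt_num(i1$x), fmt_num(i1$y),
          fmt_num(r0), fmt_num(r0), fmt_num(i0$x), fmt_num(i0$y))
}

# one circular panel (backbone ring + arcs + title) as SVG lines
panel_svg <- function(fold, opts, bold_positions = integer(0),
                      origin = c(0, 0), title = NULL) {
  seq <- fold$sequence
  n <- seq$length
  layout <- ring_layout(n, radius = 190, gap_angle = opts$gap_angle,
                        tick_every = opts$tick_every)
  cx <- origin[1] + opts$panel_size / 2
  cy <- origin[2] + 310
  ch <- seq_chars(seq)
  lines <- sprintf('<g class="panel" data-id="%s">', xml_escape(seq$id))

  title <- title %||% opts$title %||%
    sprintf("%s   MFE = %.2f %s   T = %g \u00b0C", seq$id, fold$mfe_value,
            fold$mfe_unit, fold$temperature_c)
  lines <- c(lines, svg_tag(
    "text",
    c(class = "plot-title", x = fmt_num(cx), y = fmt_num(origin[2] + 28),
      `text-anchor` = "middle", `font-size` = "14",
      `font-family` = "sans-serif"),
    xml_escape(title)))

  # outer layer: one coloured block per base, labelled with its letter
  r0 <- 193; r1 <- 215
  label_fs <- fmt_num(max(3, min(11, 0.75 * r0 * layout$block_width * pi / 180)))
  block_lines <- character(0)
  label_lines <- character(0)
  for (i in seq_len(n)) {
    a0 <- opts$gap_angle / 2 + (i - 1) * layout$block_width
    a1 <- a0 + layout$block_width
    block_lines <- c(block_lines, svg_tag("path", c(
      class = "base-block", d = wedge_path(a0, a1, r0, r1, cx, cy),
      fill = opts$base_colors[[ch[i]]], stroke = "#FFFFFF",
      `stroke-width` = "0.3")))
    lp <- angle_xy(position_angle(i, layout), (r0 + r1) / 2, cx, cy)
    bold <- i %in% bold_positions
    label_lines <- c(label_lines, svg_tag("text", c(
      class = if (bold) "base-label bold" else "base-label",
      x = fmt_num(lp$x), y = fmt_num(lp$y), `text-anchor` = "middle",
      dy = "0.35em", `font-size` = label_fs, `font-family` = "sans-serif",
      if (bold) c(`font-weight` = "bold")), ch[i]))
  }
  ticks <- unique(c(1L,
                    if (n >= layout$tick_every)
                      seq(layout$tick_every, n, by = layout$tick_every),
                    n))
  tick_lines <- vapply(ticks, function(i) {
    tp <- angle_xy(position_angle(i, layout), 232, cx, cy)
    svg_tag("text", c(class = "tick-label", x = fmt_num(tp$x),
                      y = fmt_num(tp$y), `text-anchor` = "middle",
                      dy = "0.35em", `font-size` = "8",
                      `font-family` = "sans-serif"), as.character(i))
  }, character(1))
  lines <- c(lines, '<g class="backbone">', block_lines, label_lines,
             tick_lines, "</g>")

  # inner layer: probability arcs in ascending-p order, then MFE arcs on top
  bpp <- fold$bpp
  bpp <- bpp[bpp$p >= opts$probability_cutoff, ]
  bpp <- bpp[order(bpp$p, bpp$i, bpp$j), ]
  arc_lines <- character(0)
  if (nrow(bpp) > 0) {
    style <- bin_probability(bpp$p, opts)
    for (k in seq_len(nrow(bpp))) {
      path <- chord_path(bpp$i[k], bpp$j[k], layout, cx, cy)
      arc_lines <- c(arc_lines, svg_tag("path", c(
        class = "bpp-arc", d = path$d, fill = "none",
        stroke = style$color[k], `stroke-width` = style$thickness[k],
        `stroke-opacity` = "0.75", `data-p` = fmt_num(bpp$p[k]),
        `data-bin` = style$bin[k])))
    }
  }
  mfe <- fold$mfe_structure
  if (nrow(mfe) > 0) {
    mp <- bpp_lookup(fold$bpp, mfe$i, mfe$j)
    style <- bin_probability(mp, opts, is_mfe = TRUE)
    for (k in seq_len(nrow(mfe))) {
      path <- chord_path(mfe$i[k], mfe$j[k], layout, cx, cy)
      arc_lines <- c(arc_lines, svg_tag("path", c(
        class = "mfe-arc", d = path$d, fill = "none",
        stroke = opts$mfe_color, `stroke-width` = style$thickness[k],
        `stroke-opacity` = "0.9", `data-p` = fmt_num(mp[k]))))
    }
  }
  c(lines, '<g class="arcs">', arc_lines, "</g>", "</g>")
}

# legend: five probability bins plus the MFE entry
legend_svg <- function(opts, origin = c(0, 0)) {
  x0 <- origin[1]; y0 <- origin[2]
  lines <- '<g class="legend">'
  lines <- c(lines, svg_tag("text", c(
    class = "legend-title", x = fmt_num(x0), y = fmt_num(y0),
    `font-size` = "11", `font-family` = "sans-serif"),
    "Base-pair probability"))
  labs <- bin_labels()
  for (k in 0:4) {
    lx <- x0 + k * 96
    lines <- c(lines,
      svg_tag("line", c(class = "legend-swatch", x1 = fmt_num(lx),
                        y1 = fmt_num(y0 + 14), x2 = fmt_num(lx + 26),
                        y2 = fmt_num(y0 + 14), stroke = opts$palette[k + 1],
                        `stroke-width` = 2 * k + 1)),
      svg_tag("text", c(class = "legend-label", x = fmt_num(lx + 30),
                        y = fmt_num(y0 + 17), `font-size` = "10",
                        `font-family` = "sans-serif"), labs[k + 1]))
  }
  c(lines,
    svg_tag("line", c(class = "legend-swatch mfe", x1 = fmt_num(x0),
                      y1 = fmt_num(y0 + 32), x2 = fmt_num(x0 + 26),
                      y2 = fmt_num(y0 + 32), stroke = opts$mfe_color,
                      `stroke-width` = "3")),
    svg_tag("text", c(class = "legend-label", x = fmt_num(x0 + 30),
                      y = fmt_num(y0 + 35), `font-size` = "10",
                      `font-family` = "sans-serif"),
            "MFE base pair (drawn on top)"),
    "</g>")
}

svg_document <- function(width, height, body) {
  paste(c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                         'width="%d" height="%d" viewBox="0 0 %d %d">'),
                  width, height, width, height),
          svg_tag("rect", c(x = "0", y = "0", width = as.character(width),
                            height = as.character(height), fill = "#FFFFFF")),
          body, "</svg>"),
        collapse = "\n")
}

#' Render the circular structure-and-probability chord plot
#'
#' Draws one sequence as a circular two-layer diagram: an outer ring of
#' colour-coded, letter-labelled base blocks with position ticks, and an
#' inner layer of chords -- one per base pair with ensemble probability at or
#' above the cutoff, coloured and weighted by probability bin, drawn in
#' ascending probability order, with the MFE pairing overlaid last in dark
#' red so the single most stable structure always sits on top of the
#' ensemble. A legend maps the five colours to their probability ranges.
#'
#' @param fold a [fold()] result.
#' @param opts a [plot_options()].
#' @param bold_positions 1-based residue positions rendered bold (sequence
#'   differences from a comparison).
#' @return The SVG document as a single string (class `svg_document`).
#' @examples
#' svg <- render_chordplot(fold("GGGAAACCC"))
#' @export
render_chordplot <- function(fold, opts = plot_options(),
                             bold_positions = integer(0)) {
  w <- opts$panel_size
  h <- 560 + 70
  body <- c(panel_svg(fold, opts, bold_positions = bold_positions),
            legend_svg(opts, origin = c((w - 480) / 2 + 10, 580)))
  structure(svg_document(w, h, body), class = c("svg_document", "character"))
}

#' Render the two-panel comparative figure
#'
#' Two chord plots side by side sharing a single legend; the left panel bolds
#' the difference positions of the first sequence, the right panel those of
#' the second. Per-panel titles carry each sequence's id and MFE.
#'
#' @param left,right [fold()] results for the two compared sequences.
#' @param diffs an [infer_differences()] set (left uses `a_positions`, right
#'   `b_positions`).
#' @param opts a [plot_options()].
#' @return The SVG document as a single string (class `svg_document`).
#' @export
render_comparison <- function(left, right, diffs, opts = plot_options()) {
  w <- 2 * opts$panel_size
  h <- 560 + 70
  body <- c(
    panel_svg(left, opts, bold_positions = diffs$a_positions,
              origin = c(0, 0)),
    panel_svg(right, opts, bold_positions = diffs$b_positions,
              origin = c(opts$panel_size, 0)),
    legend_svg(opts, origin = c((w - 480) / 2, 580))
  )
  structure(svg_document(w, h, body), class = c("svg_document", "character"))
}

#' @export
print.svg_document <- function(x, ...) {
  n <- length(strsplit(unclass(x), "\n", fixed = TRUE)[[1]])
  cat(sprintf("<svg_document> %d lines; write with write_svg()\n", n))
  invisible(x)
}

#' Write an SVG document to a file
#'
#' @param svg string returned by [render_chordplot()] or
#'   [render_comparison()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_svg <- function(svg, path) {
  writeLines(unclass(svg), path, useBytes = TRUE)
  invisible(path)
}
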