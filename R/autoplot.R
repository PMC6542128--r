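#' ggplot2 view of a fold result
#'
#' Convenience plot for interactive work: the same circular chord layout as
#' [render_chordplot()], drawn with ggplot2 (Bezier chords sampled as paths,
#' base letters on the rim). The SVG renderer remains the canonical,
#' byte-reproducible output; this view is for quick inspection in an R
#' session.
#'
#' @param object a [fold()] result.
#' @param opts a [plot_options()].
#' @param n_bezier points sampled per chord.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fold_result
#' @export
autoplot.fold_result <- function(object, opts = plot_options(),
                                 n_bezier = 40, ...) {
  seq <- object$sequence
  layout <- ring_layout(seq$length, radius = 1, gap_angle = opts$gap_angle)
  bezier_points <- function(i, j, grp, kind, styled) {
    path <- chord_path(i, j, layout)
    t <- seq(0, 1, length.out = n_bezier)
    tibble(
      x = (1 - t)^2 * path$x1 + 2 * (1 - t) * t * path$cx + t^2 * path$x2,
      y = -((1 - t)^2 * path$y1 + 2 * (1 - t) * t * path$cy + t^2 * path$y2),
      group = grp, kind = kind, color = styled$color,
      linewidth = styled$thickness / 4
    )
  }
  bpp <- object$bpp
  bpp <- bpp[bpp$p >= opts$probability_cutoff, ]
  bpp <- bpp[order(bpp$p, bpp$i, bpp$j), ]
  chords <- list()
  if (nrow(bpp) > 0) {
    st <- bin_probability(bpp$p, opts)
    chords <- purrr::map(seq_len(nrow(bpp)), function(k) {
      bezier_points(bpp$i[k], bpp$j[k], paste0("p", k), "ensemble", st[k, ])
    })
  }
  mfe <- object$mfe_structure
  if (nrow(mfe) > 0) {
    st <- bin_probability(bpp_lookup(object$bpp, mfe$i, mfe$j), opts,
                          is_mfe = TRUE)
    chords <- c(chords, purrr::map(seq_len(nrow(mfe)), function(k) {
      bezier_points(mfe$i[k], mfe$j[k], paste0("m", k), "mfe", st[k, ])
    }))
  }
  chord_df <- if (length(chords)) bind_rows(chords) else
    tibble(x = numeric(0), y = numeric(0), group = character(0),
           kind = character(0), color = character(0), linewidth = numeric(0))
  ring <- tibble(
    pos = seq_len(seq$length),
    base = seq_chars(seq),
    angle = position_angle(seq_len(seq$length), layout)
  )
  ring$x <- 1.08 * sin(ring$angle * pi / 180)
  ring$y <- 1.08 * cos(ring$angle * pi / 180)
  ggplot2::ggplot() +
    ggplot2::geom_path(
      data = chord_df,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$group,
                   colour = .data$color, linewidth = .data$linewidth),
      alpha = 0.8, lineend = "round") +
    ggplot2::geom_text(
      data = ring,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$base),
      size = max(1.5, min(3.2, 65 / seq$length))) +
    ggplot2::scale_colour_identity() +
    ggplot2::scale_linewidth_identity() +
    ggplot2::coord_equal(xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25)) +
    ggplot2::labs(title = sprintf("%s   MFE = %.2f %s   T = %g \u00b0C",
                                  seq$id, object$mfe_value, object$mfe_unit,
                                  object$temperature_c)) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5))
}
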