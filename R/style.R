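#' Plot options for chord diagrams
#'
#' Visual-encoding parameters. The five-colour palette covers the probability
#' interval `[0, 1]` in 0.2-unit bins, ordered blue (least stable) through
#' green (medium) to dark orange (most stable); the MFE pairing is always
#' drawn dark red on top. The specific hexes are configurable -- the contract
#' is the ordering and distinctness of the five bins.
#'
#' @param probability_cutoff minimum probability for an arc to be drawn.
#' @param palette five colours, low to high probability.
#' @param mfe_color colour of MFE arcs.
#' @param base_colors named colours for the A/C/G/U backbone blocks.
#' @param gap_angle degrees left open at 12 o'clock between the sequence ends.
#' @param tick_every position-label cadence.
#' @param panel_size side length (drawing units) of one circular panel.
#' @param title optional plot title; defaults to id, MFE and temperature.
#' @return An object of class `plot_options`.
#' @export
plot_options <- function(probability_cutoff = 0.01,
                         palette = c("#2166AC", "#67A9CF", "#1A9850",
                                     "#F46D43", "#D73027"),
                         mfe_color = "#8B0000",
                         base_colors = c(A = "#64C864", C = "#F0E442",
                                         G = "#E69F00", U = "#5AAEE0"),
                         gap_angle = 8, tick_every = 10,
                         panel_size = 520, title = NULL) {
  stopifnot(length(palette) == 5, !anyDuplicated(palette),
            probability_cutoff >= 0,
            all(c("A", "C", "G", "U") %in% names(base_colors)))
  structure(
    list(probability_cutoff = probability_cutoff, palette = palette,
         mfe_color = mfe_color, base_colors = base_colors,
         gap_angle = gap_angle, tick_every = tick_every,
         panel_size = panel_size, title = title),
    class = "plot_options"
  )
}

#' Probability-to-style binning
#'
#' Maps a base-pair probability onto one of five style bins: bin `k` covers
#' `[0.2k, 0.2(k + 1))` for `k < 4` and `[0.8, 1.0]` for `k = 4`. Arc colour
#' is the bin's palette entry and stroke thickness is `2k + 1` (1, 3, 5, 7,
#' 9), so weakly supported pairs draw thin and blue, strongly supported ones
#' thick and dark orange. MFE arcs keep the bin thickness but are forced to
#' the dark-red MFE colour.
#'
#' @param p probability in `[0, 1]` (vectorised).
#' @param opts a [plot_options()].
#' @param is_mfe does the arc belong to the MFE structure?
#' @return A tibble with columns `p`, `bin` (0-4), `color`, `thickness`,
#'   `is_mfe`.
#' @examples
#' bin_probability(c(0.1, 0.2, 1.0))
#' @export
bin_probability <- function(p, opts = plot_options(), is_mfe = FALSE) {
  if (any(is.na(p) | p < 0 | p > 1)) {
    stop("probability must lie within [0, 1]", call. = FALSE)
  }
  bin <- findInterval(p, c(0.2, 0.4, 0.6, 0.8))
  tibble(p = p, bin = bin,
         color = if (isTRUE(is_mfe)) rep(opts$mfe_color, length(p))
                 else opts$palette[bin + 1],
         thickness = 2 * bin + 1,
         is_mfe = isTRUE(is_mfe))
}

# legend labels for the five probability bins
bin_labels <- function() {
  c("[0.0, 0.2)", "[0.2, 0.4)", "[0.4, 0.6)", "[0.6, 0.8)", "[0.8, 1.0]")
}
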