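#' Circular ring layout for a sequence backbone
#'
#' Positions `1..n` tile the circle clockwise from 12 o'clock, leaving a gap
#' of `gap_angle` degrees at the top between positions `n` and `1` so the 5'
#' and 3' ends of the drawing are visually distinct (a linear molecule drawn
#' on a circle is not a circular molecule). Laying the backbone on a circle
#' compresses its horizontal extent by a factor of pi relative to a linear
#' arc diagram of the same arc length.
#'
#' @param n sequence length.
#' @param radius inner-rim radius (drawing units); arcs end on this circle.
#' @param gap_angle degrees reserved at 12 o'clock.
#' @param tick_every cadence of position labels (position 1 and `n` are
#'   always labelled).
#' @return An object of class `ring_layout`.
#' @export
ring_layout <- function(n, radius = 190, gap_angle = 8, tick_every = 10) {
  stopifnot(n >= 1, radius > 0, gap_angle >= 0, gap_angle < 360)
  structure(
    list(n = as.integer(n), radius = radius, gap_angle = gap_angle,
         block_width = (360 - gap_angle) / n,
         tick_every = as.integer(tick_every)),
    class = "ring_layout"
  )
}

#' Angle of a backbone position
#'
#' Midpoint angle of position `i`'s block, in degrees measured clockwise from
#' 12 o'clock; position 1 sits immediately clockwise of the gap.
#'
#' @param i position, `1 <= i <= n` (vectorised).
#' @param layout a [ring_layout()].
#' @return Angle(s) in degrees.
#' @examples
#' position_angle(1:4, ring_layout(4, gap_angle = 0))
#' @export
position_angle <- function(i, layout) {
  if (any(i < 1 | i > layout$n)) {
    stop(sprintf("position out of range 1..%d", layout$n), call. = FALSE)
  }
  layout$gap_angle / 2 + (i - 0.5) * layout$block_width
}

# polar (clockwise-from-12-o'clock) to cartesian, y growing downward (SVG)
angle_xy <- function(angle, r, cx = 0, cy = 0) {
  rad <- angle * pi / 180
  list(x = cx + r * sin(rad), y = cy - r * cos(rad))
}

#' Quadratic chord path between two backbone positions
#'
#' Connects the inner-rim midpoints of positions `i` and `j` with a quadratic
#' Bezier curve. The control point lies on the line from the circle centre to
#' the chord midpoint, pulled toward the centre by the factor
#' `f = span / n` with `span = min(|i - j|, n - |i - j|)`: short-range pairs
#' bow gently near the rim, long-range pairs sweep close to the centre.
#'
#' @param i,j distinct positions.
#' @param layout a [ring_layout()].
#' @param cx,cy circle centre.
#' @return A list with endpoint/control coordinates (`x1`, `y1`, `cx`, `cy`,
#'   `x2`, `y2`) and `d`, the SVG path data string.
#' @export
chord_path <- function(i, j, layout, cx = 0, cy = 0) {
  if (i == j) stop("chord endpoints must differ", call. = FALSE)
  p1 <- angle_xy(position_angle(i, layout), layout$radius, cx, cy)
  p2 <- angle_xy(position_angle(j, layout), layout$radius, cx, cy)
  span <- min(abs(i - j), layout$n - abs(i - j))
  f <- span / layout$n
  mx <- (p1$x + p2$x) / 2
  my <- (p1$y + p2$y) / 2
  qx <- cx + (1 - f) * (mx - cx)
  qy <- cy + (1 - f) * (my - cy)
  list(x1 = p1$x, y1 = p1$y, cx = qx, cy = qy, x2 = p2$x, y2 = p2$y,
       d = sprintf("M %s %s Q %s %s %s %s",
                   fmt_num(p1$x), fmt_num(p1$y), fmt_num(qx), fmt_num(qy),
                   fmt_num(p2$x), fmt_num(p2$y)))
}

# fixed-precision coordinate formatting keeps SVG output byte-reproducible
fmt_num <- function(x) sprintf("%.4f", x)
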