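#' Simplified base-pairing energy model
#'
#' The internal folding engine scores a structure as the sum of its pair
#' energies: one constant per pair type (GC, AU, GU wobble), in model units,
#' with no loop, stacking or dangle terms. The Boltzmann weight of a pair is
#' `exp(-e / kT_rel)` where `kT_rel = (273.15 + temperature_c) / 310.15`, so
#' at the reference temperature of 37 degrees Celsius a pair of energy `e`
#' weighs `exp(-e)`. Raising the temperature shrinks every weight towards 1
#' and melts structure, qualitatively reproducing thermal denaturation.
#'
#' @param pair_energy named numeric vector with elements `GC`, `AU`, `GU`
#'   (all `<= 0`, model units).
#' @param theta minimum hairpin size: a pair `(i, j)` requires `j - i > theta`.
#' @param temperature_c temperature in degrees Celsius.
#' @param allow_gu admit GU/UG wobble pairs?
#' @return An object of class `energy_model`.
#' @examples
#' energy_model(temperature_c = 70)
#' @export
energy_model <- function(pair_energy = c(GC = -3, AU = -2, GU = -1),
                         theta = 3, temperature_c = 37, allow_gu = TRUE) {
  stopifnot(all(c("GC", "AU", "GU") %in% names(pair_energy)),
            all(pair_energy <= 0), theta >= 0,
            is.numeric(temperature_c), length(temperature_c) == 1L)
  structure(
    list(pair_energy = pair_energy[c("GC", "AU", "GU")],
         theta = as.integer(theta),
         temperature_c = temperature_c,
         allow_gu = isTRUE(allow_gu)),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(
    "<energy_model> GC %g, AU %g, GU %s; theta = %d; T = %g C\n",
    x$pair_energy[["GC"]], x$pair_energy[["AU"]],
    if (x$allow_gu) sprintf("%g", x$pair_energy[["GU"]]) else "forbidden",
    x$theta, x$temperature_c))
  invisible(x)
}

# kT relative to 37 C, so Boltzmann weights are exp(-e) at 37 C
kt_rel <- function(temperature_c) (273.15 + temperature_c) / (273.15 + 37)

# canonical pair type of two bases, or NA
pair_type <- function(x, y) {
  xy <- paste0(x, y)
  type <- c(GC = "GC", CG = "GC", AU = "AU", UA = "AU",
            GU = "GU", UG = "GU")[xy]
  unname(type)
}

# energy of pair (x, y) under the model, NA if inadmissible by base identity
pair_energy_of <- function(x, y, model) {
  type <- pair_type(x, y)
  e <- rep(NA_real_, length(type))
  ok <- !is.na(type) & (model$allow_gu | type != "GU")
  e[ok] <- model$pair_energy[type[ok]]
  e
}

# n x n matrix of pair energies; +Inf where (i, j) is not admissible
# (wrong bases, GU when forbidden, or j - i <= theta)
energy_matrix <- function(seq, model) {
  ch <- seq_chars(seq)
  n <- length(ch)
  en <- matrix(Inf, n, n)
  if (n >= 2) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    idx <- idx[idx[, 2] - idx[, 1] > model$theta, , drop = FALSE]
    if (nrow(idx) > 0) {
      e <- pair_energy_of(ch[idx[, 1]], ch[idx[, 2]], model)
      en[idx] <- ifelse(is.na(e), Inf, e)
    }
  }
  en
}

# n x n matrix of Boltzmann weights; 0 where inadmissible
weight_matrix <- function(seq, model) {
  en <- energy_matrix(seq, model)
  w <- exp(-en / kt_rel(model$temperature_c))
  w[!is.finite(en)] <- 0
  w
}
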