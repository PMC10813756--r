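#' Density-to-material power laws
#'
#' The constitutive mapping used for vertebral bone: Young's modulus and
#' yield strain are power laws of apparent density,
#' \deqn{E = c_E \rho^{p_E}, \qquad
#'       \varepsilon_y = s \, c_y \rho^{p_y}, \qquad \nu = 0.3,}
#' with defaults \eqn{c_E = 3050} MPa, \eqn{p_E = 1.81},
#' \eqn{c_y = 0.0065}, \eqn{p_y = -1.42} for \eqn{\rho} in g/cm3.  The
#' yield stress follows as \eqn{\sigma_y = E \varepsilon_y}; post-yield
#' behaviour is perfectly plastic (no hardening).  `yield_scale` (\eqn{s})
#' is a dimensionless calibration factor on the yield strain (1 by
#' default; 3.1 is the value recovered by strength calibration against
#' compression experiments).  `ash_ratio` optionally converts the density
#' entering the laws (\eqn{\rho \to} `ash_ratio` \eqn{\cdot \rho}); it
#' defaults to 1 so the printed law is applied to apparent density
#' directly, and the conventional apparent/ash ratio 0.6 can be selected
#' explicitly in either direction.
#'
#' @param c_E,p_E modulus power law: coefficient (MPa at rho = 1 g/cm3)
#'   and exponent.
#' @param c_y,p_y yield-strain power law: coefficient (strain at rho = 1
#'   g/cm3) and exponent.
#' @param nu Poisson ratio, in (0, 0.5).
#' @param yield_scale dimensionless scale on the yield strain (> 0).
#' @param ash_ratio dimensionless density conversion applied before the
#'   power laws (> 0).
#' @return An object of class `material_law`.
#' @export
material_law <- function(c_E = 3050, p_E = 1.81, c_y = 0.0065, p_y = -1.42,
                         nu = 0.3, yield_scale = 1, ash_ratio = 1) {
  if (c_E <= 0 || c_y <= 0) stop("'c_E' and 'c_y' must be > 0")
  if (nu <= 0 || nu >= 0.5) stop("'nu' must lie in (0, 0.5)")
  if (yield_scale <= 0) stop("'yield_scale' must be > 0")
  if (ash_ratio <= 0) stop("'ash_ratio' must be > 0")
  structure(list(c_E = c_E, p_E = p_E, c_y = c_y, p_y = p_y, nu = nu,
                 yield_scale = yield_scale, ash_ratio = ash_ratio,
                 density_units = "g/cm3", modulus_units = "MPa"),
            class = "material_law")
}

#' @export
print.material_law <- function(x, ...) {
  cat(sprintf(
    "material_law: E = %g rho^%g MPa, eps_y = %g * %g rho^%g, nu = %g\n",
    x$c_E, x$p_E, x$yield_scale, x$c_y, x$p_y, x$nu))
  if (x$ash_ratio != 1)
    cat(sprintf("  density conversion: rho -> %g rho\n", x$ash_ratio))
  invisible(x)
}

check_rho <- function(rho) {
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("density must be finite and > 0")
  rho
}

#' Evaluate the material power laws
#'
#' `density_to_modulus` returns the Young's modulus in MPa,
#' `density_to_yield_strain` the (scaled) yield strain, and
#' `density_to_yield_stress` their product, the yield stress in MPa.
#' All are vectorised over `rho`.
#'
#' @param rho apparent density, g/cm3 (> 0).
#' @param law a [material_law()].
#' @return numeric vector, same length as `rho`.
#' @export
density_to_modulus <- function(rho, law = material_law()) {
  law$c_E * (law$ash_ratio * check_rho(rho))^law$p_E
}

#' @rdname density_to_modulus
#' @export
density_to_yield_strain <- function(rho, law = material_law()) {
  law$yield_scale * law$c_y * (law$ash_ratio * check_rho(rho))^law$p_y
}

#' @rdname density_to_modulus
#' @export
density_to_yield_stress <- function(rho, law = material_law()) {
  density_to_modulus(rho, law) * density_to_yield_strain(rho, law)
}

#' Assign per-element material cards
#'
#' Converts a per-element density vector into elastic-perfectly-plastic
#' material cards.  With `n_bins = NULL` every element gets a card
#' evaluated at its own density; otherwise densities are bucketed into
#' `n_bins` uniform-width bins over their range and each bin's card is
#' evaluated at the bin-mean density (the conventional discrete material
#' assignment of QCT-based models).
#'
#' @param density numeric vector of apparent densities, g/cm3, one per
#'   element.
#' @param law a [material_law()].
#' @param n_bins integer >= 1, or `NULL` for continuous assignment.
#' @return A data.frame of class `material_cards` with columns `element`,
#'   `rho`, `E` (MPa), `nu`, `sigma_y` (MPa), `bin`.
#' @export
assign_materials <- function(density, law = material_law(), n_bins = NULL) {
  check_rho(density)
  n <- length(density)
  if (is.null(n_bins)) {
    rho_eff <- density
    bin <- seq_len(n)
  } else {
    n_bins <- as.integer(n_bins)
    if (is.na(n_bins) || n_bins < 1L) stop("'n_bins' must be >= 1")
    rng <- range(density)
    if (rng[1] == rng[2] || n_bins == 1L) {
      bin <- rep(1L, n)
    } else {
      edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
      bin <- findInterval(density, edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
    }
    means <- tapply(density, bin, mean)
    rho_eff <- as.numeric(means[as.character(bin)])
  }
  out <- data.frame(element = seq_len(n), rho = rho_eff,
                    E = density_to_modulus(rho_eff, law),
                    nu = law$nu,
                    sigma_y = density_to_yield_stress(rho_eff, law),
                    bin = bin)
  class(out) <- c("material_cards", "data.frame")
  out
}

#' Rescale the yield stress of existing cards
#'
#' The yield-strain scale enters the yield stress linearly and the modulus
#' not at all, so cards computed at one scale can be re-used at another by
#' rescaling `sigma_y`.  Used heavily during scale calibration.
#'
#' @param cards a `material_cards` data.frame.
#' @param factor multiplicative factor applied to `sigma_y` (> 0).
#' @return The rescaled cards.
#' @export
rescale_yield <- function(cards, factor) {
  if (factor <= 0) stop("'factor' must be > 0")
  cards$sigma_y <- cards$sigma_y * factor
  cards
}

#' Write material cards as CSV
#'
#' @param cards a `material_cards` data.frame.
#' @param file output CSV path.
#' @export
write_material_cards <- function(cards, file) {
  utils::write.csv(cards[, c("element", "E", "nu", "sigma_y", "bin")],
                   file, row.names = FALSE)
  invisible(file)
}
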