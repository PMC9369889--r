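#' Density--elasticity power law parameters
#'
#' Bundles the four coefficients of the law linking Hounsfield units (HU) to
#' apparent density and Young modulus,
#' \deqn{E = a\,(c\,\mathrm{HU} + b)^d, \qquad \rho_{app} = c\,\mathrm{HU} + b,}
#' together with an upper admissibility bound `e_limit` on the modulus.
#' Apparent density is in kg/m^3 and the modulus in MPa.
#'
#' @param a Modulus scale, MPa per (kg/m^3)^d. Must be positive.
#' @param b Density offset, kg/m^3.
#' @param c Density per Hounsfield unit, kg/(m^3 HU). Must be positive.
#' @param d Dimensionless exponent. Must be positive.
#' @param e_limit Maximum admissible Young modulus, MPa. A parameter set is
#'   feasible when the modulus evaluated at the highest bin middle does not
#'   exceed this bound. The default 21000 MPa sits just above the upper end
#'   of compact-bone moduli reported in the literature.
#'
#' @return An object of class `material_law`.
#' @examples
#' law <- material_law(a = 0.388524, b = 4419.3, c = 2.20939, d = 1.17823)
#' young_modulus(1500, law)
#' @seealso [apparent_density()], [young_modulus()], [build_bin_table()]
#' @export
material_law <- function(a, b, c, d, e_limit = 21000) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d),
            length(a) == 1, length(b) == 1, length(c) == 1, length(d) == 1)
  if (a <= 0 || c <= 0 || d <= 0) {
    rlang::abort("`a`, `c` and `d` must all be positive.", class = "bonecal_invalid_input")
  }
  structure(list(a = a, b = b, c = c, d = d, e_limit = e_limit),
            class = "material_law")
}

#' @export
print.material_law <- function(x, ...) {
  cat("<material_law>  E = a * (c*HU + b)^d\n")
  cat(sprintf("  a = %g MPa/(kg/m^3)^d   b = %g kg/m^3\n", x$a, x$b))
  cat(sprintf("  c = %g kg/(m^3 HU)      d = %g\n", x$c, x$d))
  cat(sprintf("  E_limit = %g MPa\n", x$e_limit))
  invisible(x)
}

#' Hounsfield number from linear attenuation coefficients
#'
#' The Hounsfield scale expresses X-ray attenuation relative to water:
#' `1000 * (mu - mu_water) / mu_water`, so water maps to 0 HU and vacuum to
#' -1000 HU.
#'
#' @param mu Linear attenuation coefficient of the material (any consistent
#'   unit). Vectorised.
#' @param mu_water Linear attenuation coefficient of water, same unit.
#'   Must be positive.
#' @return Hounsfield unit value(s), dimensionless.
#' @examples
#' hounsfield_from_attenuation(0.38, 0.19)  # twice water -> 1000 HU
#' @export
hounsfield_from_attenuation <- function(mu, mu_water) {
  if (!is.numeric(mu_water) || length(mu_water) != 1 || !is.finite(mu_water) ||
      mu_water <= 0) {
    rlang::abort("`mu_water` must be a single positive number.",
                 class = "bonecal_invalid_input")
  }
  1000 * (mu - mu_water) / mu_water
}

#' Apparent density from Hounsfield units
#'
#' Evaluates the affine density calibration `rho_app = c*HU + b` of a
#' [material_law()].
#'
#' @param hu Hounsfield unit value(s).
#' @param law A [material_law()].
#' @return Apparent density in kg/m^3, same length as `hu`.
#' @export
apparent_density <- function(hu, law) {
  stopifnot(inherits(law, "material_law"))
  law$c * hu + law$b
}

#' Young modulus from Hounsfield units
#'
#' Evaluates `E = a*(c*HU + b)^d`. The base `c*HU + b` must be positive:
#' a fractional exponent of a non-positive density is undefined.
#'
#' @inheritParams apparent_density
#' @return Young modulus in MPa, same length as `hu`.
#' @export
young_modulus <- function(hu, law) {
  stopifnot(inherits(law, "material_law"))
  rho <- law$c * hu + law$b
  if (any(rho <= 0)) {
    rlang::abort(
      "Apparent density c*HU + b must be positive for every HU value.",
      class = "bonecal_invalid_input")
  }
  law$a * rho^law$d
}

#' Is a material law feasible under its modulus bound?
#'
#' A candidate coefficient set is admissible when the Young modulus evaluated
#' at the highest bin middle (the stiffest material actually assigned to any
#' element) stays at or below `e_limit`.
#'
#' @param law A [material_law()].
#' @param binning A [hu_binning()]; the highest middle is taken from it.
#' @return `TRUE` or `FALSE`.
#' @export
law_is_feasible <- function(law, binning = hu_binning()) {
  stopifnot(inherits(law, "material_law"), inherits(binning, "hu_binning"))
  hu_max <- max(binning$middles)
  rho <- law$c * hu_max + law$b
  if (rho <= 0) return(FALSE)
  young_modulus(hu_max, law) <= law$e_limit
}

#' Per-bin material table
#'
#' Evaluates the density--elasticity law at every bin middle of an HU binning,
#' yielding the per-range material table used to assign element properties:
#' one row per density range with its representative HU, apparent density,
#' Young modulus and Poisson ratio.
#'
#' @param binning A [hu_binning()].
#' @param law A [material_law()].
#' @param nu Poisson ratio assigned to every bin (dimensionless). Bone
#'   literature overwhelmingly uses 0.3; the ratio is not calibrated here.
#' @return A tibble with columns `bin`, `hu_lo`, `hu_hi`, `hu_middle`,
#'   `density` (kg/m^3), `modulus` (MPa) and `poisson`.
#' @examples
#' law <- material_law(0.388524, 4419.3, 2.20939, 1.17823)
#' build_bin_table(hu_binning(), law)
#' @export
build_bin_table <- function(binning, law, nu = 0.3) {
  stopifnot(inherits(binning, "hu_binning"), inherits(law, "material_law"))
  if (nu <= -1 || nu >= 0.5) {
    rlang::abort("Poisson ratio must lie in (-1, 0.5).", class = "bonecal_invalid_input")
  }
  mids <- binning$middles
  rho <- apparent_density(mids, law)
  if (any(rho <= 0)) {
    rlang::abort("A bin middle yields non-positive apparent density.",
                 class = "bonecal_invalid_input")
  }
  tibble::tibble(
    bin = seq_along(mids),
    hu_lo = c(-Inf, binning$edges),
    hu_hi = c(binning$edges, Inf),
    hu_middle = mids,
    density = rho,
    modulus = law$a * rho^law$d,
    poisson = nu
  )
}
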