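#' Stiffness from an experimental force-deflection curve
#'
#' Estimates bending stiffness as the ordinary-least-squares slope of force
#' against deflection restricted to the linear response window (0.2 to
#' 0.8 mm by convention), together with the coefficient of determination of
#' the fit. Window endpoints are inclusive; when no sample falls exactly on
#' an endpoint the curve is interpolated linearly there so the window is
#' always fully covered.
#'
#' @param curve Data frame with columns `deflection_mm` (non-decreasing) and
#'   `force_N`.
#' @param window Length-2 deflection window, mm.
#' @return A one-row tibble with columns `stiffness` (N/mm), `intercept`
#'   (N), `r_squared`, `window_lo`, `window_hi`, `n_points`.
#' @examples
#' d <- seq(0, 1, 0.05)
#' stiffness_from_curve(data.frame(deflection_mm = d, force_N = 5000 * d))
#' @export
stiffness_from_curve <- function(curve, window = c(0.2, 0.8)) {
  stopifnot(is.data.frame(curve),
            all(c("deflection_mm", "force_N") %in% names(curve)))
  d <- curve$deflection_mm
  f <- curve$force_N
  if (length(d) != length(f)) {
    rlang::abort("Deflection and force must have equal lengths.",
                 class = "bonecal_invalid_input")
  }
  if (any(diff(d) < 0)) {
    rlang::abort("Deflection samples must be non-decreasing.",
                 class = "bonecal_invalid_input")
  }
  inside <- d >= window[1] - 1e-12 & d <= window[2] + 1e-12
  if (sum(inside) < 2) {
    rlang::abort("Fewer than 2 samples inside the stiffness window.",
                 class = "bonecal_invalid_input")
  }
  dd <- d[inside]; ff <- f[inside]
  # Interpolate the endpoints when the sampling grid skips them.
  for (w in window) {
    if (!any(abs(dd - w) < 1e-12) && min(d) <= w && max(d) >= w) {
      ff <- c(ff, stats::approx(d, f, xout = w)$y)
      dd <- c(dd, w)
    }
  }
  if (length(unique(dd)) < 2) {
    rlang::abort("Fewer than 2 distinct in-window samples.",
                 class = "bonecal_invalid_input")
  }
  fit <- stats::lm(ff ~ dd)
  # summary() warns on exact fits; R^2 = 1 is a legitimate outcome here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble::tibble(
    stiffness = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    window_lo = window[1], window_hi = window[2],
    n_points = length(dd)
  )
}

#' Section properties of a rectangular bending sample
#'
#' Cross-sectional area, second moment of area about the bending plane and
#' section modulus of a rectangle of height `height` (the bent dimension)
#' and width `thickness`:
#' `P = A*B`, `I = B*A^3/12`, `W = 2*I/A`.
#'
#' @param height Section height A, mm. Vectorised.
#' @param thickness Section thickness B, mm. Vectorised.
#' @return A tibble with columns `height`, `thickness`, `area` (mm^2),
#'   `inertia` (mm^4), `section_modulus` (mm^3).
#' @examples
#' section_properties(11.58, 7.39)
#' @export
section_properties <- function(height, thickness) {
  if (any(height <= 0) || any(thickness <= 0)) {
    rlang::abort("`height` and `thickness` must be positive.",
                 class = "bonecal_invalid_input")
  }
  I <- thickness * height^3 / 12
  tibble::tibble(
    height = height, thickness = thickness,
    area = height * thickness,
    inertia = I,
    section_modulus = 2 * I / height
  )
}

#' Signed percent difference between experimental and simulated stiffness
#'
#' `100 * (k_exp - k_fea) / k_exp`: positive when the simulation is softer
#' than the experiment, negative when it is stiffer.
#'
#' @param k_exp Experimental stiffness, N/mm. Vectorised.
#' @param k_fea Simulated stiffness, N/mm. Vectorised.
#' @return Percent difference(s).
#' @examples
#' percent_difference(4080.1, 3901.9)
#' @export
percent_difference <- function(k_exp, k_fea) {
  if (any(k_exp == 0)) {
    rlang::abort("`k_exp` must be non-zero.", class = "bonecal_invalid_input")
  }
  100 * (k_exp - k_fea) / k_exp
}

#' Read a force-deflection curve from delimited text
#'
#' Expects a two-column delimited file with a header; columns are taken as
#' deflection in mm and force in N (extra columns are ignored). Recognised
#' names are matched loosely (`deflection_mm`/`deflection`/`d_mm`,
#' `force_N`/`force`/`f_N`); otherwise the first two columns are used.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return A tibble with columns `deflection_mm`, `force_N`.
#' @export
read_curve <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  dcol <- which(nm %in% c("deflection_mm", "deflection", "d_mm", "d"))[1]
  fcol <- which(nm %in% c("force_n", "force", "f_n", "f"))[1]
  if (is.na(dcol)) dcol <- 1L
  if (is.na(fcol)) fcol <- 2L
  tibble::tibble(deflection_mm = as.numeric(df[[dcol]]),
                 force_N = as.numeric(df[[fcol]]))
}

#' Write a force-deflection curve as CSV
#' @param curve Tibble with `deflection_mm`, `force_N`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(curve[, c("deflection_mm", "force_N")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
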