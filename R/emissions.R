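#' Annual CO2 emissions from exposure areas
#'
#' Converts time-averaged sidewall and bottom areas to an annual CO2
#' emission budget: `E = Sw x Ew + Sb x Eb`, with the sidewall and
#' bottom components reported separately and the per-plateau-area rate
#' increase `E / plateau_area` attached.
#'
#' @param budget An `area_budget` (from [time_averaged_areas()] or the
#'   `totals` of [catalog_area_budget()]), or a list/vector with
#'   `sidewall_area_m2` and `bottom_area_m2` entries.
#' @param constants A [model_constants()] object.
#' @return An `emission_budget` object: list with `total_emission_g`
#'   (g CO2 a^-1), `sidewall_component_g`, `bottom_component_g` and
#'   `per_area_rate_increase` (g CO2 m^-2 a^-1).
#' @examples
#' emissions_from_areas(list(sidewall_area_m2 = 1.80e9,
#'                           bottom_area_m2 = 0.17e9))
#' @export
emissions_from_areas <- function(budget, constants = model_constants()) {
  validate_constants(constants)
  sw <- as.numeric(budget[["sidewall_area_m2"]])
  sb <- as.numeric(budget[["bottom_area_m2"]])
  if (length(sw) != 1L || length(sb) != 1L || is.na(sw) || is.na(sb) ||
      sw < 0 || sb < 0) {
    stop("budget must carry single non-negative sidewall_area_m2 and ",
         "bottom_area_m2", call. = FALSE)
  }
  side <- sw * constants$sidewall_rate_Ew
  bot <- sb * constants$bottom_rate_Eb
  x <- list(
    total_emission_g = side + bot,
    sidewall_component_g = side,
    bottom_component_g = bot,
    per_area_rate_increase = (side + bot) / constants$plateau_area
  )
  class(x) <- "emission_budget"
  x
}

#' Per-plateau-area emission rate increase
#'
#' Spreads an annual emission total over the plateau area, giving the
#' increase in the area-averaged soil carbon emission rate.
#'
#' @param emission_g Annual emission, g CO2 a^-1.
#' @param constants A [model_constants()] object.
#' @return Rate increase, g CO2 m^-2 a^-1.
#' @export
per_area_rate <- function(emission_g, constants = model_constants()) {
  stopifnot(constants$plateau_area > 0)
  emission_g / constants$plateau_area
}

#' Emission as a percentage of a reference flux
#'
#' Expresses an annual emission as a percentage of a user-supplied
#' reference flux (e.g. a regional carbon sink or a provincial emission
#' inventory). A `(low, high)` reference range yields a percentage
#' range ordered low-to-high (the larger denominator gives the smaller
#' percentage).
#'
#' @param emission_g Annual emission, g CO2 a^-1.
#' @param reference_g Reference flux (single positive value) or a
#'   length-2 positive range, g CO2 a^-1.
#' @return A percentage, or a named vector `c(low = ..., high = ...)`.
#' @export
comparison_ratio <- function(emission_g, reference_g) {
  stopifnot(emission_g >= 0)
  if (any(!is.finite(reference_g)) || any(reference_g <= 0)) {
    stop("reference flux must be positive", call. = FALSE)
  }
  if (length(reference_g) == 1L) {
    100 * emission_g / reference_g
  } else if (length(reference_g) == 2L) {
    c(low = 100 * emission_g / max(reference_g),
      high = 100 * emission_g / min(reference_g))
  } else {
    stop("reference flux must be a single value or a (low, high) range",
         call. = FALSE)
  }
}

#' @export
print.emission_budget <- function(x, ...) {
  cat("Annual fissure CO2 emission budget\n")
  cat(sprintf("  sidewall component: %.3g g CO2/a\n", x$sidewall_component_g))
  cat(sprintf("  bottom component:   %.3g g CO2/a\n", x$bottom_component_g))
  cat(sprintf("  total:              %.3g g CO2/a\n", x$total_emission_g))
  cat(sprintf("  plateau rate increase: %.2f g CO2 m-2 a-1\n",
              x$per_area_rate_increase))
  invisible(x)
}
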