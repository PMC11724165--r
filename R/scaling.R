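#' Mean fissure-length range of a survey
#'
#' Averages the per-fault minimum and maximum fissure lengths of a
#' post-earthquake fissure survey, unweighted by fissure count: each
#' surveyed fault contributes one minimum and one maximum. On the Maduo
#' survey this gives the 76.6-942 m length range.
#'
#' @param survey A fissure survey data frame as returned by
#'   [read_survey()] or [table2_survey()], with columns `length_min_m`
#'   and `length_max_m`.
#' @return Named numeric vector `c(mean_min = ..., mean_max = ...)`, m.
#' @examples
#' mean_length_range(table2_survey())
#' @export
mean_length_range <- function(survey) {
  if (!is.data.frame(survey) || nrow(survey) == 0) {
    stop("survey must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(all(c("length_min_m", "length_max_m") %in% names(survey)))
  c(mean_min = mean(survey$length_min_m),
    mean_max = mean(survey$length_max_m))
}

#' Total fissure length of the Maduo earthquake
#'
#' Multiplies the representative single-fissure length by the surveyed
#' fissure count: 942 m x 653 fissures = 615,126 m for the defaults.
#'
#' @param unit_fissure_length Representative single-fissure length, m.
#' @param fissure_count Number of surveyed fissures.
#' @return Total fissure length, m.
#' @export
maduo_total_length <- function(unit_fissure_length, fissure_count) {
  stopifnot(unit_fissure_length > 0, fissure_count > 0)
  unit_fissure_length * fissure_count
}

# Coefficients of the two empirical magnitude scaling relations.
# M = 5.92 + 0.88 log10(l), l the surface-rupture length in km
# (regional magnitude-rupture-length regression for western China);
# M = 6.81 + 0.78 log10(W), W the average surface displacement in m,
# read here as the average fissure width.
.RUPTURE_A <- 5.92
.RUPTURE_B <- 0.88
.WIDTH_A <- 6.81
.WIDTH_B <- 0.78

#' Coseismic surface-rupture length from magnitude
#'
#' Inverts the empirical relation `M = 5.92 + 0.88 log10(l)` to obtain
#' the rupture length (km) of an earthquake from its magnitude. Used for
#' historical events whose rupture length was never measured.
#'
#' @param magnitude Earthquake magnitude (vectorized).
#' @return Rupture length, km.
#' @examples
#' rupture_length_from_magnitude(7.4)   # about 48.1 km
#' @export
rupture_length_from_magnitude <- function(magnitude) {
  stopifnot(all(is.finite(magnitude)))
  10^((magnitude - .RUPTURE_A) / .RUPTURE_B)
}

#' Magnitude from coseismic surface-rupture length
#'
#' Forward form of the magnitude-rupture-length relation; the exact
#' inverse of [rupture_length_from_magnitude()].
#'
#' @param rupture_length_km Rupture length, km (vectorized, positive).
#' @return Magnitude.
#' @export
magnitude_from_rupture_length <- function(rupture_length_km) {
  stopifnot(all(rupture_length_km > 0))
  .RUPTURE_A + .RUPTURE_B * log10(rupture_length_km)
}

#' Initial fissure width from magnitude
#'
#' Inverts the empirical relation `M = 6.81 + 0.78 log10(W)` to obtain
#' the average width (m) of the fissures opened by an earthquake of a
#' given magnitude.
#'
#' @param magnitude Earthquake magnitude (vectorized).
#' @return Average fissure width, m.
#' @examples
#' width_from_magnitude(6.9)   # about 1.30 m
#' @export
width_from_magnitude <- function(magnitude) {
  stopifnot(all(is.finite(magnitude)))
  10^((magnitude - .WIDTH_A) / .WIDTH_B)
}

#' Magnitude from average fissure width
#'
#' Forward form of the magnitude-width relation; the exact inverse of
#' [width_from_magnitude()].
#'
#' @param width_m Average fissure width, m (vectorized, positive).
#' @return Magnitude.
#' @export
magnitude_from_width <- function(width_m) {
  stopifnot(all(width_m > 0))
  .WIDTH_A + .WIDTH_B * log10(width_m)
}

#' Total fissure length of an earthquake from its rupture length
#'
#' Scales the Maduo total fissure length by the ratio of rupture
#' lengths: `Lk = (lk / lM) x LM`, where `LM` is the Maduo total
#' ([maduo_total_length()] of the constants) and `lM` the Maduo rupture
#' length.
#'
#' @param rupture_length_km Rupture length of the earthquake, km
#'   (vectorized, >= 0).
#' @param constants A [model_constants()] object.
#' @return Total fissure length, m.
#' @export
total_fissure_length <- function(rupture_length_km,
                                 constants = model_constants()) {
  validate_constants(constants)
  stopifnot(all(rupture_length_km >= 0))
  LM <- maduo_total_length(constants$unit_fissure_length_Lprime,
                           constants$maduo_fissure_count_NM)
  (rupture_length_km / constants$maduo_rupture_length_lM) * LM
}

#' Initial fissure geometry for a catalog event
#'
#' Composes the scaling chain for one earthquake at or above the
#' magnitude threshold: rupture length (recorded value if present,
#' otherwise derived from magnitude), total initial fissure length,
#' initial average width, and the recovery time after which the
#' representative fissure has healed completely.
#'
#' @param event One-row data frame (or list) with fields `magnitude` and
#'   optionally `rupture_length_km` (`NA` means not recorded).
#' @param constants A [model_constants()] object.
#' @return An object of class `fissure_geometry`: list with
#'   `initial_total_length_m`, `initial_width_m`, `rupture_length_km`,
#'   `recovery_time_a`.
#' @examples
#' ev <- list(magnitude = 6.9, rupture_length_km = NA)
#' geometry_for_event(ev)
#' @export
geometry_for_event <- function(event, constants = model_constants()) {
  validate_constants(constants)
  m <- as.numeric(event$magnitude)
  if (length(m) != 1L || !is.finite(m)) {
    stop("event must carry a single finite magnitude", call. = FALSE)
  }
  if (m < constants$magnitude_threshold) {
    stop("event magnitude ", m, " is below the threshold ",
         constants$magnitude_threshold, "; filter the catalog first",
         call. = FALSE)
  }
  lk <- event$rupture_length_km
  lk <- if (is.null(lk) || length(lk) == 0 || is.na(lk)) {
    rupture_length_from_magnitude(m)
  } else {
    as.numeric(lk)
  }
  if (lk <= 0) stop("rupture length must be positive", call. = FALSE)
  g <- list(
    initial_total_length_m = total_fissure_length(lk, constants),
    initial_width_m = width_from_magnitude(m),
    rupture_length_km = lk,
    recovery_time_a = recovery_time(constants)
  )
  class(g) <- "fissure_geometry"
  g
}

#' Fissure recovery time
#'
#' Time for the representative fissure (length `unit_fissure_length_Lprime`)
#' to shrink to zero at the length healing rate: `L' / rL`, about
#' 1922 years for the defaults. Infinite if the healing rate is zero.
#'
#' @param constants A [model_constants()] object.
#' @return Recovery time, years.
#' @export
recovery_time <- function(constants = model_constants()) {
  if (constants$length_heal_rate_rL == 0) {
    return(Inf)
  }
  constants$unit_fissure_length_Lprime / constants$length_heal_rate_rL
}

#' @export
print.fissure_geometry <- function(x, ...) {
  cat("Initial fissure geometry\n")
  cat(sprintf("  rupture length: %.2f km\n", x$rupture_length_km))
  cat(sprintf("  total fissure length: %.0f m\n", x$initial_total_length_m))
  cat(sprintf("  average width: %.3f m\n", x$initial_width_m))
  cat(sprintf("  recovery time: %.1f a\n", x$recovery_time_a))
  invisible(x)
}
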