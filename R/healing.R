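# Healing model: each event's total fissure length is treated as a set
# of identical representative fissures of length L' that shorten at rL,
# so the event total decays as Lk0 * (1 - t/t0) with t0 = L'/rL shared
# by all events. The alternative reading (the rL rate applied to the
# event TOTAL, t0 = Lk0/rL) is available via healing_model =
# "total_length"; both give a linear decay to zero, only the recovery
# time differs.

event_recovery_time <- function(geometry, constants,
                                healing_model = c("per_fissure",
                                                  "total_length")) {
  healing_model <- match.arg(healing_model)
  if (constants$length_heal_rate_rL == 0) return(Inf)
  switch(healing_model,
    per_fissure = recovery_time(constants),
    total_length = geometry$initial_total_length_m /
      constants$length_heal_rate_rL
  )
}

#' Fissure length at a given age
#'
#' Total open fissure length of an event `t` years after the earthquake:
#' a linear decay from the initial total to zero at the recovery time.
#'
#' @param geometry A `fissure_geometry` from [geometry_for_event()].
#' @param t Age since the earthquake, years (vectorized, >= 0).
#' @param constants A [model_constants()] object.
#' @param healing_model `"per_fissure"` (default): every representative
#'   fissure of length `unit_fissure_length_Lprime` shortens at the
#'   per-fissure healing rate, so all events recover after
#'   `L'/rL` years. `"total_length"`: the healing rate is applied to the
#'   event total instead.
#' @return Open fissure length, m.
#' @export
length_at_age <- function(geometry, t, constants = model_constants(),
                          healing_model = "per_fissure") {
  stopifnot(all(t >= 0))
  t0 <- event_recovery_time(geometry, constants, healing_model)
  frac <- if (is.infinite(t0)) rep(1, length(t)) else pmax(1 - t / t0, 0)
  geometry$initial_total_length_m * frac
}

#' Fissure width at a given age
#'
#' Average open fissure width `t` years after the earthquake: the
#' initial width plus linear widening as sidewall material slumps in,
#' truncated to zero once the fissure has fully recovered (an infilled
#' fissure has no exposed bottom).
#'
#' @inheritParams length_at_age
#' @return Average open width, m.
#' @export
width_at_age <- function(geometry, t, constants = model_constants(),
                         healing_model = "per_fissure") {
  stopifnot(all(t >= 0))
  t0 <- event_recovery_time(geometry, constants, healing_model)
  w <- geometry$initial_width_m + constants$width_widen_rate_rW * t
  w[t >= t0] <- 0
  w
}

#' Instantaneous exposed areas of an event's fissures
#'
#' Exposed soil areas at one moment, for a U-shaped cross-section:
#' sidewall area `2 x D x L(t)` (two vertical walls of depth D) and
#' bottom area `L(t) x W(t)`.
#'
#' @inheritParams length_at_age
#' @return Named numeric vector `c(sidewall_m2 = ..., bottom_m2 = ...)`
#'   for scalar `t`, or a two-column matrix for vector `t`.
#' @export
instantaneous_areas <- function(geometry, t, constants = model_constants(),
                                healing_model = "per_fissure") {
  L <- length_at_age(geometry, t, constants, healing_model)
  W <- width_at_age(geometry, t, constants, healing_model)
  sw <- 2 * constants$depth_D * L
  sb <- L * W
  if (length(t) == 1L) {
    c(sidewall_m2 = sw, bottom_m2 = sb)
  } else {
    cbind(sidewall_m2 = sw, bottom_m2 = sb)
  }
}

#' Time-averaged exposed areas of an event's fissures
#'
#' Averages the instantaneous sidewall and bottom areas over the time
#' elapsed since the earthquake, in closed form. With
#' `tau = min(T, t0)` (t0 the recovery time) and `L(t)` linear,
#' the sidewall integral is that of a linear function and the bottom
#' integral that of a quadratic:
#' \deqn{S_w = \frac{2 D L_0}{T}\left(\tau - \frac{\tau^2}{2 t_0}\right)}
#' \deqn{S_b = \frac{L_0}{T}\left(W_0\tau +
#'   \left(\frac{r_W}{2}-\frac{W_0}{2 t_0}\right)\tau^2 -
#'   \frac{r_W}{3 t_0}\tau^3\right)}
#' For events older than the recovery time the integrals are complete
#' and the averages decay as 1/T.
#'
#' @inheritParams length_at_age
#' @param elapsed_T Time since the earthquake, years (> 0).
#' @return An `area_budget` object: list with `sidewall_area_m2`,
#'   `bottom_area_m2`, `total_area_m2`, `elapsed_T_a`.
#' @export
time_averaged_areas <- function(geometry, elapsed_T,
                                constants = model_constants(),
                                healing_model = "per_fissure") {
  if (length(elapsed_T) != 1L || !is.finite(elapsed_T) || elapsed_T <= 0) {
    stop("elapsed_T must be a single positive number of years",
         call. = FALSE)
  }
  t0 <- event_recovery_time(geometry, constants, healing_model)
  inv_t0 <- if (is.infinite(t0)) 0 else 1 / t0
  tau <- min(elapsed_T, t0)
  L0 <- geometry$initial_total_length_m
  W0 <- geometry$initial_width_m
  rW <- constants$width_widen_rate_rW
  I_len <- tau - tau^2 * inv_t0 / 2
  I_bot <- W0 * tau + (rW / 2 - W0 * inv_t0 / 2) * tau^2 -
    (rW * inv_t0 / 3) * tau^3
  sw <- 2 * constants$depth_D * L0 * I_len / elapsed_T
  sb <- L0 * I_bot / elapsed_T
  area_budget(sw, sb, elapsed_T)
}

area_budget <- function(sidewall_area_m2, bottom_area_m2, elapsed_T_a) {
  stopifnot(sidewall_area_m2 >= 0, bottom_area_m2 >= 0)
  x <- list(
    sidewall_area_m2 = sidewall_area_m2,
    bottom_area_m2 = bottom_area_m2,
    total_area_m2 = sidewall_area_m2 + bottom_area_m2,
    elapsed_T_a = elapsed_T_a
  )
  class(x) <- "area_budget"
  x
}

#' @export
print.area_budget <- function(x, ...) {
  cat("Time-averaged fissure exposure areas\n")
  cat(sprintf("  sidewall: %.4g m^2\n", x$sidewall_area_m2))
  cat(sprintf("  bottom:   %.4g m^2\n", x$bottom_area_m2))
  cat(sprintf("  total:    %.4g m^2 (averaged over %s a)\n",
              x$total_area_m2,
              if (is.na(x$elapsed_T_a)) "per-event" else
                format(x$elapsed_T_a)))
  invisible(x)
}

#' Time-averaged exposure areas for a whole catalog
#'
#' Computes per-event time-averaged sidewall and bottom areas (each
#' event averaged over its own elapsed time `reference_year - year`)
#' and sums them into catalog totals.
#'
#' Events dated in the reference year itself contribute their initial
#' (instantaneous) areas, the limit of the time average as the elapsed
#' time goes to zero.
#'
#' @param events Catalog data frame, already filtered to the magnitude
#'   threshold (see [filter_by_threshold()]).
#' @param constants A [model_constants()] object.
#' @param healing_model Passed to [time_averaged_areas()].
#' @return A list with `totals` (an `area_budget` with `elapsed_T_a =
#'   NA`, totals summed over events) and `per_event` (a data frame with
#'   one row per event: id, year, magnitude, rupture length, initial
#'   geometry, elapsed time and time-averaged areas).
#' @export
catalog_area_budget <- function(events, constants = model_constants(),
                                healing_model = "per_fissure") {
  validate_catalog(events)
  n <- nrow(events)
  if (any(events$year > constants$reference_year)) {
    bad <- which(events$year > constants$reference_year)[1]
    stop("event '", events$event_id[bad], "' (year ", events$year[bad],
         ") postdates the reference year ", constants$reference_year,
         call. = FALSE)
  }
  if (any(events$magnitude < constants$magnitude_threshold)) {
    stop("catalog contains events below the magnitude threshold; ",
         "apply filter_by_threshold() first", call. = FALSE)
  }
  per <- data.frame(
    event_id = character(n), year = integer(n), magnitude = numeric(n),
    rupture_length_km = numeric(n), initial_total_length_m = numeric(n),
    initial_width_m = numeric(n), elapsed_T_a = numeric(n),
    sidewall_area_m2 = numeric(n), bottom_area_m2 = numeric(n),
    total_area_m2 = numeric(n), stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    ev <- events[i, ]
    g <- geometry_for_event(ev, constants)
    T_k <- constants$reference_year - ev$year
    if (T_k > 0) {
      b <- time_averaged_areas(g, T_k, constants, healing_model)
    } else {
      a0 <- instantaneous_areas(g, 0, constants, healing_model)
      b <- area_budget(a0[["sidewall_m2"]], a0[["bottom_m2"]], 0)
    }
    per$event_id[i] <- ev$event_id
    per$year[i] <- ev$year
    per$magnitude[i] <- ev$magnitude
    per$rupture_length_km[i] <- g$rupture_length_km
    per$initial_total_length_m[i] <- g$initial_total_length_m
    per$initial_width_m[i] <- g$initial_width_m
    per$elapsed_T_a[i] <- T_k
    per$sidewall_area_m2[i] <- b$sidewall_area_m2
    per$bottom_area_m2[i] <- b$bottom_area_m2
    per$total_area_m2[i] <- b$total_area_m2
  }
  totals <- area_budget(sum(per$sidewall_area_m2),
                        sum(per$bottom_area_m2), NA_real_)
  list(totals = totals, per_event = per)
}
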