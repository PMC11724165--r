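# Seeded synthetic-data generators. All generators are pure functions
# of their arguments: the same arguments and seed reproduce the output
# exactly, and the caller's RNG state is left untouched.

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic earthquake catalog
#'
#' Draws event magnitudes from a doubly truncated Gutenberg-Richter
#' distribution (density proportional to `10^(-b M)` on the magnitude
#' range) and event years uniformly over the year range. A configurable
#' fraction of events carries an explicit coseismic surface-rupture
#' length, drawn around the magnitude-rupture-length relation with
#' lognormal scatter; the rest leave the rupture length unrecorded, as
#' in historical catalogs.
#'
#' @param n_events Number of events (>= 1).
#' @param magnitude_range Length-2 vector `(min, max)`, within
#'   `[5, 9.5]`.
#' @param gr_b_value Gutenberg-Richter b-value (> 0).
#' @param year_range Length-2 vector of astronomical years `(min, max)`
#'   (326 B.C. is -325).
#' @param rupture_length_policy Fraction of events carrying an explicit
#'   rupture length, in `[0, 1]`.
#' @param seed Integer seed; same seed, same catalog.
#' @return A catalog data frame accepted by the catalog validators
#'   (columns `event_id`, `year`, `magnitude`, `rupture_length_km`).
#' @examples
#' head(generate_catalog(5, seed = 1))
#' @export
generate_catalog <- function(n_events,
                             magnitude_range = c(6.9, 8.5),
                             gr_b_value = 1,
                             year_range = c(-325, 2022),
                             rupture_length_policy = 0.5,
                             seed = 1) {
  stopifnot(n_events >= 1, length(magnitude_range) == 2,
            magnitude_range[1] < magnitude_range[2],
            magnitude_range[1] >= 5, magnitude_range[2] <= 9.5,
            gr_b_value > 0, length(year_range) == 2,
            year_range[1] <= year_range[2],
            rupture_length_policy >= 0, rupture_length_policy <= 1)
  with_local_seed(seed, {
    beta <- gr_b_value * log(10)
    m0 <- magnitude_range[1]
    m1 <- magnitude_range[2]
    u <- stats::runif(n_events)
    # inverse CDF of the truncated exponential on [m0, m1]
    mag <- m0 - log(1 - u * (1 - exp(-beta * (m1 - m0)))) / beta
    year <- sample(seq(year_range[1], year_range[2]), n_events,
                   replace = TRUE)
    has_lk <- stats::runif(n_events) < rupture_length_policy
    lk <- rep(NA_real_, n_events)
    if (any(has_lk)) {
      lk[has_lk] <- rupture_length_from_magnitude(mag[has_lk]) *
        stats::rlnorm(sum(has_lk), meanlog = 0, sdlog = 0.1)
    }
    out <- data.frame(
      event_id = sprintf("SYN%04d", seq_len(n_events)),
      year = as.integer(year),
      magnitude = round(mag, 2),
      rupture_length_km = lk,
      stringsAsFactors = FALSE
    )
    validate_catalog(out)
    out
  })
}

#' Generate a synthetic chamber flux campaign
#'
#' Simulates hourly chamber measurements over the 8:00-17:00 window
#' with three replicates per timepoint. The expected flux of each group
#' is the control mean times the group's multiplier times a diurnal
#' factor (half-sinusoid over the window, peaking at 13:00, matching
#' the midday maximum of solar-driven soil warming). Replicate noise is
#' multiplicative lognormal with unit mean and the given coefficient of
#' variation.
#'
#' @param n_days Number of measurement days.
#' @param group_multipliers Named vector mapping group labels to their
#'   expected flux as a multiple of the control mean; must include
#'   `control`. The defaults reproduce the measured sidewall and bottom
#'   fractions of the uncracked-surface rate.
#' @param control_mean_flux Control-group mean flux, umol CO2 m^-2
#'   s^-1. The default annualizes to the measured uncracked-surface
#'   rate of about 1525 g CO2 m^-2 a^-1.
#' @param diurnal_amplitude Fractional amplitude of the diurnal cycle.
#' @param noise_cv Replicate coefficient of variation, in `[0, 1)`.
#' @param seed Integer seed.
#' @param campaign Campaign label.
#' @param start_date First measurement date (ISO-8601).
#' @return A flux record data frame accepted by
#'   [collapse_replicates()] and [summarize_groups()].
#' @examples
#' camp <- generate_campaign(n_days = 2, noise_cv = 0, seed = 1)
#' summarize_groups(camp)
#' @export
generate_campaign <- function(n_days = 30,
                              group_multipliers = c(control = 1,
                                                    sidewall = 0.6351,
                                                    bottom = 0.3376),
                              control_mean_flux = 1.0987,
                              diurnal_amplitude = 0.3,
                              noise_cv = 0.2,
                              seed = 1,
                              campaign = "synthetic",
                              start_date = "2022-04-01") {
  stopifnot(n_days >= 1, all(group_multipliers > 0),
            "control" %in% names(group_multipliers),
            control_mean_flux > 0,
            diurnal_amplitude >= 0, diurnal_amplitude < 1,
            noise_cv >= 0, noise_cv < 1)
  with_local_seed(seed, {
    dates <- format(as.Date(start_date) + seq_len(n_days) - 1L)
    grid <- expand.grid(
      replicate = 1:3, hour = MEASUREMENT_HOURS, date = dates,
      group = names(group_multipliers),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    diurnal <- 1 + diurnal_amplitude * sin(pi * (grid$hour - 8) / 10)
    expected <- control_mean_flux *
      group_multipliers[grid$group] * diurnal
    noise <- if (noise_cv == 0) {
      1
    } else {
      sdlog <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    out <- data.frame(
      campaign = campaign,
      group = grid$group,
      date = grid$date,
      hour = grid$hour,
      replicate = grid$replicate,
      flux_umol_m2_s = as.numeric(expected * noise),
      stringsAsFactors = FALSE
    )
    validate_flux_records(out)
    out
  })
}

#' The Maduo fissure survey table
#'
#' The published per-fault fissure survey of the 2021 Maduo earthquake:
#' 653 fissures along five active faults, with per-fault fissure counts
#' and length ranges. This is the anchor dataset of the scaling chain
#' (mean length range 76.6-942 m; total length 615,126 m).
#'
#' @return A survey data frame with columns `fault_name`,
#'   `fissure_count`, `length_min_m`, `length_max_m`.
#' @examples
#' sum(table2_survey()$fissure_count)   # 653
#' @export
table2_survey <- function() {
  s <- data.frame(
    fault_name = c("Maduo-Gande fault", "Maqu-Duoqueshan fault",
                   "Kamuka fault", "Kunlun-Jiangcuo fault",
                   "Southern edge of Gande fault"),
    fissure_count = c(35L, 75L, 12L, 451L, 80L),
    length_min_m = c(16, 280, 50, 35, 2),
    length_max_m = c(300, 2200, 760, 800, 650),
    stringsAsFactors = FALSE
  )
  validate_survey(s)
  s
}
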