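# Chamber campaign processing. Input records are one chamber
# measurement each: campaign, group label (control, sidewall, bottom,
# or a width-x-depth test-group code), ISO date, hour of day within the
# 8:00-17:00 measurement window, replicate 1-3, and the instantaneous
# flux in umol CO2 m-2 s-1.

MEASUREMENT_HOURS <- 8:17
CO2_G_PER_UMOL <- 44.01e-6
SECONDS_PER_YEAR <- 365 * 24 * 3600

#' Read chamber flux records
#'
#' Reads a CSV of soil chamber CO2 flux measurements with columns
#' `campaign`, `group`, `date` (ISO-8601), `hour`, `replicate`,
#' `flux_umol_m2_s`.
#'
#' @param path Path to a CSV file with header.
#' @return A validated data frame of flux records.
#' @export
read_flux_records <- function(path) {
  if (!file.exists(path)) stop("flux file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("campaign", "group", "date", "hour", "replicate",
                "flux_umol_m2_s")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("flux file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_flux_records(x)
  x
}

validate_flux_records <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (any(records$flux_umol_m2_s < 0)) {
    stop("negative flux value at record ",
         which(records$flux_umol_m2_s < 0)[1], call. = FALSE)
  }
  if (!all(records$hour %in% MEASUREMENT_HOURS)) {
    bad <- which(!records$hour %in% MEASUREMENT_HOURS)[1]
    stop("record ", bad, " has hour ", records$hour[bad],
         " outside the 8:00-17:00 measurement window", call. = FALSE)
  }
  if (!all(records$replicate %in% 1:3)) {
    stop("replicate numbers must be in {1, 2, 3}", call. = FALSE)
  }
  invisible(records)
}

#' Collapse replicate measurements to timepoint means
#'
#' Averages the (up to three) replicate chamber readings taken at each
#' (campaign, group, date, hour) timepoint, mirroring the field
#' protocol of measuring three chambers and taking the mean. Timepoints
#' with fewer than three replicates are averaged as-is with a warning;
#' more than three replicates at one timepoint is an error.
#'
#' @param records Flux record data frame (see [read_flux_records()]).
#' @return A data frame with one row per timepoint: `campaign`,
#'   `group`, `date`, `hour`, `n_replicates`, `flux_umol_m2_s` (the
#'   replicate mean).
#' @export
collapse_replicates <- function(records) {
  validate_flux_records(records)
  key <- interaction(records$campaign, records$group, records$date,
                     records$hour, drop = TRUE, lex.order = TRUE)
  n_rep <- tapply(records$replicate, key, length)
  if (any(n_rep > 3)) {
    stop("more than 3 replicates at timepoint ",
         names(n_rep)[which(n_rep > 3)[1]], call. = FALSE)
  }
  if (any(n_rep < 3)) {
    warning(sum(n_rep < 3), " timepoint(s) have fewer than 3 replicates; ",
            "averaging the available readings", call. = FALSE)
  }
  first <- !duplicated(key)
  out <- data.frame(
    campaign = records$campaign[first],
    group = records$group[first],
    date = records$date[first],
    hour = records$hour[first],
    n_replicates = as.integer(n_rep[as.character(key[first])]),
    flux_umol_m2_s = as.numeric(
      tapply(records$flux_umol_m2_s, key, mean)[as.character(key[first])]
    ),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Convert a mean chamber flux to an annual emission rate
#'
#' Converts umol CO2 m^-2 s^-1 to g CO2 m^-2 a^-1 assuming the campaign
#' mean represents the annual mean: molar mass 44.01 g mol^-1 and a
#' 365-day year (31,536,000 s). A mean flux of 1 umol m^-2 s^-1 is
#' about 1387.9 g CO2 m^-2 a^-1.
#'
#' @param mean_flux Mean flux, umol CO2 m^-2 s^-1 (vectorized, >= 0).
#' @return Annual emission rate, g CO2 m^-2 a^-1.
#' @export
annualize_flux <- function(mean_flux) {
  stopifnot(all(mean_flux >= 0))
  mean_flux * CO2_G_PER_UMOL * SECONDS_PER_YEAR
}

#' Summarize a chamber campaign by measurement group
#'
#' Collapses replicates, averages each group's timepoint means (all
#' timepoints weighted equally), annualizes, and reports each group's
#' annual rate as a fraction of the control group's. The control group
#' (label `"control"`) must be present.
#'
#' @param records Flux record data frame; may span several campaigns,
#'   which are pooled (subset beforehand for per-campaign summaries).
#' @return A data frame with one row per group: `group`,
#'   `n_timepoints`, `mean_flux_umol_m2_s`, `annual_rate_g_m2_a`,
#'   `ratio_to_control`. The control row has ratio 1.
#' @export
summarize_groups <- function(records) {
  tp <- collapse_replicates(records)
  if (!"control" %in% tp$group) {
    stop("no 'control' group present; cannot form ratios", call. = FALSE)
  }
  groups <- unique(tp$group)
  mean_flux <- vapply(groups, function(g) {
    mean(tp$flux_umol_m2_s[tp$group == g])
  }, numeric(1))
  n_tp <- vapply(groups, function(g) sum(tp$group == g), integer(1))
  annual <- annualize_flux(mean_flux)
  out <- data.frame(
    group = groups,
    n_timepoints = n_tp,
    mean_flux_umol_m2_s = mean_flux,
    annual_rate_g_m2_a = annual,
    ratio_to_control = annual / annual[groups == "control"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
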