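# Pipeline entry points, wiring the stages in estimation order:
# filter -> per-event geometry -> healing / time-averaged areas ->
# emission budget. Each run writes a manifest (input digests, config,
# seed, package version) sufficient to reproduce it.

run_manifest <- function(inputs = character(), constants = NULL,
                         seed = NULL) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(normalizePath(inputs)))
  } else {
    list()
  }
  list(
    package = "fissureflux",
    version = as.character(utils::packageVersion("fissureflux")),
    inputs = digests,
    constants = if (!is.null(constants)) unclass(constants),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full emission-budget estimation
#'
#' Reads an earthquake catalog, filters it to the magnitude threshold,
#' computes per-event time-averaged exposure areas and the catalog
#' emission budget, and writes three files to `out_dir`: `report.json`
#' (totals, per-area rate increase, optional reference comparisons),
#' `per_event.csv` (one row per retained event) and `manifest.json`.
#' Stage-boundary progress (event counts, area totals) is logged to
#' standard error.
#'
#' @param catalog_path Path to a catalog CSV (see [read_catalog()]).
#' @param config_path Optional constants config file (see
#'   [load_constants()]).
#' @param out_dir Output directory, created if needed.
#' @param reference_fluxes Optional named list of reference fluxes
#'   (g CO2 a^-1; single values or `(low, high)` ranges) to express the
#'   budget against as percentages.
#' @param healing_model Passed to [catalog_area_budget()].
#' @return Invisibly, a list with `areas`, `emissions`, `summary` (the
#'   report list) and the paths written.
#' @export
run_estimate <- function(catalog_path, config_path = NULL,
                         out_dir = ".", reference_fluxes = NULL,
                         healing_model = "per_fissure") {
  constants <- load_constants(config_path)
  events <- read_catalog(catalog_path)
  message("read ", nrow(events), " events from ", catalog_path)
  kept <- filter_by_threshold(events, constants)
  message(nrow(kept), " events at or above M ",
          constants$magnitude_threshold)
  if (nrow(kept) > 0) {
    areas <- catalog_area_budget(kept, constants, healing_model)
  } else {
    areas <- list(totals = area_budget(0, 0, NA_real_),
                  per_event = data.frame())
  }
  message(sprintf("time-averaged areas: sidewall %.4g m^2, bottom %.4g m^2",
                  areas$totals$sidewall_area_m2,
                  areas$totals$bottom_area_m2))
  emis <- emissions_from_areas(areas$totals, constants)
  message(sprintf("annual emission budget: %.4g g CO2/a",
                  emis$total_emission_g))
  comparisons <- if (!is.null(reference_fluxes)) {
    lapply(reference_fluxes, function(ref) {
      cr <- comparison_ratio(emis$total_emission_g, unlist(ref))
      if (length(cr) == 1) unname(cr) else as.list(cr)
    })
  }
  report <- list(
    n_events_input = nrow(events),
    n_events_retained = nrow(kept),
    sidewall_area_m2 = areas$totals$sidewall_area_m2,
    bottom_area_m2 = areas$totals$bottom_area_m2,
    total_area_m2 = areas$totals$total_area_m2,
    sidewall_emission_g_a = emis$sidewall_component_g,
    bottom_emission_g_a = emis$bottom_component_g,
    total_emission_g_a = emis$total_emission_g,
    per_area_rate_increase_g_m2_a = emis$per_area_rate_increase,
    comparisons_percent = comparisons
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report_path <- file.path(out_dir, "report.json")
  write_json(report, report_path)
  csv_path <- file.path(out_dir, "per_event.csv")
  utils::write.csv(areas$per_event, csv_path, row.names = FALSE)
  inputs <- c(catalog_path, if (!is.null(config_path)) config_path)
  manifest_path <- file.path(out_dir, "manifest.json")
  write_json(run_manifest(inputs, constants), manifest_path)
  invisible(list(areas = areas, emissions = emis, summary = report,
                 paths = c(report = report_path, per_event = csv_path,
                           manifest = manifest_path)))
}

#' Summarize a chamber campaign from file
#'
#' Reads chamber flux records, summarizes them by measurement group
#' (see [summarize_groups()]), and writes `group_summary.csv` and a
#' manifest to `out_dir`.
#'
#' @param measurements_path Path to a flux record CSV.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the group summary data frame.
#' @export
run_chamber <- function(measurements_path, out_dir = ".") {
  records <- read_flux_records(measurements_path)
  message("read ", nrow(records), " flux records from ", measurements_path)
  summary <- summarize_groups(records)
  message("summarized ", nrow(summary), " measurement groups")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summary, file.path(out_dir, "group_summary.csv"),
                   row.names = FALSE)
  write_json(run_manifest(measurements_path),
             file.path(out_dir, "manifest.json"))
  invisible(summary)
}

#' Generate synthetic inputs from a spec file
#'
#' Reads a YAML spec describing a synthetic catalog and/or campaign and
#' writes the generated CSV files (in the dialects the readers accept)
#' plus a manifest to `out_dir`. Spec keys: a `catalog` mapping with
#' the arguments of [generate_catalog()] and/or a `campaign` mapping
#' with the arguments of [generate_campaign()]; a top-level `seed`
#' applies to both unless overridden inside.
#'
#' @param spec_path Path to the YAML spec.
#' @param out_dir Output directory, created if needed.
#' @param seed Optional seed overriding the spec's.
#' @return Invisibly, named character vector of files written.
#' @export
run_simulate <- function(spec_path, out_dir = ".", seed = NULL) {
  spec <- yaml::read_yaml(spec_path)
  top_seed <- if (!is.null(seed)) seed else spec$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if (!is.null(spec$catalog)) {
    args <- spec$catalog
    if (is.null(args$seed)) args$seed <- if (!is.null(top_seed)) top_seed else 1
    for (f in c("magnitude_range", "year_range")) {
      if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
    }
    cat_df <- do.call(generate_catalog, args)
    p <- file.path(out_dir, "catalog.csv")
    write_catalog(cat_df, p)
    message("wrote ", nrow(cat_df), "-event catalog to ", p)
    written["catalog"] <- p
  }
  if (!is.null(spec$campaign)) {
    args <- spec$campaign
    if (is.null(args$seed)) args$seed <- if (!is.null(top_seed)) top_seed else 1
    if (!is.null(args$group_multipliers)) {
      args$group_multipliers <- unlist(args$group_multipliers)
    }
    camp <- do.call(generate_campaign, args)
    p <- file.path(out_dir, "campaign.csv")
    utils::write.csv(camp, p, row.names = FALSE)
    message("wrote ", nrow(camp), " flux records to ", p)
    written["campaign"] <- p
  }
  write_json(run_manifest(spec_path, seed = top_seed),
             file.path(out_dir, "manifest.json"))
  invisible(written)
}
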