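#' Read an earthquake catalog
#'
#' Reads a CSV earthquake catalog with columns `event_id`, `year`,
#' `magnitude` and optional `rupture_length_km` (km; empty or `NA` when
#' not recorded). Years follow astronomical numbering (1 B.C. is year 0,
#' 326 B.C. is -325); alternatively an `era` column with values `BC` or
#' `AD` may accompany positive years and is converted on read
#' (`326,BC` becomes -325).
#'
#' @param path Path to a CSV file with a header row.
#' @return A data frame with columns `event_id` (character), `year`
#'   (integer, astronomical), `magnitude` (numeric) and
#'   `rupture_length_km` (numeric, `NA` when absent), one row per event
#'   in file order.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  required <- c("event_id", "year", "magnitude")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("catalog '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  parse_num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & nzchar(trimws(raw[[col]])) & is.na(v))
    if (length(bad) > 0) {
      stop("unparseable ", what, " in catalog '", path, "' at data row ",
           bad[1], " (file line ", bad[1] + 1L, "): '",
           raw[[col]][bad[1]], "'", call. = FALSE)
    }
    v
  }
  year <- parse_num("year", "year")
  magnitude <- parse_num("magnitude", "magnitude")
  if (anyNA(year) || anyNA(magnitude)) {
    bad <- which(is.na(year) | is.na(magnitude))[1]
    stop("missing year or magnitude in catalog '", path, "' at data row ",
         bad, call. = FALSE)
  }
  if ("era" %in% names(raw)) {
    era <- toupper(trimws(raw$era))
    era[!nzchar(era)] <- "AD"
    if (!all(era %in% c("BC", "AD"))) {
      stop("era column values must be 'BC' or 'AD'", call. = FALSE)
    }
    if (any(era == "BC" & year <= 0)) {
      stop("BC years must be entered as positive calendar years ",
           "when an era column is used", call. = FALSE)
    }
    year <- ifelse(era == "BC", -(year - 1), year)
  }
  rl <- if ("rupture_length_km" %in% names(raw)) {
    parse_num("rupture_length_km", "rupture length")
  } else {
    rep(NA_real_, n)
  }
  out <- data.frame(
    event_id = as.character(raw$event_id),
    year = as.integer(year),
    magnitude = magnitude,
    rupture_length_km = rl,
    stringsAsFactors = FALSE
  )
  validate_catalog(out)
  out
}

validate_catalog <- function(events) {
  stopifnot(is.data.frame(events))
  req <- c("event_id", "year", "magnitude", "rupture_length_km")
  missing <- setdiff(req, names(events))
  if (length(missing) > 0) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(events) == 0) return(invisible(events))
  bad_mag <- which(events$magnitude < 5 | events$magnitude > 9.5)
  if (length(bad_mag) > 0) {
    stop("event '", events$event_id[bad_mag[1]], "' has magnitude ",
         events$magnitude[bad_mag[1]],
         " outside the supported range [5, 9.5]", call. = FALSE)
  }
  bad_rl <- which(!is.na(events$rupture_length_km) &
                    events$rupture_length_km <= 0)
  if (length(bad_rl) > 0) {
    stop("event '", events$event_id[bad_rl[1]],
         "' has non-positive rupture length", call. = FALSE)
  }
  dup <- unique(events$event_id[duplicated(events$event_id)])
  if (length(dup) > 0) {
    warning("duplicate event_id(s) in catalog: ",
            paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(events)
}

#' Write an earthquake catalog
#'
#' Writes a catalog data frame in the CSV dialect [read_catalog()]
#' accepts, so reading the file back reproduces the catalog.
#'
#' @param events Catalog data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(events, path) {
  validate_catalog(events)
  utils::write.csv(
    events[, c("event_id", "year", "magnitude", "rupture_length_km")],
    path, row.names = FALSE, quote = FALSE, na = ""
  )
  invisible(path)
}

#' Read a fissure survey table
#'
#' Reads a per-fault fissure survey as CSV with columns `fault_name`,
#' `fissure_count`, `length_min_m`, `length_max_m`. The packaged
#' Maduo survey ([table2_survey()]) is the reference instance.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated data frame, one row per surveyed fault.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("fault_name", "fissure_count", "length_min_m", "length_max_m")
  missing <- setdiff(required, names(s))
  if (length(missing) > 0) {
    stop("survey '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_survey(s)
  s
}

validate_survey <- function(survey) {
  stopifnot(is.data.frame(survey), nrow(survey) > 0)
  bad <- which(survey$length_min_m <= 0 |
                 survey$length_min_m > survey$length_max_m)
  if (length(bad) > 0) {
    stop("survey record '", survey$fault_name[bad[1]],
         "' has an invalid length range (need 0 < min <= max)",
         call. = FALSE)
  }
  if (any(survey$fissure_count < 1)) {
    bad <- which(survey$fissure_count < 1)[1]
    stop("survey record '", survey$fault_name[bad],
         "' has fissure_count < 1", call. = FALSE)
  }
  invisible(survey)
}

#' Filter a catalog by the magnitude threshold
#'
#' Keeps events with magnitude greater than or equal to the threshold
#' in the constants (inclusive comparison), preserving row order.
#'
#' @param events Catalog data frame.
#' @param constants A [model_constants()] object.
#' @return The filtered catalog.
#' @export
filter_by_threshold <- function(events, constants = model_constants()) {
  validate_catalog(events)
  events[events$magnitude >= constants$magnitude_threshold, , drop = FALSE]
}
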