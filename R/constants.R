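#' Model constants for the fissure carbon-emission model
#'
#' Builds the full set of fixed parameters used throughout the estimation
#' chain. All other functions in the package take a `model_constants`
#' object rather than hard-coding values, so sensitivity runs only need a
#' modified constants set.
#'
#' @param sidewall_rate_Ew Annual soil CO2 emission rate of fissure
#'   sidewalls, g CO2 m^-2 a^-1.
#' @param bottom_rate_Eb Annual emission rate of fissure bottoms,
#'   g CO2 m^-2 a^-1.
#' @param uncracked_rate Annual emission rate of undisturbed (uncracked)
#'   surface soil, g CO2 m^-2 a^-1.
#' @param depth_D Assumed fissure depth, m. Soil organic carbon on the
#'   plateau is concentrated in the top 3 m, hence the default.
#' @param length_heal_rate_rL Rate at which a single fissure shortens as
#'   it heals, m a^-1.
#' @param width_widen_rate_rW Rate at which a fissure widens as sidewall
#'   material slumps into it, m a^-1.
#' @param unit_fissure_length_Lprime Representative single-fissure
#'   length, m (upper bound of the Maduo survey length range).
#' @param maduo_fissure_count_NM Number of fissures surveyed after the
#'   Maduo earthquake.
#' @param maduo_magnitude Magnitude anchoring the Maduo rupture length.
#' @param maduo_rupture_length_lM Coseismic surface-rupture length of the
#'   Maduo earthquake, km. If `NULL` (default), derived from
#'   `maduo_magnitude` through the magnitude-rupture-length relation
#'   (about 48.1 km at M 7.4).
#' @param magnitude_threshold Minimum magnitude retained in catalog
#'   analyses; comparisons are inclusive (M >= threshold).
#' @param plateau_area Area of the Qinghai-Tibet Plateau, m^2.
#' @param reference_year Astronomical year taken as "now" when computing
#'   elapsed times (1 B.C. is year 0, so 326 B.C. is -325).
#' @return An object of class `model_constants`: a validated named list
#'   with the fields above, `maduo_rupture_length_lM` always resolved to
#'   a number.
#' @examples
#' cst <- model_constants()
#' cst$depth_D
#' model_constants(depth_D = 1.9)$depth_D
#' @export
model_constants <- function(sidewall_rate_Ew = 968.53,
                            bottom_rate_Eb = 514.79,
                            uncracked_rate = 1524.95,
                            depth_D = 3.0,
                            length_heal_rate_rL = 0.49,
                            width_widen_rate_rW = 0.05,
                            unit_fissure_length_Lprime = 942.0,
                            maduo_fissure_count_NM = 653,
                            maduo_magnitude = 7.4,
                            maduo_rupture_length_lM = NULL,
                            magnitude_threshold = 6.9,
                            plateau_area = 2.57e12,
                            reference_year = 2022) {
  if (is.null(maduo_rupture_length_lM)) {
    maduo_rupture_length_lM <- rupture_length_from_magnitude(maduo_magnitude)
  }
  x <- list(
    sidewall_rate_Ew = as.numeric(sidewall_rate_Ew),
    bottom_rate_Eb = as.numeric(bottom_rate_Eb),
    uncracked_rate = as.numeric(uncracked_rate),
    depth_D = as.numeric(depth_D),
    length_heal_rate_rL = as.numeric(length_heal_rate_rL),
    width_widen_rate_rW = as.numeric(width_widen_rate_rW),
    unit_fissure_length_Lprime = as.numeric(unit_fissure_length_Lprime),
    maduo_fissure_count_NM = as.numeric(maduo_fissure_count_NM),
    maduo_magnitude = as.numeric(maduo_magnitude),
    maduo_rupture_length_lM = as.numeric(maduo_rupture_length_lM),
    magnitude_threshold = as.numeric(magnitude_threshold),
    plateau_area = as.numeric(plateau_area),
    reference_year = as.numeric(reference_year)
  )
  class(x) <- "model_constants"
  validate_constants(x)
  x
}

# Fields that must be strictly positive. Healing rates may be zero (no
# healing, a useful limiting case) but not negative.
.positive_fields <- c(
  "sidewall_rate_Ew", "bottom_rate_Eb", "uncracked_rate", "depth_D",
  "unit_fissure_length_Lprime", "maduo_fissure_count_NM",
  "maduo_rupture_length_lM", "plateau_area"
)
.nonnegative_fields <- c("length_heal_rate_rL", "width_widen_rate_rW")

validate_constants <- function(x) {
  stopifnot(inherits(x, "model_constants"))
  for (f in names(x)) {
    v <- x[[f]]
    if (length(v) != 1L || !is.finite(v)) {
      stop("constant '", f, "' must be a single finite number", call. = FALSE)
    }
  }
  for (f in .positive_fields) {
    if (x[[f]] <= 0) {
      stop("constant '", f, "' must be strictly positive (got ", x[[f]], ")",
           call. = FALSE)
    }
  }
  for (f in .nonnegative_fields) {
    if (x[[f]] < 0) {
      stop("constant '", f, "' must be non-negative (got ", x[[f]], ")",
           call. = FALSE)
    }
  }
  if (x$magnitude_threshold < 5 || x$magnitude_threshold > 9.5) {
    stop("constant 'magnitude_threshold' must lie in [5, 9.5] (got ",
         x$magnitude_threshold, ")", call. = FALSE)
  }
  # The measured ordering bottom < sidewall < uncracked holds for the
  # defaults; a user override that breaks it is suspicious but allowed.
  if (x$sidewall_rate_Ew >= x$uncracked_rate ||
      x$bottom_rate_Eb >= x$sidewall_rate_Ew) {
    warning("emission-rate ordering bottom_rate_Eb < sidewall_rate_Ew < ",
            "uncracked_rate does not hold for these constants",
            call. = FALSE)
  }
  invisible(x)
}

#' Load model constants from a configuration file
#'
#' Reads a flat key-value configuration file (YAML or JSON) and overlays
#' it on the defaults of [model_constants()]. Keys must match the
#' constant names exactly; unknown keys are rejected so typos cannot
#' silently leave a default in place.
#'
#' @param path Path to a YAML or JSON file, or `NULL` for pure defaults.
#' @return A validated `model_constants` object.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("depth_D: 1.9", cfg)
#' load_constants(cfg)$depth_D
#' @export
load_constants <- function(path = NULL) {
  if (is.null(path)) {
    return(model_constants())
  }
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  vals <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop("failed to parse config file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (length(vals) == 0) {
    return(model_constants())
  }
  if (is.null(names(vals)) || any(names(vals) == "")) {
    stop("config file '", path, "' must be a flat key-value mapping",
         call. = FALSE)
  }
  known <- names(formals(model_constants))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(model_constants, vals)
}

#' Save model constants to a YAML file
#'
#' Writes every field of a constants set as a flat key-value YAML file
#' readable by [load_constants()]. Loading the saved file reproduces the
#' constants exactly.
#'
#' @param constants A `model_constants` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_constants <- function(constants, path) {
  validate_constants(constants)
  yaml::write_yaml(unclass(constants), path, precision = 15L)
  invisible(path)
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Fissure carbon-emission model constants\n")
  cat(sprintf("  emission rates (g CO2 m-2 a-1): sidewall %.2f, bottom %.2f, uncracked %.2f\n",
              x$sidewall_rate_Ew, x$bottom_rate_Eb, x$uncracked_rate))
  cat(sprintf("  fissure depth D: %g m; healing: length -%g m/a, width +%g m/a\n",
              x$depth_D, x$length_heal_rate_rL, x$width_widen_rate_rW))
  cat(sprintf("  Maduo anchor: %d fissures x %g m; M %g, rupture %.2f km\n",
              as.integer(x$maduo_fissure_count_NM),
              x$unit_fissure_length_Lprime, x$maduo_magnitude,
              x$maduo_rupture_length_lM))
  cat(sprintf("  magnitude threshold >= %g; plateau area %.3g m^2; reference year %d\n",
              x$magnitude_threshold, x$plateau_area,
              as.integer(x$reference_year)))
  invisible(x)
}
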