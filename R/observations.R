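#' @keywords internal
"_PACKAGE"

## Enumerations used across the package. Definitions follow the ICD viability
## thresholds: GA28 = >=28 completed weeks' gestation (the reporting standard),
## GA22 = >=22 weeks, BW1000 = >=1000 g, BW500 = >=500 g birthweight.
sbr_definitions <- function() c("GA28", "GA22", "BW1000", "BW500", "UNSPECIFIED")
sbr_source_types <- function() c("ADMIN", "HMIS", "SURVEY", "STUDY")
sbr_income_groups <- function() c("LIC", "LMIC_GROUP", "UMIC", "HIC")

obs_columns <- function() {
  c("country_code", "year", "sbr_observed", "definition", "source_type",
    "n_total_births", "n_stillbirths", "nmr_same_source",
    "unknown_ga_fraction", "livebirth_coverage", "child_death_completeness")
}

cov_columns <- function() c("country_code", "year", "nmr", "lbw", "anc4", "csec", "edu", "gni")

births_columns <- function() c("country_code", "year", "livebirths", "region_code", "income_group")

#' Default estimation window
#'
#' Inclusive calendar-year window over which rates are estimated. Years label
#' calendar years with a mid-year reference point.
#' @return Integer vector of length 2.
#' @export
default_window <- function() c(2000L, 2019L)

stop_row <- function(row, col, msg) {
  stop(sprintf("row %d, column '%s': %s", row, col, msg), call. = FALSE)
}

#' Validate a table of stillbirth-rate observations
#'
#' Checks column presence and types, domain constraints (rates positive,
#' fractions in \[0,1\]), consistency of the observed rate with reported counts
#' (|sbr − 1000·stillbirths/total| < 0.05 when both counts are present), and
#' uniqueness of (country, year, source, definition). Rows outside `window`
#' are dropped with a message.
#'
#' @param df data.frame with the observation schema (see [obs_columns()]).
#' @param window inclusive year range, default [default_window()].
#' @return The validated, canonically sorted data.frame (class
#'   `sbr_observations`).
#' @export
validate_sbr_observations <- function(df, window = default_window()) {
  cols <- obs_columns()
  if (!identical(sort(intersect(names(df), cols)), sort(cols))) {
    missing <- setdiff(cols, names(df))
    stop("observation table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, cols]
  df$country_code <- as.character(df$country_code)
  df$definition <- as.character(df$definition)
  df$source_type <- as.character(df$source_type)
  num_cols <- setdiff(cols, c("country_code", "definition", "source_type"))
  for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])
  df$year <- as.integer(df$year)

  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.na(r$country_code) || !nzchar(r$country_code) || nchar(r$country_code) != 3L)
      stop_row(i, "country_code", "must be a 3-letter ISO3 code")
    if (is.na(r$year)) stop_row(i, "year", "missing or non-integer")
    if (is.na(r$sbr_observed) || r$sbr_observed <= 0)
      stop_row(i, "sbr_observed", "must be > 0 (stillbirths per 1000 total births)")
    if (!r$definition %in% sbr_definitions())
      stop_row(i, "definition", paste("must be one of", paste(sbr_definitions(), collapse = "/")))
    if (!r$source_type %in% sbr_source_types())
      stop_row(i, "source_type", paste("must be one of", paste(sbr_source_types(), collapse = "/")))
    if (!is.na(r$n_total_births) && r$n_total_births <= 0)
      stop_row(i, "n_total_births", "must be a positive count")
    if (!is.na(r$n_stillbirths) && r$n_stillbirths < 0)
      stop_row(i, "n_stillbirths", "must be a non-negative count")
    if (!is.na(r$n_total_births) && !is.na(r$n_stillbirths)) {
      implied <- 1000 * r$n_stillbirths / r$n_total_births
      if (abs(r$sbr_observed - implied) >= 0.05)
        stop_row(i, "sbr_observed",
                 sprintf("inconsistent with counts (implied %.4f)", implied))
    }
    if (!is.na(r$nmr_same_source) && r$nmr_same_source <= 0)
      stop_row(i, "nmr_same_source", "must be > 0 when present")
    for (fc in c("unknown_ga_fraction", "livebirth_coverage", "child_death_completeness")) {
      v <- r[[fc]]
      if (!is.na(v) && (v < 0 || v > 1)) stop_row(i, fc, "must lie in [0, 1]")
    }
  }

  inside <- df$year >= window[1] & df$year <= window[2]
  if (any(!inside)) {
    message(sum(!inside), " observation(s) outside window [",
            window[1], ", ", window[2], "] dropped")
    df <- df[inside, , drop = FALSE]
  }

  key <- paste(df$country_code, df$year, df$source_type, df$definition, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicated (country, year, source, definition): ", dup, call. = FALSE)
  }

  df <- df[order(df$country_code, df$year, df$source_type, df$definition), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sbr_observations", "data.frame")
  df
}

#' Read stillbirth-rate observations from CSV
#'
#' @param path CSV file with header exactly matching the observation schema
#'   (UTF-8, "." decimal separator).
#' @inheritParams validate_sbr_observations
#' @return Validated `sbr_observations` data.frame; a message reports the row
#'   count read.
#' @export
read_sbr_observations <- function(path, window = default_window()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!identical(names(df), obs_columns()))
    stop("header of ", path, " does not match the observation schema", call. = FALSE)
  message("read ", nrow(df), " observation rows from ", path)
  validate_sbr_observations(df, window)
}

#' Write stillbirth-rate observations to CSV
#' @param df `sbr_observations` (or compatible data.frame).
#' @param path output file.
#' @export
write_sbr_observations <- function(df, path) {
  utils::write.csv(as.data.frame(df)[, obs_columns()], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_rectangular <- function(df, what) {
  countries <- sort(unique(df$country_code))
  years <- sort(unique(df$year))
  key <- paste(df$country_code, df$year)
  if (anyDuplicated(key)) stop(what, ": duplicated (country, year) cell", call. = FALSE)
  full <- as.vector(outer(countries, years, paste))
  miss <- setdiff(full, key)
  if (length(miss))
    stop(what, ": missing cell(s): ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Validate a covariate table
#'
#' Requires a complete rectangular country-by-year grid; `nmr`, `lbw` and
#' `gni` must be strictly positive (they enter the model on the log scale)
#' and `anc4`/`csec` must be fractions in \[0, 1\].
#' @param df data.frame with columns [cov_columns()].
#' @return Canonically sorted data.frame of class `sbr_covariates`.
#' @export
validate_covariate_table <- function(df) {
  cols <- cov_columns()
  if (!all(cols %in% names(df)))
    stop("covariate table missing columns: ",
         paste(setdiff(cols, names(df)), collapse = ", "), call. = FALSE)
  df <- df[, cols]
  df$country_code <- as.character(df$country_code)
  df$year <- as.integer(df$year)
  for (cc in c("nmr", "lbw", "gni")) {
    bad <- which(!is.finite(df[[cc]]) | df[[cc]] <= 0)
    if (length(bad))
      stop_row(bad[1], cc, "must be strictly positive (log-transform domain)")
  }
  for (cc in c("anc4", "csec")) {
    bad <- which(!is.finite(df[[cc]]) | df[[cc]] < 0 | df[[cc]] > 1)
    if (length(bad)) stop_row(bad[1], cc, "must lie in [0, 1]")
  }
  if (any(!is.finite(df$edu))) stop("edu contains non-finite values", call. = FALSE)
  check_rectangular(df, "covariate table")
  df <- df[order(df$country_code, df$year), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sbr_covariates", "data.frame")
  df
}

#' Read a covariate table from CSV
#' @param path CSV file with columns [cov_columns()].
#' @return `sbr_covariates` data.frame.
#' @export
read_covariate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_covariate_table(utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#"))
}

#' @rdname read_covariate_table
#' @param df covariate table.
#' @export
write_covariate_table <- function(df, path) {
  utils::write.csv(as.data.frame(df)[, cov_columns()], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a livebirths table
#'
#' Livebirth counts per country-year with regional grouping and World Bank
#' income group. The count unit (default "thousands") travels as an attribute
#' and is written as a `# livebirths_unit:` comment line.
#' @param df data.frame with columns [births_columns()].
#' @param unit character, unit of the `livebirths` column.
#' @return Canonically sorted data.frame of class `sbr_births` with attribute
#'   `livebirths_unit`.
#' @export
validate_births_table <- function(df, unit = "thousands") {
  cols <- births_columns()
  if (!all(cols %in% names(df)))
    stop("births table missing columns: ",
         paste(setdiff(cols, names(df)), collapse = ", "), call. = FALSE)
  df <- df[, cols]
  df$country_code <- as.character(df$country_code)
  df$year <- as.integer(df$year)
  df$region_code <- as.character(df$region_code)
  df$income_group <- as.character(df$income_group)
  if (any(!is.finite(df$livebirths) | df$livebirths <= 0))
    stop("livebirths must be > 0 for every (country, year)", call. = FALSE)
  bad <- setdiff(unique(df$income_group), sbr_income_groups())
  if (length(bad))
    stop("unknown income_group value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  check_rectangular(df, "births table")
  df <- df[order(df$country_code, df$year), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "livebirths_unit") <- unit
  class(df) <- c("sbr_births", "data.frame")
  df
}

#' Read a livebirths table from CSV
#' @param path CSV file with columns [births_columns()]; an optional leading
#'   `# livebirths_unit: <unit>` comment records the count unit.
#' @return `sbr_births` data.frame.
#' @export
read_births_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  unit <- "thousands"
  if (grepl("^#\\s*livebirths_unit:", first))
    unit <- trimws(sub("^#\\s*livebirths_unit:", "", first))
  validate_births_table(
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#"),
    unit = unit)
}

#' @rdname read_births_table
#' @param df births table.
#' @export
write_births_table <- function(df, path) {
  unit <- attr(df, "livebirths_unit")
  if (is.null(unit)) unit <- "thousands"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# livebirths_unit: ", unit), con)
  utils::write.table(as.data.frame(df)[, births_columns()], con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
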