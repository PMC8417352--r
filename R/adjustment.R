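## Definitional adjustment: conversion of stillbirth rates reported under
## alternative viability thresholds (>=22 weeks, >=1000 g, >=500 g) to the
## >=28-weeks-gestation reporting standard, with propagated uncertainty.
## Adjustments pool high-income countries (HIC) separately from a single
## low/middle-income pool (LMIC_POOL).

adjustment_income_classes <- function() c("HIC", "LMIC_POOL")

#' Map a World Bank income group to an adjustment pool
#' @param income_group one of `r paste(sbr_income_groups(), collapse=", ")`.
#' @return "HIC" or "LMIC_POOL".
#' @export
income_class_of <- function(income_group) {
  if (!all(income_group %in% sbr_income_groups()))
    stop("unknown income group: ", paste(setdiff(income_group, sbr_income_groups()),
                                         collapse = ", "), call. = FALSE)
  ifelse(income_group == "HIC", "HIC", "LMIC_POOL")
}

new_adjustment_ratio <- function(definition, income_class, ratio_mean, ratio_var, n_pairs) {
  if (ratio_mean <= 0) stop("ratio_mean must be > 0", call. = FALSE)
  if (ratio_var < 0) stop("ratio_var must be >= 0", call. = FALSE)
  if (definition %in% c("GA22", "BW500") && ratio_mean < 1)
    stop(definition, " is a broader definition; its ratio to GA28 must be >= 1",
         call. = FALSE)
  structure(list(definition = definition, income_class = income_class,
                 ratio_mean = ratio_mean, ratio_var = ratio_var,
                 n_pairs = n_pairs),
            class = "adjustment_ratio")
}

#' The identity adjustment (GA28 to GA28)
#' @return `adjustment_ratio` with mean 1 and variance 0.
#' @export
identity_adjustment <- function() {
  new_adjustment_ratio("GA28", "ANY", 1, 0, NA_integer_)
}

#' Estimate a definitional adjustment ratio from paired rates
#'
#' Given rates measured in the same population under both an alternative
#' definition and the 28-week standard, estimates the expected
#' alternative:GA28 ratio as the geometric mean of the per-pair ratios
#' (matching the model's log-scale observation equation) and its variance as
#' the sample variance of the per-pair ratios.
#'
#' @param alt_rate,ga28_rate positive paired rates (per 1000 total births).
#' @param definition the alternative definition the pairs measure.
#' @param income_class "HIC" or "LMIC_POOL".
#' @return An `adjustment_ratio`.
#' @export
estimate_adjustment_ratio <- function(alt_rate, ga28_rate,
                                      definition = "GA22",
                                      income_class = "LMIC_POOL") {
  if (length(alt_rate) != length(ga28_rate))
    stop("alt_rate and ga28_rate must have equal length", call. = FALSE)
  if (length(alt_rate) < 3) stop("at least 3 pairs are required", call. = FALSE)
  if (any(alt_rate <= 0) || any(ga28_rate <= 0))
    stop("all rates must be > 0", call. = FALSE)
  ratios <- alt_rate / ga28_rate
  new_adjustment_ratio(definition, income_class,
                       ratio_mean = exp(mean(log(ratios))),
                       ratio_var = stats::var(ratios),
                       n_pairs = length(ratios))
}

#' Packaged default adjustment table
#'
#' GA22:GA28 means are the published comparison values (1.5 for high-income
#' settings, 1.2 for the low/middle-income pool). The ratio variances and the
#' birthweight-definition rows are documented placeholders meant to be
#' replaced with user-supplied paired data via [estimate_adjustment_ratio()]
#' and [read_adjustment_table()].
#' @return data.frame with columns definition, income_class, ratio_mean,
#'   ratio_var, n_pairs.
#' @export
default_adjustment_table <- function() {
  path <- system.file("extdata", "adjustment_defaults.csv", package = "stillbirthr")
  read_adjustment_table(path)
}

#' Read / write an adjustment table (CSV)
#' @param path CSV with columns definition, income_class, ratio_mean,
#'   ratio_var, n_pairs.
#' @return data.frame of adjustment rows (validated).
#' @export
read_adjustment_table <- function(path) {
  if (!file.exists(path) || !nzchar(path))
    stop("adjustment table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("definition", "income_class", "ratio_mean", "ratio_var", "n_pairs")
  if (!all(need %in% names(df)))
    stop("adjustment table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(df)))     # constructor enforces row invariants
    new_adjustment_ratio(df$definition[i], df$income_class[i],
                         df$ratio_mean[i], df$ratio_var[i], df$n_pairs[i])
  df
}

#' @rdname read_adjustment_table
#' @param table adjustment table data.frame.
#' @export
write_adjustment_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up the adjustment for a definition and income group
#'
#' GA28 observations return the identity adjustment. UNSPECIFIED definitions
#' are unadjustable and raise an error of class `sbr_unadjustable` (such
#' observations must be excluded upstream).
#'
#' @param definition observation definition.
#' @param income_group World Bank income group of the country.
#' @param table adjustment table, default [default_adjustment_table()].
#' @return An `adjustment_ratio`.
#' @export
lookup_adjustment <- function(definition, income_group,
                              table = default_adjustment_table()) {
  if (definition == "GA28") return(identity_adjustment())
  if (definition == "UNSPECIFIED")
    stop(structure(class = c("sbr_unadjustable", "error", "condition"),
                   list(message = "UNSPECIFIED definition cannot be adjusted; exclude the observation",
                        call = sys.call(-1))))
  ic <- income_class_of(income_group)
  row <- table[table$definition == definition & table$income_class == ic, , drop = FALSE]
  if (nrow(row) != 1)
    stop("no adjustment ratio for (", definition, ", ", ic, ")", call. = FALSE)
  new_adjustment_ratio(row$definition, row$income_class, row$ratio_mean,
                       row$ratio_var, row$n_pairs)
}

#' Convert an observed rate to the GA28 scale
#'
#' The adjusted log rate is `log(sbr_observed) - log(ratio_mean)`; the extra
#' log-scale variance contributed by the conversion is `ratio_var /
#' ratio_mean^2` (delta method for the log of the ratio). GA28 observations
#' pass through unchanged with zero added variance.
#'
#' @param sbr_observed observed rate, per 1000 total births.
#' @param adj an `adjustment_ratio` matching the observation's definition.
#' @return list with `log_adjusted_mean` (log of the GA28-scale per-1000
#'   rate) and `def_log_var`.
#' @export
apply_adjustment <- function(sbr_observed, adj) {
  stopifnot(inherits(adj, "adjustment_ratio"))
  if (any(sbr_observed <= 0)) stop("sbr_observed must be > 0", call. = FALSE)
  list(log_adjusted_mean = log(sbr_observed) - log(adj$ratio_mean),
       def_log_var = adj$ratio_var / adj$ratio_mean^2)
}

#' Invert an adjustment (GA28-scale log rate back to the observed scale)
#' @param log_adjusted_mean log GA28-scale rate.
#' @param adj the `adjustment_ratio` that produced it.
#' @return rate on the original definition's scale, per 1000 total births.
#' @export
invert_adjustment <- function(log_adjusted_mean, adj) {
  exp(log_adjusted_mean) * adj$ratio_mean
}

#' Adjust a whole observation table to the GA28 definition
#'
#' Joins each observation with its (definition, income group) adjustment and
#' appends `log_adjusted_mean` and `def_log_var` columns. Rows with
#' UNSPECIFIED definitions must have been excluded already.
#'
#' @param obs `sbr_observations`.
#' @param births `sbr_births` (supplies each country's income group).
#' @param table adjustment table.
#' @return `obs` with adjustment columns appended.
#' @export
adjust_observations <- function(obs, births, table = default_adjustment_table()) {
  if (any(obs$definition == "UNSPECIFIED"))
    stop("UNSPECIFIED-definition rows present; run deterministic QC first",
         call. = FALSE)
  income <- births$income_group[match(obs$country_code, births$country_code)]
  if (anyNA(income))
    stop("countries missing from births table: ",
         paste(unique(obs$country_code[is.na(income)]), collapse = ", "),
         call. = FALSE)
  la <- numeric(nrow(obs)); dv <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    adj <- lookup_adjustment(obs$definition[i], income[i], table)
    a <- apply_adjustment(obs$sbr_observed[i], adj)
    la[i] <- a$log_adjusted_mean
    dv[i] <- a$def_log_var
  }
  obs$log_adjusted_mean <- la
  obs$def_log_var <- dv
  obs
}
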