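## Indicator computation: uncertainty intervals, stillbirth counts, regional
## aggregation (performed draw-wise before summarisation), annual rates of
## reduction, percentage change, and SBR:NMR ratios.

#' Empirical uncertainty interval
#'
#' Equal-tailed interval from posterior draws using the linear-interpolation
#' quantile convention (type 7); 90% by convention, so the 5th and 95th
#' percentiles. Intervals need not be symmetric about the point estimate.
#'
#' @param draws numeric vector of at least 100 draws.
#' @param level interval mass (default 0.90).
#' @return named vector c(low, high).
#' @export
uncertainty_interval <- function(draws, level = 0.90) {
  if (length(draws) < 100) stop("at least 100 draws are required", call. = FALSE)
  a <- (1 - level) / 2
  q <- stats::quantile(draws, c(a, 1 - a), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Stillbirth count from a rate and livebirths
#'
#' `S = L * r / (1 - r)` with `r` the stillbirth rate as a proportion of
#' total births, so that `S / (S + L) = r` exactly.
#'
#' @param r rate as a proportion of total births, in \[0, 1).
#' @param livebirths livebirth count (> 0), any unit.
#' @return stillbirth count in the same unit as `livebirths`.
#' @export
stillbirth_count <- function(r, livebirths) {
  if (any(r < 0) || any(r >= 1))
    stop("rate must lie in [0, 1) as a proportion of total births", call. = FALSE)
  if (any(livebirths <= 0)) stop("livebirths must be > 0", call. = FALSE)
  livebirths * r / (1 - r)
}

#' Aggregate country rate draws to a region or the world
#'
#' For each posterior draw, member-country counts are formed with
#' [stillbirth_count()] and the aggregate rate is total stillbirths over
#' total births: `sum(S_c) / sum(S_c + L_c)`. Aggregation happens draw-wise,
#' before any quantile is taken.
#'
#' @param rate_draws draws x countries matrix of rates (proportions of total
#'   births), columns named by country.
#' @param livebirths named vector of member livebirth counts.
#' @param members country codes to aggregate (default: all columns).
#' @return vector of aggregate rate draws (proportion scale).
#' @export
aggregate_rate_draws <- function(rate_draws, livebirths, members = colnames(rate_draws)) {
  miss <- setdiff(members, colnames(rate_draws))
  if (length(miss)) stop("no draws for member country: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(members, names(livebirths))
  if (length(miss)) stop("no livebirths for member country: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  R <- rate_draws[, members, drop = FALSE]
  L <- livebirths[members]
  S <- sweep(R / (1 - R), 2, L, "*")            # counts per draw
  tot_sb <- rowSums(S)
  tot_births <- rowSums(sweep(S, 2, L, "+"))
  tot_sb / tot_births
}

#' Annual rate of reduction
#'
#' `log(rate_t2 / rate_t1) / (t1 - t2)` for `t1 < t2`; positive when the
#' rate declines. Returned as a fraction per year.
#'
#' @param rate_t1,rate_t2 positive rates (draws or scalars) at `t1`, `t2`.
#' @param t1,t2 years, `t1 < t2`.
#' @return annual rate of reduction (fraction/year).
#' @export
arr <- function(rate_t1, t1, rate_t2, t2) {
  if (t1 >= t2) stop("t1 must be earlier than t2", call. = FALSE)
  if (any(rate_t1 <= 0) || any(rate_t2 <= 0))
    stop("rates must be > 0", call. = FALSE)
  log(rate_t2 / rate_t1) / (t1 - t2)
}

#' Percentage decrease between two values
#'
#' `100 * (1 - v_t2 / v_t1)`; positive values are declines, negative values
#' increases.
#'
#' @param v_t1 baseline value (> 0).
#' @param v_t2 comparison value.
#' @return percentage decrease.
#' @export
percent_change <- function(v_t1, v_t2) {
  if (any(v_t1 <= 0)) stop("baseline value must be > 0", call. = FALSE)
  100 * (1 - v_t2 / v_t1)
}

#' Ratio of stillbirth rate to neonatal mortality rate
#'
#' Draw-wise division of the stillbirth rate (per 1000 total births) by the
#' neonatal mortality rate (per 1000 livebirths), as the indicator is
#' conventionally reported.
#'
#' @param sbr_draws stillbirth-rate draws, per 1000 total births.
#' @param nmr neonatal mortality rate (scalar or matching draws), per 1000
#'   livebirths, > 0.
#' @return ratio draws.
#' @export
sbr_nmr_ratio <- function(sbr_draws, nmr) {
  if (any(nmr <= 0)) stop("nmr must be > 0", call. = FALSE)
  sbr_draws / nmr
}

#' Summarise draws into a tidy estimate row
#' @param draws numeric draws.
#' @param level interval mass.
#' @return list(median, ui_low, ui_high).
#' @export
summarise_draws <- function(draws, level = 0.90) {
  ui <- uncertainty_interval(draws, level)
  list(median = stats::median(draws), ui_low = ui[["low"]], ui_high = ui[["high"]])
}

#' Tidy rate and count estimates for countries, regions and the world
#'
#' Builds the reporting table: for every entity (country, region, world) and
#' year, the posterior median and 90% interval of the stillbirth rate (per
#' 1000 total births) and of the stillbirth count (same unit as the
#' livebirths input; livebirth counts are treated as known).
#'
#' @param rate_draws_by_year list (one element per year) of draws x
#'   countries matrices of rate draws on the proportion scale.
#' @param births `sbr_births`.
#' @param years years to report (default: names of `rate_draws_by_year`).
#' @param level interval mass.
#' @return data.frame (entity, level, year, quantity, median, ui_low,
#'   ui_high).
#' @export
rate_estimates <- function(rate_draws_by_year, births,
                           years = as.integer(names(rate_draws_by_year)),
                           level = 0.90) {
  out <- list()
  regions <- sort(unique(births$region_code))
  for (k in seq_along(years)) {
    yr <- years[k]
    R <- rate_draws_by_year[[k]]
    byr <- births[births$year == yr, ]
    L <- stats::setNames(byr$livebirths, byr$country_code)
    ents <- list()
    for (ct in colnames(R)) {
      r <- R[, ct]
      ents[[length(ents) + 1]] <- list(ct, "country", r, stillbirth_count(r, L[[ct]]))
    }
    for (rg in regions) {
      mem <- byr$country_code[byr$region_code == rg]
      r <- aggregate_rate_draws(R, L, mem)
      ents[[length(ents) + 1]] <- list(rg, "region", r,
                                       rowSums(sweep(R[, mem, drop = FALSE] /
                                                       (1 - R[, mem, drop = FALSE]),
                                                     2, L[mem], "*")))
    }
    r <- aggregate_rate_draws(R, L)
    ents[[length(ents) + 1]] <- list("WORLD", "world", r,
                                     rowSums(sweep(R / (1 - R), 2, L[colnames(R)], "*")))
    for (e in ents) {
      sr <- summarise_draws(1000 * e[[3]], level)
      sc <- summarise_draws(e[[4]], level)
      out[[length(out) + 1]] <- data.frame(
        entity = e[[1]], level = e[[2]], year = yr,
        quantity = c("sbr_per_1000", "stillbirths"),
        median = c(sr$median, sc$median),
        ui_low = c(sr$ui_low, sc$ui_low),
        ui_high = c(sr$ui_high, sc$ui_high), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
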