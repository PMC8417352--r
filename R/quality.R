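## Data-quality assessment: deterministic exclusion rules (definition and
## coverage criteria) followed by a probabilistic plausibility test on the
## stillbirth-rate : neonatal-mortality-rate ratio, which flags observations
## whose stillbirths look under-reported relative to neonatal deaths.

exclusion_reasons <- function() {
  c("NO_DEFINITION", "UNKNOWN_GA_GT_50", "LIVEBIRTH_COVERAGE_LT_80",
    "HMIS_COVERAGE_LT_75", "DEATH_COMPLETENESS_LT_95", "IMPLAUSIBLE_RATIO",
    "EXTERNAL_FLAG")
}

#' Quality-control thresholds
#'
#' @param unknown_ga exclude when more than this fraction of reported
#'   stillbirths have unknown gestational age/birthweight (default 0.50).
#' @param livebirth_coverage minimum livebirth registration coverage for
#'   administrative sources (default 0.80).
#' @param hmis_coverage minimum coverage for HMIS sources (default 0.75).
#' @param death_completeness minimum child-death registration completeness
#'   for administrative sources (default 0.95).
#' @param alpha ratio-test exclusion level: exclude when the probability of a
#'   smaller ratio under the high-quality reference is strictly below this
#'   (default 0.05).
#' @return list of thresholds.
#' @export
qc_thresholds <- function(unknown_ga = 0.50, livebirth_coverage = 0.80,
                          hmis_coverage = 0.75, death_completeness = 0.95,
                          alpha = 0.05) {
  list(unknown_ga = unknown_ga, livebirth_coverage = livebirth_coverage,
       hmis_coverage = hmis_coverage, death_completeness = death_completeness,
       alpha = alpha)
}

exclusion_record <- function(obs, idx, reason, detail, probability = NA_real_) {
  n <- length(idx)
  data.frame(country_code = obs$country_code[idx], year = obs$year[idx],
             source_type = obs$source_type[idx], definition = obs$definition[idx],
             reason = rep_len(reason, n), detail = rep_len(detail, n),
             probability = rep_len(probability, n), stringsAsFactors = FALSE)
}

#' Apply the deterministic exclusion rules
#'
#' Rules are evaluated in fixed priority order; each excluded observation
#' carries exactly one (the first triggered) reason. A rule is skipped where
#' its metadata field is missing. Rules:
#' unspecified definition; unknown gestational age fraction > 50%; livebirth
#' coverage < 80% (administrative) or < 75% (HMIS); child-death registration
#' completeness < 95% (administrative); externally flagged rows.
#'
#' @param obs `sbr_observations`.
#' @param thresholds see [qc_thresholds()].
#' @param external_flags optional data.frame (country_code, year,
#'   source_type, definition) of rows to exclude on external evidence.
#' @return list with `kept` (observations) and `excluded` (exclusion
#'   records, one row per excluded observation).
#' @export
apply_deterministic_rules <- function(obs, thresholds = qc_thresholds(),
                                      external_flags = NULL) {
  n <- nrow(obs)
  reason <- rep(NA_character_, n)
  detail <- rep(NA_real_, n)

  hit <- function(cond, why, val) {
    new <- which(is.na(reason) & cond %in% TRUE)
    reason[new] <<- why
    detail[new] <<- val[new]
  }

  hit(obs$definition == "UNSPECIFIED", "NO_DEFINITION", rep(NA_real_, n))
  hit(obs$unknown_ga_fraction > thresholds$unknown_ga, "UNKNOWN_GA_GT_50",
      obs$unknown_ga_fraction)
  hit(obs$source_type == "ADMIN" & obs$livebirth_coverage < thresholds$livebirth_coverage,
      "LIVEBIRTH_COVERAGE_LT_80", obs$livebirth_coverage)
  hit(obs$source_type == "HMIS" & obs$livebirth_coverage < thresholds$hmis_coverage,
      "HMIS_COVERAGE_LT_75", obs$livebirth_coverage)
  hit(obs$source_type == "ADMIN" & obs$child_death_completeness < thresholds$death_completeness,
      "DEATH_COMPLETENESS_LT_95", obs$child_death_completeness)
  if (!is.null(external_flags)) {
    fk <- paste(external_flags$country_code, external_flags$year,
                external_flags$source_type, external_flags$definition, sep = "|")
    ok <- paste(obs$country_code, obs$year, obs$source_type, obs$definition, sep = "|")
    hit(ok %in% fk, "EXTERNAL_FLAG", rep(NA_real_, n))
  }

  excl_idx <- which(!is.na(reason))
  excluded <- if (length(excl_idx))
    exclusion_record(obs, excl_idx, reason[excl_idx], detail[excl_idx])
  else exclusion_record(obs, integer(0), character(0), numeric(0))
  kept <- obs[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Fit the high-quality SBR:NMR ratio reference distribution
#'
#' Lognormal, fitted by log-moment matching to ratios observed in
#' high-quality study data.
#'
#' @param hq_ratios at least 10 positive SBR:NMR ratios.
#' @return object of class `ratio_reference` with fields `family`,
#'   `meanlog`, `sdlog`, `n_source`.
#' @export
fit_ratio_reference <- function(hq_ratios) {
  if (length(hq_ratios) < 10) stop("at least 10 ratios are required", call. = FALSE)
  if (any(hq_ratios <= 0)) stop("all ratios must be > 0", call. = FALSE)
  lr <- log(hq_ratios)
  sdlog <- stats::sd(lr)
  if (!is.finite(sdlog) || sdlog < 1e-8)
    stop("degenerate reference: ratios have (near-)zero spread", call. = FALSE)
  structure(list(family = "lognormal", meanlog = mean(lr), sdlog = sdlog,
                 n_source = length(hq_ratios)),
            class = "ratio_reference")
}

#' @export
print.ratio_reference <- function(x, ...) {
  cat("SBR:NMR ratio reference (lognormal)\n",
      sprintf("  meanlog %.4f (median ratio %.3f), sdlog %.4f, n = %d\n",
              x$meanlog, exp(x$meanlog), x$sdlog, x$n_source))
  invisible(x)
}

## Run code with a private RNG stream, restoring the caller's state.
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Probability of a smaller SBR:NMR ratio under the reference
#'
#' Computes `E[F_ref(R)]` where `F_ref` is the reference CDF and `R` follows
#' the observed ratio's sampling distribution: lognormal with mean `r_obs`
#' and coefficient of variation `r_se / r_obs`. With `r_se = 0` this reduces
#' exactly to `F_ref(r_obs)`. Monte-Carlo integration with a fixed private
#' seed keeps results reproducible.
#'
#' @param r_obs observed SBR:NMR ratio (> 0).
#' @param r_se standard error of the observed ratio (>= 0).
#' @param ref a `ratio_reference`.
#' @param n_draws Monte-Carlo draws (>= 1e4 recommended).
#' @param seed integer seed for the private Monte-Carlo stream.
#' @return probability in \[0, 1\].
#' @export
ratio_plausibility_probability <- function(r_obs, r_se, ref, n_draws = 1e4,
                                           seed = 20190201L) {
  stopifnot(inherits(ref, "ratio_reference"))
  if (!is.finite(r_obs) || r_obs <= 0) stop("r_obs must be > 0", call. = FALSE)
  if (!is.finite(r_se) || r_se < 0) stop("r_se must be >= 0", call. = FALSE)
  if (r_se == 0)
    return(stats::plnorm(r_obs, ref$meanlog, ref$sdlog))
  cv <- r_se / r_obs
  sdl <- sqrt(log1p(cv^2))
  mul <- log(r_obs) - sdl^2 / 2          # E[R] = r_obs
  with_private_seed(seed, {
    draws <- stats::rlnorm(n_draws, mul, sdl)
    mean(stats::plnorm(draws, ref$meanlog, ref$sdlog))
  })
}

## Log-scale sampling CV^2 of an observed rate: binomial delta method when
## counts are present, otherwise a source-type default variance.
obs_log_cv2 <- function(obs_row, source_var_defaults, design_effect) {
  p <- obs_row$sbr_observed / 1000
  if (!is.na(obs_row$n_total_births) && obs_row$n_total_births > 0 && p < 1) {
    v <- (1 - p) / (obs_row$n_total_births * p)
    if (obs_row$source_type == "SURVEY") v <- v * design_effect
  } else {
    v <- source_var_defaults[[obs_row$source_type]]
  }
  v
}

#' Exclude observations with implausibly low SBR:NMR ratios
#'
#' For each adjusted observation the SBR:NMR ratio is formed from the
#' GA28-scale rate and a neonatal mortality rate — the same-source NMR when
#' present (except HMIS, whose facility NMR under-captures deaths occurring
#' at home), otherwise the external country-year estimate in `nmr_lookup`.
#' The probability of a smaller ratio under the high-quality reference is
#' computed with [ratio_plausibility_probability()]; observations with
#' probability strictly below `thresholds$alpha` are excluded. The standard
#' error of the observed ratio combines the rate's sampling + definitional
#' CV with the NMR CV (delta method).
#'
#' @param obs adjusted observations (with `log_adjusted_mean`,
#'   `def_log_var` from [adjust_observations()]).
#' @param nmr_lookup data.frame (country_code, year, nmr, optional nmr_se):
#'   external NMR estimates per 1000 livebirths.
#' @param ref `ratio_reference`.
#' @param thresholds see [qc_thresholds()].
#' @param source_var_defaults fallback log-scale sampling variances by
#'   source type, used when counts are absent.
#' @param design_effect survey design effect multiplier on sampling variance.
#' @param default_nmr_cv NMR coefficient of variation when `nmr_se` absent.
#' @param n_draws,seed Monte-Carlo controls for the probability integral.
#' @return list(kept, excluded); observations with no available NMR are kept
#'   with a warning, not excluded.
#' @export
exclude_implausible <- function(obs, nmr_lookup, ref,
                                thresholds = qc_thresholds(),
                                source_var_defaults = default_sampling_variances(),
                                design_effect = 2.0,
                                default_nmr_cv = 0.1,
                                n_draws = 1e4, seed = 20190201L) {
  if (is.null(obs$log_adjusted_mean))
    stop("observations must be definition-adjusted first (adjust_observations)",
         call. = FALSE)
  n <- nrow(obs)
  prob <- rep(NA_real_, n)
  ratio_i <- rep(NA_real_, n)
  excl <- rep(FALSE, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    r <- obs[i, ]
    use_source_nmr <- !is.na(r$nmr_same_source) && r$source_type != "HMIS"
    if (use_source_nmr) {
      nmr <- r$nmr_same_source
      nmr_cv <- default_nmr_cv
    } else {
      j <- which(nmr_lookup$country_code == r$country_code & nmr_lookup$year == r$year)
      if (!length(j)) { skipped <- skipped + 1L; next }
      nmr <- nmr_lookup$nmr[j[1]]
      nmr_cv <- if (!is.null(nmr_lookup$nmr_se) && !is.na(nmr_lookup$nmr_se[j[1]]))
        nmr_lookup$nmr_se[j[1]] / nmr else default_nmr_cv
    }
    sbr28 <- exp(r$log_adjusted_mean)          # per 1000 total births, GA28 scale
    ratio <- sbr28 / nmr
    ratio_i[i] <- ratio
    cv2 <- obs_log_cv2(r, source_var_defaults, design_effect) + r$def_log_var + nmr_cv^2
    r_se <- ratio * sqrt(cv2)
    prob[i] <- ratio_plausibility_probability(ratio, r_se, ref,
                                              n_draws = n_draws,
                                              seed = seed + i)
    excl[i] <- prob[i] < thresholds$alpha       # strict: exactly alpha is kept
  }
  if (skipped)
    warning(skipped, " observation(s) skipped in the ratio test: no NMR available",
            call. = FALSE)
  excluded <- exclusion_record(obs, which(excl), "IMPLAUSIBLE_RATIO",
                               detail = ratio_i[excl],
                               probability = prob[excl])
  kept <- obs[!excl, , drop = FALSE]
  kept$ratio_test_probability <- prob[!excl]
  rownames(kept) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Default fallback sampling variances (log-rate scale) by source type
#' @return named list.
#' @export
default_sampling_variances <- function() {
  list(ADMIN = 0.005, HMIS = 0.02, SURVEY = 0.05, STUDY = 0.02)
}

#' Write an exclusion report
#'
#' One row per input observation with a kept flag, exclusion reason, detail
#' and ratio-test probability; a commented summary block at the top records
#' counts and the percentage excluded.
#'
#' @param obs the full input observation set.
#' @param excluded combined exclusion records.
#' @param path output CSV.
#' @return invisibly, the summary list.
#' @export
write_exclusion_report <- function(obs, excluded, path) {
  key <- function(d) paste(d$country_code, d$year, d$source_type, d$definition, sep = "|")
  ok <- key(obs); ek <- key(excluded)
  m <- match(ok, ek)
  rep_df <- data.frame(country_code = obs$country_code, year = obs$year,
                       source_type = obs$source_type, definition = obs$definition,
                       kept = is.na(m),
                       reason = ifelse(is.na(m), "", excluded$reason[m]),
                       detail = ifelse(is.na(m), NA_real_, excluded$detail[m]),
                       probability = ifelse(is.na(m), NA_real_, excluded$probability[m]))
  summary <- list(n_input = nrow(obs), n_excluded = nrow(excluded),
                  n_kept = nrow(obs) - nrow(excluded),
                  pct_excluded = round(100 * nrow(excluded) / max(1, nrow(obs)), 1))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# input: %d; excluded: %d (%.1f%%); kept: %d",
                     summary$n_input, summary$n_excluded, summary$pct_excluded,
                     summary$n_kept), con)
  utils::write.table(rep_df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(summary)
}
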