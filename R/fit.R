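## The main user surface: sbr_fit() runs quality control, definitional
## adjustment, covariate preparation and blocked MCMC posterior sampling,
## returning a classed fit object with the standard modelling methods.

theta_param_names <- function(inputs) {
  lo <- theta_layout(inputs)
  nm <- character(0)
  for (b in names(lo$sizes))
    nm <- c(nm, if (lo$sizes[[b]] == 1) b else paste0(b, "[", seq_len(lo$sizes[[b]]), "]"))
  nm
}

init_theta <- function(inputs, jitter) {
  lo <- theta_layout(inputs)
  op <- inputs$options
  th <- stats::rnorm(lo$total, 0, jitter)
  set_block <- function(th, name, val) {
    th[lo$starts[[name]]:lo$ends[[name]]] <-
      val + stats::rnorm(lo$sizes[[name]], 0, jitter)
    th
  }
  th <- set_block(th, "aw", op$alpha_mean)
  th <- set_block(th, "ltau", log(op$hs_tau0))
  th <- set_block(th, "ltau_a", log(0.1))
  th <- set_block(th, "ltau_r", log(0.1))
  th <- set_block(th, "mu_t", op$mu_tau_mean)
  th <- set_block(th, "lsig_t", log(0.2))
  th <- set_block(th, "lsig_s", log(0.1))
  th <- set_block(th, "ub", log(0.05))
  th
}

## flattened latent surface in (country-major, year-fastest) order
latent_from_theta <- function(theta, inputs) {
  p <- sbr_theta_to_params(theta, inputs)
  as.numeric(t(latent_log_sbr(p, inputs)))
}

#' Fit the stillbirth-rate model
#'
#' Runs the full estimation pipeline on validated input tables:
#' deterministic quality control, definitional adjustment to the GA28
#' standard, the SBR:NMR ratio plausibility test (when a high-quality ratio
#' sample is supplied), covariate smoothing and standardisation, and
#' posterior sampling of the hierarchical model with the blocked sampler in
#' [run_sbr_mcmc()].
#'
#' @param observations `sbr_observations` (see [read_sbr_observations()]).
#' @param covariates `sbr_covariates` covering the estimation grid.
#' @param births `sbr_births` covering the estimation grid.
#' @param nmr_lookup external NMR estimates (country_code, year, nmr,
#'   optional nmr_se) for the ratio test; required when `hq_ratios` given.
#' @param hq_ratios high-quality SBR:NMR ratios for the reference
#'   distribution; `NULL` skips the ratio test.
#' @param adjustments definitional adjustment table.
#' @param thresholds [qc_thresholds()].
#' @param external_flags optional externally flagged rows (see
#'   [apply_deterministic_rules()]).
#' @param smooth_vars covariate columns to smooth (default the
#'   survey-derived coverage indicators).
#' @param model [sbr_model_options()].
#' @param mcmc [mcmc_options()].
#' @param seed integer seed controlling initialisation and sampling.
#' @return object of class `sbr_fit`.
#' @export
sbr_fit <- function(observations, covariates, births,
                    nmr_lookup = NULL, hq_ratios = NULL,
                    adjustments = default_adjustment_table(),
                    thresholds = qc_thresholds(),
                    external_flags = NULL,
                    smooth_vars = c("anc4", "csec"),
                    model = sbr_model_options(),
                    mcmc = mcmc_options(),
                    seed = 1L) {
  cl <- match.call()
  n_input <- nrow(observations)

  det <- apply_deterministic_rules(observations, thresholds, external_flags)
  adj <- adjust_observations(det$kept, births, adjustments)

  ref <- NULL
  ratio_excluded <- det$excluded[0, ]
  if (!is.null(hq_ratios)) {
    if (is.null(nmr_lookup))
      stop("nmr_lookup is required for the ratio plausibility test", call. = FALSE)
    ref <- fit_ratio_reference(hq_ratios)
    rt <- exclude_implausible(adj, nmr_lookup, ref, thresholds,
                              model$sampling_var_defaults, model$design_effect,
                              seed = seed)
    adj <- rt$kept
    ratio_excluded <- rt$excluded
  }
  excluded <- rbind(det$excluded, ratio_excluded)
  if (nrow(adj) == 0) stop("no observations survive quality control", call. = FALSE)

  cov_s <- smooth_covariate_table(covariates, smooth_vars)
  years <- sort(unique(births$year))
  countries <- sort(unique(births$country_code))
  design <- build_design_matrix(cov_s, countries, years)
  inputs <- assemble_model_inputs(adj, design, births, model)

  samples <- run_sbr_mcmc(inputs, options = mcmc, seed = seed)
  str <- samples$structures
  slayout <- samples$scale_layout

  ndraws <- mcmc$draws * mcmc$chains
  flat <- matrix(aperm(samples$draws, c(1, 3, 2)), nrow = ndraws)
  w <- flat[, seq_len(str$d), drop = FALSE]
  b <- flat[, str$d + 1L]
  s_off <- str$d + 1L
  scol <- function(name) {
    s_off + slayout$starts[[name]]:slayout$ends[[name]]
  }
  latent <- w %*% t(str$Lmap)
  pars <- cbind(w[, str$idx_beta, drop = FALSE],
                exp(flat[, scol("lss"), drop = FALSE]),
                b,
                exp(flat[, scol("ltau")]),
                exp(flat[, scol("lta")]),
                exp(flat[, scol("ltr")]),
                w[, str$idx_aw],
                flat[, scol("mu_t")])
  colnames(pars) <- c(paste0("beta_", design_columns()), "sigma_HMIS",
                      "sigma_SURVEY", "sigma_STUDY", "b_survey", "hs_tau",
                      "tau_alpha", "tau_region", "alpha_w", "mu_tau")
  colnames(latent) <- paste(rep(inputs$countries, each = inputs$n_years),
                            rep(inputs$years, inputs$n_countries), sep = "_")

  diagnostics <- mcmc_diagnostics(
    samples, param_names = sbr_sample_param_names(inputs, str, slayout))

  structure(list(call = cl, countries = countries, years = years,
                 n_input = n_input, kept = adj, excluded = excluded,
                 design = design, inputs = inputs, ref = ref,
                 samples = samples, latent = latent, par_draws = pars,
                 diagnostics = diagnostics,
                 model_options = model, mcmc_options = mcmc, seed = seed),
            class = "sbr_fit")
}

## latent columns are (country, year) pairs, year fastest.
latent_cols <- function(fit, country, year) {
  match(paste(country, year, sep = "_"), colnames(fit$latent))
}

#' Posterior rate draws on the proportion scale
#' @param fit `sbr_fit`.
#' @param years years to extract (default all).
#' @return named list per year of draws x countries matrices.
#' @export
posterior_rate_draws <- function(fit, years = fit$years) {
  out <- lapply(years, function(yr) {
    cols <- latent_cols(fit, fit$countries, yr)
    m <- exp(fit$latent[, cols, drop = FALSE])
    colnames(m) <- fit$countries
    m
  })
  names(out) <- years
  out
}

#' @export
print.sbr_fit <- function(x, ...) {
  cat("Stillbirth-rate hierarchical model fit\n")
  cat(sprintf("  %d countries x %d years (%d-%d)\n", length(x$countries),
              length(x$years), min(x$years), max(x$years)))
  cat(sprintf("  observations: %d input, %d excluded, %d used\n",
              x$n_input, nrow(x$excluded), nrow(x$kept)))
  cat(sprintf("  draws: %d chains x %d (max Rhat %.3f, min ESS %.0f, %s)\n",
              x$mcmc_options$chains, x$mcmc_options$draws,
              x$diagnostics$max_rhat, x$diagnostics$min_ess,
              if (x$diagnostics$pass) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.sbr_fit <- function(object, ...) {
  b <- apply(object$par_draws[, paste0("beta_", design_columns())], 2, stats::median)
  names(b) <- design_columns()
  b
}

#' @export
summary.sbr_fit <- function(object, level = 0.90, ...) {
  pd <- object$par_draws
  tab <- t(apply(pd, 2, function(d)
    c(median = stats::median(d), uncertainty_interval(d, level))))
  out <- list(coefficients = tab[paste0("beta_", design_columns()), , drop = FALSE],
              bias_and_scales = tab[setdiff(rownames(tab),
                                            paste0("beta_", design_columns())), ,
                                    drop = FALSE],
              diagnostics = object$diagnostics,
              n_used = nrow(object$kept), n_excluded = nrow(object$excluded))
  class(out) <- "summary.sbr_fit"
  out
}

#' @export
print.summary.sbr_fit <- function(x, ...) {
  cat("Coefficients (standardised covariates, posterior median and 90% UI):\n")
  print(round(x$coefficients, 4))
  cat("\nBias and scale parameters:\n")
  print(round(x$bias_and_scales, 4))
  cat(sprintf("\nObservations: %d used, %d excluded; max Rhat %.3f, min ESS %.0f\n",
              x$n_used, x$n_excluded, x$diagnostics$max_rhat, x$diagnostics$min_ess))
  invisible(x)
}

#' Posterior rate estimates
#'
#' @param object `sbr_fit`.
#' @param countries,years subset to report (defaults: all).
#' @param level interval mass.
#' @param ... unused.
#' @return data.frame (country_code, year, median, ui_low, ui_high) of rates
#'   per 1000 total births.
#' @export
predict.sbr_fit <- function(object, countries = object$countries,
                            years = object$years, level = 0.90, ...) {
  out <- list()
  for (ct in countries) {
    cols <- latent_cols(object, ct, years)
    if (anyNA(cols)) stop("unknown country or year requested", call. = FALSE)
    for (j in seq_along(years)) {
      s <- summarise_draws(1000 * exp(object$latent[, cols[j]]), level)
      out[[length(out) + 1]] <- data.frame(country_code = ct, year = years[j],
                                           median = s$median, ui_low = s$ui_low,
                                           ui_high = s$ui_high)
    }
  }
  do.call(rbind, out)
}

#' @export
fitted.sbr_fit <- function(object, ...) {
  med <- apply(object$latent, 2, stats::median)
  m <- matrix(1000 * exp(med), nrow = length(object$years))
  t(structure(m, dimnames = list(object$years, object$countries)))
}

#' @export
residuals.sbr_fit <- function(object, ...) {
  med <- apply(object$latent, 2, stats::median)
  cols <- latent_cols(object, object$kept$country_code, object$kept$year)
  (object$kept$log_adjusted_mean - log(1000)) - med[cols]
}

#' Posterior-predictive replicates of the observation vector
#' @param object `sbr_fit`.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return matrix observations x nsim of replicated adjusted log rates.
#' @export
simulate.sbr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  inputs <- object$inputs
  ndraws <- nrow(object$latent)
  idx <- sample.int(ndraws, nsim, replace = nsim > ndraws)
  cols <- latent_cols(object, inputs$obs$country_code, inputs$obs$year)
  out <- matrix(NA_real_, length(cols), nsim)
  for (j in seq_len(nsim)) {
    i <- idx[j]
    b <- object$par_draws[i, "b_survey"]
    sig <- c(object$model_options$sigma_admin,
             object$par_draws[i, c("sigma_HMIS", "sigma_SURVEY", "sigma_STUDY")])
    mu <- object$latent[i, cols] + b * inputs$is_survey
    v <- inputs$var_known + sig[inputs$source_idx]^2
    out[, j] <- stats::rnorm(length(mu), mu, sqrt(v))
  }
  out
}

#' Plot posterior rate trajectories
#' @param x `sbr_fit`.
#' @param countries countries to draw (default: first 6).
#' @param level interval mass for the shaded band.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sbr_fit <- function(x, countries = utils::head(x$countries, 6),
                         level = 0.90, ...) {
  est <- predict(x, countries = countries, level = level)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(countries)),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (ct in countries) {
    e <- est[est$country_code == ct, ]
    obs <- x$kept[x$kept$country_code == ct, ]
    ylim <- range(e$ui_low, e$ui_high, exp(obs$log_adjusted_mean), na.rm = TRUE)
    graphics::plot(e$year, e$median, type = "n", ylim = ylim, xlab = "", ylab = "",
                   main = ct, ...)
    graphics::polygon(c(e$year, rev(e$year)), c(e$ui_low, rev(e$ui_high)),
                      col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
    graphics::lines(e$year, e$median, col = "steelblue4", lwd = 2)
    if (nrow(obs))
      graphics::points(obs$year, exp(obs$log_adjusted_mean), pch = 19, cex = 0.6)
  }
  invisible(x)
}
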