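## Synthetic-world generator. Emulates the statistical structure the model
## assumes: true log rates driven by standardised covariates plus a smooth
## country deviation (random-walk spline coefficients), observations with
## source-type biases and error scales, definitional scaling of GA22 rates,
## binomial sampling error where counts exist, and a corrupt subset whose
## stillbirths are under-reported by a fixed factor. Ground truth and
## per-row provenance are retained so every pipeline stage is testable.

#' Synthetic world configuration
#'
#' Defaults describe a small world (4 regions x 5 countries x 20 years)
#' whose scales mirror the model's prior centre: world log rate around 14
#' per 1000, two active covariates, survey bias -0.10 on the log scale,
#' 15% corrupt observations under-reporting stillbirths by half, and a true
#' stillbirth:neonatal mortality ratio of 0.8.
#'
#' @param n_regions,countries_per_region world size.
#' @param years estimation years.
#' @param beta_true 6 regression coefficients on the standardised covariate
#'   scale, ordered log(nmr), log(lbw), anc4, csec, edu, log(gni).
#' @param alpha_world world mean log rate (proportion scale).
#' @param tau_region,tau_alpha intercept hierarchy scales.
#' @param tau_delta median spline random-walk innovation scale.
#' @param tau_delta_spread lognormal spread of per-country innovation scales.
#' @param obs_prob income-group x source-type observation probabilities.
#' @param sigma_source per-source error scales (log scale).
#' @param b_survey survey bias, log scale (<= 0).
#' @param ga22_fraction probability an observation is reported under the
#'   22-week definition, by adjustment income class.
#' @param unspecified_fraction probability the definition label is missing.
#' @param corrupt_fraction,underreport_factor corrupt subset controls.
#' @param sbr_nmr_ratio_true true stillbirth:neonatal mortality ratio.
#' @param ratio_noise_sd log-scale spread of high-quality reference ratios.
#' @param n_hq_ratios size of the high-quality ratio sample.
#' @param design_effect survey design effect.
#' @param covariate_noise_sd measurement noise added to the emitted anc4 and
#'   csec series (the model smooths these).
#' @param sampling_noise FALSE switches off binomial/sampling noise (counts
#'   are then omitted and observed rates equal biased true rates exactly).
#' @param seed RNG seed, recorded in the manifest.
#' @return list of class `world_config`.
#' @export
world_config <- function(n_regions = 4, countries_per_region = 5,
                         years = 2000:2019,
                         beta_true = c(0.5, 0.2, 0, 0, 0, 0),
                         alpha_world = log(0.014),
                         tau_region = 0.15, tau_alpha = 0.2,
                         tau_delta = 0.05, tau_delta_spread = 0.3,
                         obs_prob = default_obs_prob(),
                         sigma_source = c(ADMIN = 0.01, HMIS = 0.10,
                                          SURVEY = 0.15, STUDY = 0.10),
                         b_survey = -0.10,
                         ga22_fraction = c(HIC = 0.3, LMIC_POOL = 0.15),
                         unspecified_fraction = 0.05,
                         corrupt_fraction = 0.15, underreport_factor = 0.5,
                         sbr_nmr_ratio_true = 0.8, ratio_noise_sd = 0.15,
                         n_hq_ratios = 100, design_effect = 2.0,
                         covariate_noise_sd = 0.02,
                         sampling_noise = TRUE,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$beta_true) == 6,
            cfg$underreport_factor > 0, cfg$underreport_factor <= 1,
            cfg$corrupt_fraction >= 0, cfg$corrupt_fraction <= 1,
            cfg$b_survey <= 0)
  class(cfg) <- "world_config"
  cfg
}

#' Default observation probabilities by income group and source type
#' @return matrix, rows LIC/LMIC_GROUP/UMIC/HIC, columns source types.
#' @export
default_obs_prob <- function() {
  m <- rbind(LIC        = c(0.02, 0.20, 0.25, 0.10),
             LMIC_GROUP = c(0.10, 0.30, 0.25, 0.08),
             UMIC       = c(0.60, 0.10, 0.05, 0.05),
             HIC        = c(0.90, 0.00, 0.00, 0.02))
  colnames(m) <- sbr_source_types()
  m
}

#' Generate a synthetic world
#'
#' @param config [world_config()].
#' @return object of class `sbr_world`: `truth` (latent log-rate matrix,
#'   beta, scales, per-row provenance), `observations`, `covariates`,
#'   `births`, `nmr_lookup`, `hq_ratios`, `manifest`.
#' @export
generate_world <- function(config = world_config()) {
  set.seed(config$seed)
  n_c <- config$n_regions * config$countries_per_region
  countries <- sprintf("C%02d", seq_len(n_c))
  regions <- sprintf("R%d", rep(seq_len(config$n_regions),
                                each = config$countries_per_region))
  income_levels <- rep(c("HIC", "UMIC", "LMIC_GROUP", "LIC"),
                       length.out = config$n_regions)
  income <- income_levels[rep(seq_len(config$n_regions),
                              each = config$countries_per_region)]
  years <- config$years
  T <- length(years); t_rel <- years - years[1]

  base <- list(
    nmr = c(HIC = 3, UMIC = 8, LMIC_GROUP = 20, LIC = 30),
    lbw = c(HIC = 0.07, UMIC = 0.09, LMIC_GROUP = 0.14, LIC = 0.16),
    anc4 = c(HIC = 0.90, UMIC = 0.75, LMIC_GROUP = 0.55, LIC = 0.40),
    csec = c(HIC = 0.25, UMIC = 0.30, LMIC_GROUP = 0.08, LIC = 0.03),
    edu = c(HIC = 12, UMIC = 9, LMIC_GROUP = 6, LIC = 3),
    gni = c(HIC = 45000, UMIC = 9000, LMIC_GROUP = 2500, LIC = 700),
    lb_growth = c(HIC = 0.998, UMIC = 1.000, LMIC_GROUP = 1.012, LIC = 1.022))

  cov_rows <- vector("list", n_c)
  births_rows <- vector("list", n_c)
  cov_true <- vector("list", n_c)
  for (i in seq_len(n_c)) {
    ig <- income[i]
    lev <- function(nm) base[[nm]][[ig]]
    ## wide independent country-level variation keeps the covariates
    ## identifiable despite their shared income-group gradient
    nmr <- lev("nmr") * exp(stats::rnorm(1, 0, 0.40)) *
      exp(-stats::runif(1, 0.005, 0.035) * t_rel)
    lbw <- lev("lbw") * exp(stats::rnorm(1, 0, 0.40)) *
      exp(-stats::runif(1, 0, 0.012) * t_rel)
    anc4 <- pmin(0.99, pmax(0.05, lev("anc4") * exp(stats::rnorm(1, 0, 0.25)) +
                   stats::runif(1, 0.002, 0.018) * t_rel))
    csec <- pmin(0.6, lev("csec") * exp(stats::rnorm(1, 0, 0.4)) +
                   stats::runif(1, 0.001, 0.008) * t_rel)
    edu <- lev("edu") * exp(stats::rnorm(1, 0, 0.25)) +
      stats::runif(1, 0.02, 0.15) * t_rel
    gni <- lev("gni") * exp(stats::rnorm(1, 0, 0.5)) *
      exp(stats::runif(1, 0, 0.04) * t_rel)
    lb0 <- exp(stats::rnorm(1, log(300), 0.8))          # thousands
    lb <- lb0 * lev("lb_growth")^t_rel
    cov_true[[i]] <- data.frame(country_code = countries[i], year = years,
                                nmr = nmr, lbw = lbw, anc4 = anc4, csec = csec,
                                edu = edu, gni = gni, stringsAsFactors = FALSE)
    cov_rows[[i]] <- within(cov_true[[i]], {
      anc4 <- pmin(1, pmax(0.01, anc4 + stats::rnorm(T, 0, config$covariate_noise_sd)))
      csec <- pmin(1, pmax(0.005, csec + stats::rnorm(T, 0, config$covariate_noise_sd / 2)))
    })
    births_rows[[i]] <- data.frame(country_code = countries[i], year = years,
                                   livebirths = lb, region_code = regions[i],
                                   income_group = ig, stringsAsFactors = FALSE)
  }
  covariates <- validate_covariate_table(do.call(rbind, cov_rows))
  covariates_true <- validate_covariate_table(do.call(rbind, cov_true))
  births <- validate_births_table(do.call(rbind, births_rows))

  ## true latent log rates from the noise-free covariates
  design_true <- build_design_matrix(covariates_true)
  sp <- spline_deviation_basis(years)
  alpha_r <- config$alpha_world + config$tau_region * stats::rnorm(config$n_regions)
  alpha_c <- alpha_r[rep(seq_len(config$n_regions),
                         each = config$countries_per_region)] +
    config$tau_alpha * stats::rnorm(n_c)
  tau_d <- config$tau_delta * exp(config$tau_delta_spread * stats::rnorm(n_c))
  eps <- matrix(stats::rnorm((sp$K - 1) * n_c), sp$K - 1, n_c)
  delta <- sweep(sp$A %*% eps, 2, tau_d, "*")          # T x C, centred
  latent <- t(matrix(design_true$X %*% config$beta_true, nrow = T) + delta) +
    alpha_c                                             # C x T log proportion
  dimnames(latent) <- list(countries, years)

  nmr_true <- 1000 * exp(latent) / config$sbr_nmr_ratio_true  # per 1000 livebirths
  nmr_lookup <- data.frame(country_code = rep(countries, each = T),
                           year = rep(years, n_c),
                           nmr = as.numeric(t(nmr_true)),
                           nmr_se = 0.05 * as.numeric(t(nmr_true)),
                           stringsAsFactors = FALSE)
  hq_ratios <- config$sbr_nmr_ratio_true *
    exp(stats::rnorm(config$n_hq_ratios, 0, config$ratio_noise_sd))

  adj_sd <- c(HIC = sqrt(0.0225) / 1.5, LMIC_POOL = sqrt(0.0324) / 1.2)
  obs <- list(); prov <- list()
  for (i in seq_len(n_c)) {
    ic <- income_class_of(income[i])
    ga22_ratio <- if (ic == "HIC") 1.5 else 1.2
    for (k in seq_len(T)) {
      lb_count <- births_rows[[i]]$livebirths[k] * 1000
      for (src in sbr_source_types()) {
        if (stats::runif(1) >= config$obs_prob[income[i], src]) next
        ga22 <- stats::runif(1) < config$ga22_fraction[[ic]]
        def_ratio <- if (ga22) ga22_ratio else 1
        def_err <- if (ga22) stats::rnorm(1, 0, adj_sd[[ic]]) else 0
        bias <- if (src == "SURVEY") config$b_survey else 0
        src_err <- stats::rnorm(1, 0, config$sigma_source[[src]])
        corrupt <- stats::runif(1) < config$corrupt_fraction
        y <- latent[i, k] + log(def_ratio) + def_err + bias + src_err

        n_tot <- NA_real_; n_sb <- NA_real_
        if (config$sampling_noise && src %in% c("ADMIN", "HMIS")) {
          coverage <- if (src == "ADMIN") stats::runif(1, 0.82, 1.0)
                      else stats::runif(1, 0.72, 1.0)
          n_tot <- round(lb_count * coverage)
          n_sb <- stats::rbinom(1, n_tot, min(0.5, exp(y)))
          if (corrupt) n_sb <- round(n_sb * config$underreport_factor)
          n_sb <- max(n_sb, 1)
          y <- log(n_sb / n_tot)
          sbr <- 1000 * n_sb / n_tot
        } else if (config$sampling_noise) {
          coverage <- NA_real_
          ess <- round(exp(stats::runif(1, log(3000), log(20000))))
          p <- exp(y)
          v <- (1 - p) / (p * ess) * if (src == "SURVEY") config$design_effect else 1
          y <- y + stats::rnorm(1, 0, sqrt(v))
          if (corrupt) y <- y + log(config$underreport_factor)
          n_tot <- ess
          sbr <- 1000 * exp(y)
        } else {
          coverage <- NA_real_
          if (corrupt) y <- y + log(config$underreport_factor)
          sbr <- 1000 * exp(y)
        }

        definition <- if (ga22) "GA22" else "GA28"
        if (stats::runif(1) < config$unspecified_fraction) definition <- "UNSPECIFIED"
        nmr_ss <- NA_real_
        if (src %in% c("ADMIN", "SURVEY", "STUDY"))
          nmr_ss <- nmr_true[i, k] * exp(stats::rnorm(1, 0, 0.05))
        unk_ga <- if (stats::runif(1) < 0.05) stats::runif(1, 0.5, 0.8)
                  else stats::runif(1, 0, 0.25)
        cdc <- if (src == "ADMIN") {
          if (stats::runif(1) < 0.9) stats::runif(1, 0.95, 1) else stats::runif(1, 0.85, 0.95)
        } else NA_real_

        obs[[length(obs) + 1]] <- data.frame(
          country_code = countries[i], year = years[k], sbr_observed = sbr,
          definition = definition, source_type = src,
          n_total_births = n_tot, n_stillbirths = n_sb,
          nmr_same_source = nmr_ss, unknown_ga_fraction = unk_ga,
          livebirth_coverage = if (src %in% c("ADMIN", "HMIS")) coverage else NA_real_,
          child_death_completeness = cdc, stringsAsFactors = FALSE)
        prov[[length(prov) + 1]] <- data.frame(
          country_code = countries[i], year = years[k], source_type = src,
          definition = definition, true_log_rate = latent[i, k],
          def_ratio = def_ratio, def_err = def_err, bias = bias,
          src_err = src_err, corrupt = corrupt, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(obs)) stop("degenerate configuration: no observations generated",
                         call. = FALSE)
  observations <- validate_sbr_observations(do.call(rbind, obs),
                                            window = range(years))
  provenance <- do.call(rbind, prov)
  provenance <- provenance[order(provenance$country_code, provenance$year,
                                 provenance$source_type, provenance$definition), ]
  rownames(provenance) <- NULL

  structure(list(
    truth = list(latent_log_rate = latent, beta = config$beta_true,
                 alpha_world = config$alpha_world, alpha_r = alpha_r,
                 alpha_c = alpha_c, tau_delta = tau_d,
                 gamma = sweep(rbind(0, apply(eps, 2, cumsum)), 2, tau_d, "*"),
                 nmr_true = nmr_true, provenance = provenance),
    observations = observations, covariates = covariates, births = births,
    nmr_lookup = nmr_lookup, hq_ratios = hq_ratios,
    manifest = list(seed = config$seed, config = unclass(config),
                    n_observations = nrow(observations))),
    class = "sbr_world")
}

#' Write a synthetic world as a fixture directory
#'
#' Emits exactly the CSV schemas the loaders read (observations, covariates,
#' births), plus the NMR lookup, high-quality ratios, ground-truth latent
#' rates, provenance and a JSON manifest.
#'
#' @param world `sbr_world`.
#' @param dir output directory (created).
#' @return invisibly, the file paths.
#' @export
write_world_fixture <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, x)
  write_sbr_observations(world$observations, f("observations.csv"))
  write_covariate_table(world$covariates, f("covariates.csv"))
  write_births_table(world$births, f("births.csv"))
  utils::write.csv(world$nmr_lookup, f("nmr_lookup.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(ratio = world$hq_ratios), f("hq_ratios.csv"),
                   row.names = FALSE, quote = FALSE)
  lat <- world$truth$latent_log_rate
  truth_df <- data.frame(country_code = rep(rownames(lat), each = ncol(lat)),
                         year = rep(as.integer(colnames(lat)), nrow(lat)),
                         true_log_rate = as.numeric(t(lat)))
  utils::write.csv(truth_df, f("truth_latent.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(world$truth$provenance, f("provenance.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(world$manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(vapply(c("observations.csv", "covariates.csv", "births.csv",
                     "nmr_lookup.csv", "hq_ratios.csv", "truth_latent.csv",
                     "provenance.csv", "manifest.json"), f, ""))
}

#' Read a fixture directory back into memory
#' @param dir fixture directory written by [write_world_fixture()].
#' @param window estimation window for observation validation.
#' @return list with the re-loaded tables (no ground truth reconstruction).
#' @export
read_world_fixture <- function(dir, window = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (is.null(window))
    window <- range(manifest$config$years)
  list(observations = read_sbr_observations(file.path(dir, "observations.csv"),
                                            window = window),
       covariates = read_covariate_table(file.path(dir, "covariates.csv")),
       births = read_births_table(file.path(dir, "births.csv")),
       nmr_lookup = utils::read.csv(file.path(dir, "nmr_lookup.csv")),
       hq_ratios = utils::read.csv(file.path(dir, "hq_ratios.csv"))$ratio,
       truth = utils::read.csv(file.path(dir, "truth_latent.csv")),
       manifest = manifest)
}
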