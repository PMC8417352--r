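## Bayesian hierarchical temporal sparse regression for log stillbirth rates.
##
## Process model (log proportion scale) for country c, year t:
##   log r_{c,t} = X_{c,t} beta + alpha_c + delta_c(t)
## with a regularised-horseshoe prior on beta (covariate shrinkage), a
## region/world hierarchy on the country intercepts alpha_c, and a
## country-specific smoothing process delta_c(t) built from a cubic B-spline
## basis whose coefficients follow a first-order random walk; delta_c is
## sum-to-zero over the year grid so alpha_c carries the level.
##
## Observation model for adjusted observation i (y_i = log GA28-scale rate):
##   y_i ~ Normal(log r_{c_i,t_i} + b_survey * 1[survey],
##                var_sampling_i + var_def_i + sigma_source(s_i)^2)
## with b_survey <= 0 (surveys under-report stillbirths) and per-source-type
## error scales; the administrative scale is fixed near zero to anchor the
## variance decomposition.

#' Model options
#'
#' Hyperparameters of the hierarchical model. Defaults are documented
#' choices, not quantities estimated elsewhere.
#'
#' @param knot_spacing B-spline knot spacing in years (cubic basis).
#' @param slab_scale regularised-horseshoe slab scale (limits how far a
#'   selected coefficient can travel on the standardised-covariate scale).
#' @param hs_tau0 horseshoe global-scale prior scale; small values encode an
#'   expectation of few active covariates (default tuned toward ~2).
#' @param alpha_mean,alpha_sd prior on the world-level intercept, log
#'   proportion scale (default centred at log(0.014) ~ 14 per 1000).
#' @param tau_alpha_scale,tau_region_scale half-normal prior scales of the
#'   country- and region-intercept standard deviations.
#' @param mu_tau_mean,mu_tau_sd prior on the mean log innovation scale of
#'   the spline random walks.
#' @param sigma_tau_scale half-normal scale of the spread of per-country log
#'   innovation scales.
#' @param sigma_admin fixed administrative-source error scale (log scale).
#' @param sigma_source_scale half-normal prior scale for the HMIS / survey /
#'   study error scales.
#' @param b_survey_scale scale of the zero-truncated normal prior on the
#'   (non-positive) survey bias.
#' @param design_effect survey design-effect multiplier on count-based
#'   sampling variances.
#' @param sampling_var_defaults fallback sampling variances by source type.
#' @return list of options.
#' @export
sbr_model_options <- function(knot_spacing = 2.5,
                              slab_scale = 1.0,
                              hs_tau0 = 0.05,
                              alpha_mean = log(0.014), alpha_sd = 1.5,
                              tau_alpha_scale = 0.5, tau_region_scale = 0.5,
                              mu_tau_mean = log(0.03), mu_tau_sd = 1,
                              sigma_tau_scale = 0.5,
                              sigma_admin = 0.01,
                              sigma_source_scale = 0.3,
                              b_survey_scale = 0.2,
                              design_effect = 2.0,
                              sampling_var_defaults = default_sampling_variances()) {
  as.list(environment())
}

#' Sampling variance of an observed log rate
#'
#' Binomial delta method on the log scale: `(1 - p) / (T * p)` with `p` the
#' rate as a proportion of total births and `T` the total births. Survey
#' observations are multiplied by the design effect. When counts are absent
#' the source-type default variance is used (with a note).
#'
#' @param sbr_observed rate per 1000 total births.
#' @param n_total_births total births (NA when unavailable).
#' @param source_type one of ADMIN/HMIS/SURVEY/STUDY.
#' @param design_effect survey design effect (default 2).
#' @param defaults fallback variances, see [default_sampling_variances()].
#' @param quiet suppress the fallback note.
#' @return variance of the log rate.
#' @export
sampling_variance <- function(sbr_observed, n_total_births, source_type,
                              design_effect = 2.0,
                              defaults = default_sampling_variances(),
                              quiet = FALSE) {
  p <- sbr_observed / 1000
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("rate must correspond to a proportion in (0, 1)", call. = FALSE)
  if (is.na(n_total_births)) {
    if (!quiet) message("no counts for a ", source_type,
                        " observation; using the source-type default variance")
    return(defaults[[source_type]])
  }
  v <- (1 - p) / (n_total_births * p)
  if (source_type == "SURVEY") v <- v * design_effect
  v
}

## Cubic B-spline basis on the year grid with knots every `spacing` years,
## centred over the grid, times the cumulative-sum map of random-walk
## innovations: delta_c = tau_c * A %*% eps_c with eps standard normal.
spline_deviation_basis <- function(years, spacing = 2.5) {
  t0 <- min(years); t1 <- max(years)
  interior <- seq(t0 + spacing, t1 - spacing / 2, by = spacing)
  interior <- interior[interior < t1]
  B <- splines::bs(years, knots = interior, degree = 3, intercept = TRUE,
                   Boundary.knots = c(t0, t1))
  B <- matrix(as.numeric(B), nrow = length(years))
  K <- ncol(B)
  Bc <- sweep(B, 2, colMeans(B))                 # sum-to-zero over the grid
  L <- matrix(0, K, K - 1)                       # cumulative-sum map
  for (j in seq_len(K - 1)) L[(j + 1):K, j] <- 1
  list(B = B, Bc = Bc, A = Bc %*% L, K = K)
}

#' Assemble model inputs from adjusted observations
#'
#' Resolves every per-observation quantity the likelihood needs (log rate on
#' the proportion scale, variance components, source and country/year
#' indices) and the fixed structures (design matrix, spline basis, region
#' map).
#'
#' @param adjusted_obs observations with adjustment columns (see
#'   [adjust_observations()]).
#' @param design `sbr_design` from [build_design_matrix()].
#' @param births `sbr_births` (region and income metadata).
#' @param options [sbr_model_options()].
#' @return list of class `sbr_model_inputs`.
#' @export
assemble_model_inputs <- function(adjusted_obs, design, births,
                                  options = sbr_model_options()) {
  countries <- design$countries
  years <- design$years
  C <- length(countries); T <- length(years)

  cmeta <- unique(births[, c("country_code", "region_code", "income_group")])
  if (anyDuplicated(cmeta$country_code))
    stop("inconsistent region/income metadata in births table", call. = FALSE)
  m <- match(countries, cmeta$country_code)
  if (anyNA(m)) stop("births table missing countries: ",
                     paste(countries[is.na(m)], collapse = ", "), call. = FALSE)
  regions <- sort(unique(cmeta$region_code[m]))
  region_of <- match(cmeta$region_code[m], regions)

  sp <- spline_deviation_basis(years, options$knot_spacing)

  ob <- adjusted_obs
  ci <- match(ob$country_code, countries)
  ti <- match(ob$year, years)
  if (anyNA(ci) || anyNA(ti))
    stop("observations outside the estimation grid", call. = FALSE)
  vs <- vapply(seq_len(nrow(ob)), function(i)
    sampling_variance(ob$sbr_observed[i], ob$n_total_births[i],
                      ob$source_type[i], options$design_effect,
                      options$sampling_var_defaults, quiet = TRUE),
    numeric(1))
  structure(list(
    countries = countries, years = years, regions = regions,
    region_of = region_of, n_countries = C, n_years = T,
    n_regions = length(regions),
    X = design$X, design = design, basis = sp,
    obs = data.frame(country_code = ob$country_code, year = ob$year,
                     source_type = ob$source_type, stringsAsFactors = FALSE),
    y = ob$log_adjusted_mean - log(1000),   # log proportion of total births
    c_idx = ci, t_idx = ti, cy_idx = (ci - 1L) * T + ti,
    source_idx = match(ob$source_type, sbr_source_types()),
    is_survey = ob$source_type == "SURVEY",
    var_known = vs + ob$def_log_var,
    options = options), class = "sbr_model_inputs")
}

#' Latent log stillbirth rate surface
#'
#' Evaluates `X beta + alpha_c + delta_c(t)` for all country-years, with the
#' spline deviation centred to sum to zero per country over the year grid.
#'
#' @param params named list with `beta` (6), `alpha_c` (per country) and
#'   `gamma` (spline coefficients, K x countries matrix).
#' @param inputs `sbr_model_inputs`.
#' @param country,year optional single cell to extract.
#' @return countries x years matrix of log rates (proportion scale), or a
#'   scalar when `country`/`year` are given.
#' @export
latent_log_sbr <- function(params, inputs, country = NULL, year = NULL) {
  C <- inputs$n_countries; T <- inputs$n_years
  gamma <- params$gamma
  if (is.null(gamma)) gamma <- matrix(0, inputs$basis$K, C)
  stopifnot(nrow(gamma) == inputs$basis$K, ncol(gamma) == C)
  delta <- inputs$basis$Bc %*% gamma               # T x C, centred
  reg <- matrix(inputs$X %*% params$beta, nrow = T) # rows years, cols countries
  lat <- t(reg + delta) + params$alpha_c            # C x T
  dimnames(lat) <- list(inputs$countries, inputs$years)
  if (!is.null(country) || !is.null(year)) {
    ci <- match(country, inputs$countries)
    ti <- match(year, inputs$years)
    if (anyNA(ci)) stop("unknown country: ", country, call. = FALSE)
    if (anyNA(ti)) stop("unknown year: ", year, call. = FALSE)
    return(lat[ci, ti])
  }
  lat
}

#' Observation log likelihood
#'
#' Sum over observations of the normal log density of the adjusted log rate
#' at the latent log rate plus the survey bias, with total variance
#' `var_sampling + var_def + sigma_source^2`.
#'
#' @param params named list: `beta`, `alpha_c`, `gamma`, `b_survey`,
#'   `sigma_source` (named HMIS/SURVEY/STUDY; ADMIN is fixed in `options`).
#' @param inputs `sbr_model_inputs`.
#' @return log likelihood (scalar).
#' @export
sbr_log_likelihood <- function(params, inputs) {
  lat <- latent_log_sbr(params, inputs)
  mu <- lat[cbind(inputs$c_idx, inputs$t_idx)] +
    ifelse(inputs$is_survey, params$b_survey, 0)
  sig <- source_sigmas(params, inputs$options)
  v <- inputs$var_known + sig[inputs$source_idx]^2
  ld <- stats::dnorm(inputs$y, mu, sqrt(v), log = TRUE)
  if (any(!is.finite(ld)))
    stop("non-finite log density at observation ", which(!is.finite(ld))[1],
         call. = FALSE)
  sum(ld)
}

source_sigmas <- function(params, options) {
  c(options$sigma_admin, params$sigma_source[["HMIS"]],
    params$sigma_source[["SURVEY"]], params$sigma_source[["STUDY"]])
}

#' Joint log prior density (natural scale)
#'
#' Regularised horseshoe on `beta`; hierarchical normal intercepts
#' (country within region within world); half-normal priors on all scale
#' parameters; first-difference Gaussian random-walk penalty on each
#' country's spline coefficients (plus a proper N(0,1) prior on their mean,
#' the level freed by the sum-to-zero constraint); zero-truncated normal
#' (<= 0) on the survey bias. Parameters outside their support return
#' `-Inf`, not an error.
#'
#' @param params full parameter list: `beta`, `hs_lambda`, `hs_tau`,
#'   `alpha_w`, `alpha_r`, `alpha_c`, `tau_alpha`, `tau_region`, `gamma`,
#'   `tau_delta` (per country), `mu_tau`, `sigma_tau`, `sigma_source`,
#'   `b_survey`.
#' @param inputs `sbr_model_inputs` (region map).
#' @param options [sbr_model_options()].
#' @return log prior density (scalar, possibly `-Inf`).
#' @export
sbr_log_prior <- function(params, inputs, options = inputs$options) {
  p <- params
  scales <- c(p$hs_lambda, p$hs_tau, p$tau_alpha, p$tau_region, p$tau_delta,
              p$sigma_tau, unlist(p$sigma_source))
  if (any(!is.finite(scales)) || any(scales <= 0)) return(-Inf)
  if (!is.finite(p$b_survey) || p$b_survey > 0) return(-Inf)

  half_cauchy <- function(x, s) sum(log(2 / pi) - log(s) - log1p((x / s)^2))
  half_normal <- function(x, s) sum(stats::dnorm(x, 0, s, log = TRUE) + log(2))

  lam_t2 <- options$slab_scale^2 * p$hs_lambda^2 /
    (options$slab_scale^2 + p$hs_tau^2 * p$hs_lambda^2)
  lp <- sum(stats::dnorm(p$beta, 0, p$hs_tau * sqrt(lam_t2), log = TRUE)) +
    half_cauchy(p$hs_lambda, 1) + half_cauchy(p$hs_tau, options$hs_tau0)

  lp <- lp + stats::dnorm(p$alpha_w, options$alpha_mean, options$alpha_sd, log = TRUE) +
    sum(stats::dnorm(p$alpha_r, p$alpha_w, p$tau_region, log = TRUE)) +
    sum(stats::dnorm(p$alpha_c, p$alpha_r[inputs$region_of], p$tau_alpha, log = TRUE)) +
    half_normal(p$tau_alpha, options$tau_alpha_scale) +
    half_normal(p$tau_region, options$tau_region_scale)

  for (c in seq_len(ncol(p$gamma))) {
    g <- p$gamma[, c]
    lp <- lp + sum(stats::dnorm(diff(g), 0, p$tau_delta[c], log = TRUE)) +
      stats::dnorm(mean(g), 0, 1, log = TRUE)
  }
  lp <- lp + sum(stats::dnorm(log(p$tau_delta), p$mu_tau, p$sigma_tau, log = TRUE) -
                   log(p$tau_delta)) +
    stats::dnorm(p$mu_tau, options$mu_tau_mean, options$mu_tau_sd, log = TRUE) +
    half_normal(p$sigma_tau, options$sigma_tau_scale) +
    half_normal(unlist(p$sigma_source), options$sigma_source_scale) +
    stats::dnorm(p$b_survey, 0, options$b_survey_scale, log = TRUE) + log(2)
  lp
}

## ---------------------------------------------------------------------------
## Unconstrained (non-centred) parameterisation used by the HMC sampler.
## theta blocks: z(6), llam(6), ltau(1), aw(1), eta_r(R), eta_c(C),
## ltau_a(1), ltau_r(1), eps((K-1)*C), xi(C), mu_t(1), lsig_t(1), lsig_s(3),
## ub(1) with b_survey = -exp(ub).
## ---------------------------------------------------------------------------

theta_layout <- function(inputs) {
  C <- inputs$n_countries; R <- inputs$n_regions; Km1 <- inputs$basis$K - 1L
  sizes <- c(z = 6, llam = 6, ltau = 1, aw = 1, eta_r = R, eta_c = C,
             ltau_a = 1, ltau_r = 1, eps = Km1 * C, xi = C, mu_t = 1,
             lsig_t = 1, lsig_s = 3, ub = 1)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  list(sizes = sizes, starts = starts, ends = ends, total = sum(sizes),
       C = C, R = R, Km1 = Km1, T = inputs$n_years)
}

theta_block <- function(theta, layout, name) {
  theta[layout$starts[[name]]:layout$ends[[name]]]
}

#' Transform an unconstrained parameter vector to the natural scale
#' @param theta unconstrained vector (sampler coordinates).
#' @param inputs `sbr_model_inputs`.
#' @return full natural-scale parameter list (see [sbr_log_prior()]).
#' @export
sbr_theta_to_params <- function(theta, inputs) {
  lo <- theta_layout(inputs)
  op <- inputs$options
  g <- function(n) theta_block(theta, lo, n)
  lam <- exp(g("llam")); tau <- exp(g("ltau"))
  lam_t <- op$slab_scale * lam / sqrt(op$slab_scale^2 + tau^2 * lam^2)
  beta <- g("z") * tau * lam_t
  tr <- exp(g("ltau_r")); ta <- exp(g("ltau_a"))
  aw <- g("aw")
  alpha_r <- aw + tr * g("eta_r")
  alpha_c <- alpha_r[inputs$region_of] + ta * g("eta_c")
  st <- exp(g("lsig_t")); mu_t <- g("mu_t")
  tau_delta <- exp(mu_t + st * g("xi"))
  E <- matrix(g("eps"), lo$Km1, lo$C)
  L <- rbind(0, apply(E, 2, cumsum))            # K x C cumulative RW paths
  gamma <- sweep(L, 2, tau_delta, "*")
  sig <- exp(g("lsig_s"))
  list(beta = as.numeric(beta), hs_lambda = lam, hs_tau = tau,
       alpha_w = aw, alpha_r = alpha_r, alpha_c = alpha_c,
       tau_alpha = ta, tau_region = tr,
       gamma = gamma, tau_delta = tau_delta, mu_tau = mu_t, sigma_tau = st,
       sigma_source = list(HMIS = sig[1], SURVEY = sig[2], STUDY = sig[3]),
       b_survey = -exp(g("ub")))
}

#' Unconstrained log posterior and its gradient
#'
#' The density targeted by the sampler: observation likelihood plus priors
#' on the non-centred, log-transformed coordinates (change-of-variable
#' Jacobians included). The gradient is analytic.
#'
#' @param theta unconstrained parameter vector.
#' @param inputs `sbr_model_inputs`.
#' @return list(lp, grad).
#' @export
sbr_lp_grad <- function(theta, inputs) {
  lo <- theta_layout(inputs)
  op <- inputs$options
  C <- lo$C; R <- lo$R; T <- lo$T; Km1 <- lo$Km1
  gb <- function(n) theta_block(theta, lo, n)

  z <- gb("z"); llam <- gb("llam"); ltau <- gb("ltau"); aw <- gb("aw")
  eta_r <- gb("eta_r"); eta_c <- gb("eta_c")
  ltau_a <- gb("ltau_a"); ltau_r <- gb("ltau_r")
  eps <- matrix(gb("eps"), Km1, C); xi <- gb("xi")
  mu_t <- gb("mu_t"); lsig_t <- gb("lsig_t"); lsig_s <- gb("lsig_s"); ub <- gb("ub")

  lam <- exp(llam); tau <- exp(ltau)
  q <- op$slab_scale^2 + tau^2 * lam^2
  s_beta <- tau * op$slab_scale * lam / sqrt(q)   # marginal scale of beta_j
  beta <- z * s_beta
  tr <- exp(ltau_r); ta <- exp(ltau_a)
  alpha_r <- aw + tr * eta_r
  alpha_c <- alpha_r[inputs$region_of] + ta * eta_c
  st <- exp(lsig_t)
  tau_d <- exp(mu_t + st * xi)
  sig <- exp(lsig_s)
  b_surv <- -exp(ub)

  A <- inputs$basis$A                              # T x (K-1)
  D0 <- A %*% eps                                  # T x C, unscaled deviations
  delta <- sweep(D0, 2, tau_d, "*")
  mu_cy <- as.numeric(matrix(inputs$X %*% beta, nrow = T) +
                        delta + rep(alpha_c, each = T))  # length C*T, (c-1)*T + t

  m_i <- mu_cy[inputs$cy_idx] + b_surv * inputs$is_survey
  sig_all <- c(op$sigma_admin, sig)
  v_i <- inputs$var_known + sig_all[inputs$source_idx]^2
  res <- inputs$y - m_i
  lp <- -0.5 * sum(log(2 * pi * v_i) + res^2 / v_i)

  w <- res / v_i                                   # d ll / d m_i
  u <- 0.5 * (res^2 / v_i^2 - 1 / v_i)             # d ll / d v_i

  ## accumulate observation gradients onto the country-year grid
  G <- numeric(C * T)
  ag <- rowsum(w, inputs$cy_idx)
  G[as.integer(rownames(ag))] <- ag
  Gm <- matrix(G, T, C)

  g_beta <- as.numeric(crossprod(inputs$X, G))
  g_alpha_c <- colSums(Gm)
  g_ar <- as.numeric(rowsum(g_alpha_c, inputs$region_of))

  ## horseshoe chain rule: s_beta = tau * slab * lam / sqrt(q)
  g_z <- g_beta * s_beta - z
  ds_dlam <- tau * op$slab_scale^3 / q^1.5
  ds_dtau <- op$slab_scale^3 * lam / q^1.5
  g_llam <- g_beta * z * ds_dlam * lam +
    (-2 * lam^2 / (1 + lam^2) + 1)
  g_ltau <- sum(g_beta * z * ds_dtau) * tau +
    (-2 * (tau / op$hs_tau0)^2 / (1 + (tau / op$hs_tau0)^2) + 1)

  g_eta_c <- g_alpha_c * ta - eta_c
  g_ltau_a <- sum(g_alpha_c * eta_c) * ta + (-ta^2 / op$tau_alpha_scale^2 + 1)
  g_eta_r <- g_ar * tr - eta_r
  g_ltau_r <- sum(g_ar * eta_r) * tr + (-tr^2 / op$tau_region_scale^2 + 1)
  g_aw <- sum(g_ar) - (aw - op$alpha_mean) / op$alpha_sd^2

  g_eps <- sweep(crossprod(A, Gm), 2, tau_d, "*") - eps     # (K-1) x C
  gd0 <- colSums(Gm * D0)                         # d ll / d tau_c
  g_mu_t <- sum(gd0 * tau_d) - (mu_t - op$mu_tau_mean) / op$mu_tau_sd^2
  g_xi <- gd0 * tau_d * st - xi
  g_lsig_t <- sum(gd0 * tau_d * xi) * st + (-st^2 / op$sigma_tau_scale^2 + 1)

  g_lsig_s <- numeric(3)
  for (k in 1:3) {
    sel <- inputs$source_idx == k + 1L
    g_lsig_s[k] <- sum(u[sel]) * 2 * sig[k]^2 +
      (-sig[k]^2 / op$sigma_source_scale^2 + 1)
  }
  g_ub <- sum(w[inputs$is_survey]) * b_surv +
    (-b_surv^2 / op$b_survey_scale^2 + 1)

  ## priors on the remaining standard-normal blocks + transformed scales
  lp <- lp - 0.5 * sum(z^2) +
    sum(-log1p(lam^2) + llam) +
    (-log1p((tau / op$hs_tau0)^2) + ltau) +
    -0.5 * (aw - op$alpha_mean)^2 / op$alpha_sd^2 +
    -0.5 * sum(eta_r^2) - 0.5 * sum(eta_c^2) +
    (-ta^2 / (2 * op$tau_alpha_scale^2) + ltau_a) +
    (-tr^2 / (2 * op$tau_region_scale^2) + ltau_r) +
    -0.5 * sum(eps^2) - 0.5 * sum(xi^2) +
    -0.5 * (mu_t - op$mu_tau_mean)^2 / op$mu_tau_sd^2 +
    (-st^2 / (2 * op$sigma_tau_scale^2) + lsig_t) +
    sum(-sig^2 / (2 * op$sigma_source_scale^2) + lsig_s) +
    (-b_surv^2 / (2 * op$b_survey_scale^2) + ub)

  grad <- c(g_z, g_llam, g_ltau, g_aw, g_eta_r, g_eta_c, g_ltau_a, g_ltau_r,
            as.numeric(g_eps), g_xi, g_mu_t, g_lsig_t, g_lsig_s, g_ub)
  list(lp = lp, grad = grad)
}
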