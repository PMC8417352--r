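zero_params <- function(inputs) {
  list(beta = rep(0, 6),
       alpha_c = rep(log(0.014), inputs$n_countries),
       gamma = matrix(0, inputs$basis$K, inputs$n_countries))
}

test_that("the latent surface is the regression plus intercept plus spline deviation", {
  inputs <- cached_tiny_inputs()
  p0 <- zero_params(inputs)
  lat <- latent_log_sbr(p0, inputs)
  expect_true(all(lat == log(0.014)))
  expect_equal(latent_log_sbr(p0, inputs, country = inputs$countries[1],
                              year = inputs$years[3]), log(0.014))
  expect_error(latent_log_sbr(p0, inputs, country = "XXX", year = 2005),
               "unknown country")

  # linearity: a unit coefficient shifts the latent by the covariate value
  p1 <- p0; p1$beta <- c(1, 0, 0, 0, 0, 0)
  lat1 <- latent_log_sbr(p1, inputs)
  shift <- matrix(inputs$X[, 1], nrow = inputs$n_years)
  expect_equal(unname(lat1 - lat), unname(t(shift)))

  # dense-algebra oracle with random parameters
  set.seed(9)
  pr <- list(beta = rnorm(6, 0, 0.3),
             alpha_c = rnorm(inputs$n_countries, log(0.014), 0.2),
             gamma = matrix(rnorm(inputs$basis$K * inputs$n_countries, 0, 0.1),
                            inputs$basis$K))
  lat_pkg <- latent_log_sbr(pr, inputs)
  B <- inputs$basis$B
  Bc <- B - matrix(colMeans(B), nrow(B), ncol(B), byrow = TRUE)
  oracle <- matrix(NA_real_, inputs$n_countries, inputs$n_years)
  for (c in seq_len(inputs$n_countries)) {
    rows <- (c - 1) * inputs$n_years + seq_len(inputs$n_years)
    oracle[c, ] <- inputs$X[rows, ] %*% pr$beta + pr$alpha_c[c] +
      Bc %*% pr$gamma[, c]
  }
  expect_equal(unname(lat_pkg), oracle, tolerance = 1e-12)
})

test_that("sampling variance follows the binomial delta method with a survey design effect", {
  expect_equal(sampling_variance(10, 1e5, "ADMIN"), 0.99 / 1000)
  expect_equal(sampling_variance(10, 1e5, "ADMIN"), 9.9e-4)
  # simulation cross-check of the delta-method variance of the log rate
  set.seed(41)
  s <- rbinom(4000, 1e5, 0.01)
  expect_equal(var(log(s / 1e5)), 9.9e-4, tolerance = 0.1)

  expect_equal(sampling_variance(10, 1e5, "SURVEY"),
               2 * sampling_variance(10, 1e5, "ADMIN"))
  expect_error(sampling_variance(1000, 1e5, "ADMIN"), "proportion")
  expect_message(v <- sampling_variance(10, NA, "HMIS"), "default")
  expect_equal(v, default_sampling_variances()$HMIS)
})

test_that("the observation log likelihood matches per-observation normal densities", {
  inputs <- cached_tiny_inputs()
  set.seed(10)
  params <- list(beta = rnorm(6, 0, 0.2),
                 alpha_c = rnorm(inputs$n_countries, log(0.014), 0.2),
                 gamma = matrix(rnorm(inputs$basis$K * inputs$n_countries, 0, 0.05),
                                inputs$basis$K),
                 b_survey = -0.1,
                 sigma_source = list(HMIS = 0.1, SURVEY = 0.15, STUDY = 0.1))
  ll <- sbr_log_likelihood(params, inputs)
  lat <- latent_log_sbr(params, inputs)
  sig <- c(inputs$options$sigma_admin, 0.1, 0.15, 0.1)
  oracle <- 0
  for (i in seq_along(inputs$y)) {
    mu <- lat[inputs$c_idx[i], inputs$t_idx[i]] +
      if (inputs$is_survey[i]) params$b_survey else 0
    v <- inputs$var_known[i] + sig[inputs$source_idx[i]]^2
    oracle <- oracle + dnorm(inputs$y[i], mu, sqrt(v), log = TRUE)
  }
  expect_equal(ll, oracle, tolerance = 1e-12)

  # single observation exactly at the latent mean: density is -log(2 pi v)/2
  one <- inputs
  keep <- 1L
  for (f in c("y", "c_idx", "t_idx", "cy_idx", "source_idx", "is_survey",
              "var_known")) one[[f]] <- one[[f]][keep]
  one$obs <- one$obs[keep, ]
  one$y <- lat[one$c_idx, one$t_idx] + if (one$is_survey) params$b_survey else 0
  v <- one$var_known + sig[one$source_idx]^2
  expect_equal(sbr_log_likelihood(params, one), -0.5 * log(2 * pi * v))

  # a survey observation's likelihood is maximised at b = y - latent
  sv <- one
  sv$is_survey <- TRUE; sv$source_idx <- 3L
  sv$y <- lat[sv$c_idx, sv$t_idx] - 0.23
  lls <- vapply(seq(-0.5, 0, by = 0.01), function(b) {
    p <- params; p$b_survey <- b; sbr_log_likelihood(p, sv)
  }, numeric(1))
  expect_equal(seq(-0.5, 0, by = 0.01)[which.max(lls)], -0.23)
})

test_that("the joint log prior matches an independent density-by-density oracle", {
  inputs <- cached_tiny_inputs()
  op <- inputs$options
  set.seed(12)
  C <- inputs$n_countries; K <- inputs$basis$K
  params <- list(beta = rnorm(6, 0, 0.2), hs_lambda = rlnorm(6, 0, 0.5),
                 hs_tau = 0.08, alpha_w = log(0.013),
                 alpha_r = rnorm(inputs$n_regions, log(0.013), 0.1),
                 alpha_c = rnorm(C, log(0.013), 0.2),
                 tau_alpha = 0.25, tau_region = 0.12,
                 gamma = matrix(rnorm(K * C, 0, 0.05), K),
                 tau_delta = rlnorm(C, log(0.04), 0.3),
                 mu_tau = log(0.04), sigma_tau = 0.3,
                 sigma_source = list(HMIS = 0.1, SURVEY = 0.2, STUDY = 0.15),
                 b_survey = -0.12)
  lp <- sbr_log_prior(params, inputs)

  hn <- function(x, s) dnorm(x, 0, s, log = TRUE) + log(2)
  hc <- function(x, s) log(2 / pi) - log(s) - log1p((x / s)^2)
  lt2 <- op$slab_scale^2 * params$hs_lambda^2 /
    (op$slab_scale^2 + params$hs_tau^2 * params$hs_lambda^2)
  oracle <- sum(dnorm(params$beta, 0, params$hs_tau * sqrt(lt2), log = TRUE)) +
    sum(hc(params$hs_lambda, 1)) + hc(params$hs_tau, op$hs_tau0) +
    dnorm(params$alpha_w, op$alpha_mean, op$alpha_sd, log = TRUE) +
    sum(dnorm(params$alpha_r, params$alpha_w, params$tau_region, log = TRUE)) +
    sum(dnorm(params$alpha_c, params$alpha_r[inputs$region_of],
              params$tau_alpha, log = TRUE)) +
    hn(params$tau_alpha, op$tau_alpha_scale) +
    hn(params$tau_region, op$tau_region_scale) +
    sum(vapply(seq_len(C), function(c)
      sum(dnorm(diff(params$gamma[, c]), 0, params$tau_delta[c], log = TRUE)) +
        dnorm(mean(params$gamma[, c]), 0, 1, log = TRUE), numeric(1))) +
    sum(dlnorm(params$tau_delta, params$mu_tau, params$sigma_tau, log = TRUE)) +
    dnorm(params$mu_tau, op$mu_tau_mean, op$mu_tau_sd, log = TRUE) +
    hn(params$sigma_tau, op$sigma_tau_scale) +
    sum(vapply(unlist(params$sigma_source), hn, numeric(1),
               s = op$sigma_source_scale)) +
    dnorm(params$b_survey, 0, op$b_survey_scale, log = TRUE) + log(2)
  expect_equal(lp, oracle, tolerance = 1e-10)

  # shrinkage direction: prior falls monotonically as |beta| grows under
  # tiny horseshoe scales
  small <- params; small$hs_lambda <- rep(0.01, 6); small$hs_tau <- 0.01
  lps <- vapply(c(0.1, 0.5, 1, 2), function(b) {
    p <- small; p$beta <- rep(b, 6); sbr_log_prior(p, inputs)
  }, numeric(1))
  expect_true(all(diff(lps) < 0))

  # constant spline coefficients: only the free-level term changes
  flat <- params; flat$gamma <- matrix(0.3, K, C)
  flat0 <- params; flat0$gamma <- matrix(0, K, C)
  expect_equal(sbr_log_prior(flat, inputs) - sbr_log_prior(flat0, inputs),
               C * (dnorm(0.3, 0, 1, log = TRUE) - dnorm(0, 0, 1, log = TRUE)))

  # out-of-support parameters return -Inf, not an error
  neg <- params; neg$tau_alpha <- -1
  expect_identical(sbr_log_prior(neg, inputs), -Inf)
  pos_bias <- params; pos_bias$b_survey <- 0.1
  expect_identical(sbr_log_prior(pos_bias, inputs), -Inf)
})

test_that("the unconstrained log-posterior gradient matches numerical differentiation", {
  skip_if_not_installed("pracma")
  inputs <- cached_tiny_inputs()
  lo <- stillbirthr:::theta_layout(inputs)
  set.seed(21)
  for (rep in 1:2) {
    th <- rnorm(lo$total, 0, 0.3)
    r <- sbr_lp_grad(th, inputs)
    expect_true(is.finite(r$lp))
    ng <- pracma::grad(function(t) sbr_lp_grad(t, inputs)$lp, th, heps = 1e-6)
    expect_lt(max(abs(r$grad - ng) / pmax(1, abs(ng))), 1e-5)
  }
})

test_that("the log posterior is finite at the generator's true parameters", {
  for (sd in 1:3) {
    w <- generate_world(world_config(n_regions = 2, countries_per_region = 2,
                                     years = 2000:2009, seed = sd))
    det <- apply_deterministic_rules(w$observations)
    adj <- suppressMessages(adjust_observations(det$kept, w$births))
    design <- build_design_matrix(smooth_covariate_table(w$covariates))
    inputs <- assemble_model_inputs(adj, design, w$births)
    params <- list(beta = w$truth$beta, hs_lambda = rep(1, 6), hs_tau = 0.05,
                   alpha_w = w$manifest$config$alpha_world,
                   alpha_r = w$truth$alpha_r, alpha_c = w$truth$alpha_c,
                   tau_alpha = w$manifest$config$tau_alpha,
                   tau_region = w$manifest$config$tau_region,
                   gamma = w$truth$gamma, tau_delta = w$truth$tau_delta,
                   mu_tau = log(w$manifest$config$tau_delta), sigma_tau = 0.3,
                   sigma_source = list(HMIS = 0.1, SURVEY = 0.15, STUDY = 0.1),
                   b_survey = w$manifest$config$b_survey)
    expect_true(is.finite(sbr_log_likelihood(params, inputs)))
    expect_true(is.finite(sbr_log_prior(params, inputs)))
  }
})
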