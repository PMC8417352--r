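test_that("split-Rhat matches the textbook formula", {
  set.seed(51)
  x <- cbind(rnorm(100), rnorm(100))
  # independent textbook implementation on the 4 half-chains
  halves <- cbind(x[1:50, 1], x[51:100, 1], x[1:50, 2], x[51:100, 2])
  n <- 50; m <- 4
  W <- mean(apply(halves, 2, var))
  B <- n * var(colMeans(halves))
  oracle <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(split_rhat(x), oracle, tolerance = 1e-10)

  # well-mixed chains sit near 1; separated chains are flagged
  expect_lt(split_rhat(x), 1.05)
  y <- cbind(rnorm(100, 0), rnorm(100, 5))
  expect_gt(split_rhat(y), 1.05)
  expect_true(is.na(split_rhat(cbind(rep(1, 100), rep(1, 100)))))
})

test_that("effective sample size reflects autocorrelation", {
  set.seed(52)
  iid <- cbind(rnorm(500), rnorm(500))
  expect_gt(ess_mean(iid), 500)           # near the nominal 1000
  ar <- matrix(0, 500, 2)
  for (ch in 1:2) {
    e <- rnorm(500)
    for (i in 2:500) ar[i, ch] <- 0.9 * ar[i - 1, ch] + e[i]
  }
  expect_lt(ess_mean(ar), 300)            # strongly autocorrelated
})

test_that("diagnostics summarise all parameters and require two chains", {
  fit <- cached_tiny_fit()
  d <- fit$diagnostics
  expect_true(all(c("table", "max_rhat", "min_ess", "pass") %in% names(d)))
  expect_equal(nrow(d$table), dim(fit$samples$draws)[2])
  one_chain <- fit$samples
  one_chain$draws <- one_chain$draws[, , 1, drop = FALSE]
  expect_error(mcmc_diagnostics(one_chain), "2 chains")
})

test_that("the posterior sampler is reproducible and converges on a tiny world", {
  w <- cached_world()
  fit <- cached_tiny_fit()
  expect_true(fit$diagnostics$pass)
  expect_lt(fit$diagnostics$max_rhat, 1.05)
  expect_gt(fit$diagnostics$min_ess, 100)

  inputs <- cached_tiny_inputs()
  s1 <- run_sbr_mcmc(inputs, mcmc_options(chains = 2, warmup = 50, draws = 20),
                     seed = 33L)
  s2 <- run_sbr_mcmc(inputs, mcmc_options(chains = 2, warmup = 50, draws = 20),
                     seed = 33L)
  expect_identical(s1$draws, s2$draws)          # same seed, same draws
  s3 <- run_sbr_mcmc(inputs, mcmc_options(chains = 2, warmup = 50, draws = 20),
                     seed = 34L)
  expect_false(identical(s1$draws[1, , 1], s3$draws[1, , 1]))
})

test_that("the generic HMC sampler recovers a known Gaussian and is deterministic", {
  lp_grad <- function(th) list(lp = -0.5 * sum((th - c(1, -2))^2 / c(1, 4)),
                               grad = -(th - c(1, -2)) / c(1, 4))
  opt <- mcmc_options(chains = 2, warmup = 300, draws = 700,
                      adapt_metric = TRUE)
  s <- run_hmc(lp_grad, c(0, 0), options = opt, seed = 3L)
  flat <- rbind(s$draws[, , 1], s$draws[, , 2])
  expect_equal(colMeans(flat), c(1, -2), tolerance = 0.15)
  expect_equal(apply(flat, 2, sd), c(1, 2), tolerance = 0.2)
  s2 <- run_hmc(lp_grad, c(0, 0), options = opt, seed = 3L)
  expect_identical(s$draws, s2$draws)
})

test_that("with no observations the posterior reproduces the prior", {
  w <- cached_world()
  det <- apply_deterministic_rules(w$observations)
  adj <- suppressMessages(adjust_observations(det$kept, w$births))
  design <- build_design_matrix(smooth_covariate_table(w$covariates))
  inputs <- assemble_model_inputs(adj[0, ], design, w$births)
  s <- run_sbr_mcmc(inputs, mcmc_options(chains = 2, warmup = 200, draws = 400),
                    seed = 9L)
  str <- s$structures
  flat <- rbind(s$draws[, , 1], s$draws[, , 2])
  aw <- flat[, str$idx_aw]
  op <- inputs$options
  # the world-level intercept should match its prior moments
  expect_lt(abs(mean(aw) - op$alpha_mean), 4 * op$alpha_sd / sqrt(50))
  expect_lt(abs(sd(aw) - op$alpha_sd), 0.3 * op$alpha_sd)
  # and latent rates should be far more dispersed than in a fitted model
  lat <- flat[, seq_len(str$d)] %*% t(str$Lmap)
  expect_gt(mean(apply(lat, 2, sd)), 0.5 * op$alpha_sd)
})

test_that("more draws do not worsen latent recovery on a fixed world", {
  w <- cached_world()
  truth <- as.numeric(t(w$truth$latent_log_rate))
  rmse <- function(draws) {
    fit <- suppressMessages(suppressWarnings(
      sbr_fit(w$observations, w$covariates, w$births,
              nmr_lookup = w$nmr_lookup, hq_ratios = w$hq_ratios,
              mcmc = mcmc_options(chains = 2, warmup = 200, draws = draws),
              seed = 61L)))
    sqrt(mean((apply(fit$latent, 2, median) - truth)^2))
  }
  r_small <- rmse(150)
  r_large <- rmse(600)
  expect_lt(r_large, r_small + 0.02)      # allowance for Monte-Carlo noise
})

test_that("posterior medians track precise data and intervals shrink with data", {
  cfg <- world_config(n_regions = 1, countries_per_region = 3,
                      years = 2000:2009, seed = 5L)
  w <- generate_world(cfg)                # its covariates/births; obs hand-built
  rate <- 6.0                              # per 1000, plausible for this income
  mk <- function(ct, yrs) {
    do.call(rbind, lapply(yrs, function(y) {
      s <- round(rate * 1e6 / 1000)
      obs_row(ct, y, 1000 * s / 1e6, source_type = "ADMIN",
              n_total_births = 1e6, n_stillbirths = s)
    }))
  }
  obs <- validate_sbr_observations(rbind(mk("C01", 2000:2009), mk("C02", c(2002, 2007))))
  fit <- suppressMessages(sbr_fit(obs, w$covariates, w$births,
                                  mcmc = mcmc_options(chains = 2, warmup = 300,
                                                      draws = 600),
                                  seed = 8L))
  est <- predict(fit)
  # data-rich country: median tracks the empirical log rate within the
  # observation standard deviation
  e1 <- est[est$country_code == "C01", ]
  obs_sd <- sqrt(sampling_variance(rate, 1e6, "ADMIN") +
                   fit$model_options$sigma_admin^2)
  mad <- mean(abs(log(e1$median / 1000) - log(rate / 1000)))
  expect_lt(mad, obs_sd)
  # interval width ordering: 10 observations < 2 observations < none
  width <- function(ct) {
    e <- est[est$country_code == ct, ]
    mean(log(e$ui_high) - log(e$ui_low))
  }
  expect_lt(width("C01"), width("C02"))
  expect_lt(width("C02"), width("C03"))
})
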