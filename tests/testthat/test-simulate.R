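test_that("a noise-free configuration reproduces the truth exactly", {
  cfg <- world_config(n_regions = 2, countries_per_region = 2,
                      years = 2000:2005,
                      sigma_source = c(ADMIN = 0, HMIS = 0, SURVEY = 0, STUDY = 0),
                      b_survey = 0, ga22_fraction = c(HIC = 0, LMIC_POOL = 0),
                      unspecified_fraction = 0, corrupt_fraction = 0,
                      sampling_noise = FALSE, seed = 3L)
  w <- generate_world(cfg)
  key <- paste(w$observations$country_code, w$observations$year)
  truth <- as.numeric(t(w$truth$latent_log_rate))
  names(truth) <- paste(rep(rownames(w$truth$latent_log_rate), each = 6),
                        rep(colnames(w$truth$latent_log_rate), 4))
  expect_equal(log(w$observations$sbr_observed / 1000), unname(truth[key]),
               tolerance = 1e-12)
})

test_that("world generation is deterministic given the seed", {
  w1 <- generate_world(tiny_config(seed = 5L))
  w2 <- generate_world(tiny_config(seed = 5L))
  expect_identical(w1$observations, w2$observations)
  expect_identical(w1$truth$latent_log_rate, w2$truth$latent_log_rate)
  w3 <- generate_world(tiny_config(seed = 6L))
  expect_false(identical(w1$observations, w3$observations))
})

test_that("survey observations carry the configured negative bias on average", {
  op <- default_obs_prob()
  op[] <- 0
  op[, "SURVEY"] <- 1                      # every country-year, surveys only
  cfg <- world_config(n_regions = 4, countries_per_region = 5,
                      years = 2000:2019, obs_prob = op,
                      ga22_fraction = c(HIC = 0, LMIC_POOL = 0),
                      unspecified_fraction = 0, corrupt_fraction = 0,
                      seed = 9L)
  w <- generate_world(cfg)
  expect_true(all(w$observations$source_type == "SURVEY"))
  pv <- w$truth$provenance
  err <- log(w$observations$sbr_observed / 1000) -
    pv$true_log_rate[match(paste(w$observations$country_code, w$observations$year),
                           paste(pv$country_code, pv$year))]
  n <- length(err)
  se <- sd(err) / sqrt(n)
  expect_lt(abs(mean(err) - cfg$b_survey), 4 * se)
})

test_that("generated 22-week observations embed the configured definitional ratios", {
  cfg <- world_config(ga22_fraction = c(HIC = 1, LMIC_POOL = 1),
                      unspecified_fraction = 0, corrupt_fraction = 0,
                      sigma_source = c(ADMIN = 0, HMIS = 0, SURVEY = 0, STUDY = 0),
                      b_survey = 0, sampling_noise = FALSE, seed = 13L)
  w <- generate_world(cfg)
  pv <- w$truth$provenance
  income <- w$births$income_group[match(pv$country_code, w$births$country_code)]
  ratio <- exp(log(w$observations$sbr_observed / 1000) - pv$true_log_rate -
                 pv$def_err)
  for (ic in c("HIC", "LMIC_POOL")) {
    sel <- income_class_of(income) == ic
    est <- estimate_adjustment_ratio(ratio[sel], rep(1, sum(sel)),
                                     income_class = ic)
    expect_equal(est$ratio_mean, if (ic == "HIC") 1.5 else 1.2,
                 tolerance = 1e-9)
  }
})

test_that("clean observations sit above corrupt ones on the SBR:NMR scale", {
  w <- cached_world("default", world_config(seed = 21L))
  pv <- w$truth$provenance
  obs <- w$observations
  key <- function(d) paste(d$country_code, d$year, d$source_type, d$definition)
  m <- match(key(obs), key(pv))
  nmr <- w$nmr_lookup$nmr[match(paste(obs$country_code, obs$year),
                                paste(w$nmr_lookup$country_code, w$nmr_lookup$year))]
  ratio <- obs$sbr_observed / nmr
  corrupt <- pv$corrupt[m]
  expect_gt(median(ratio[!corrupt]), median(ratio[corrupt]))
  expect_gt(mean(ratio[!corrupt] > median(ratio[corrupt])), 0.8)
})

test_that("fixtures round-trip through the loaders without loss", {
  w <- cached_world()
  dir <- withr::local_tempdir()
  write_world_fixture(w, dir)
  r <- suppressMessages(read_world_fixture(dir))
  expect_equal(as.data.frame(r$observations), as.data.frame(w$observations))
  expect_equal(as.data.frame(r$covariates), as.data.frame(w$covariates),
               tolerance = 1e-12)
  expect_equal(as.data.frame(r$births), as.data.frame(w$births),
               tolerance = 1e-12)
  expect_equal(r$manifest$seed, w$manifest$seed)
  expect_equal(nrow(r$truth),
               nrow(w$truth$latent_log_rate) * ncol(w$truth$latent_log_rate))
  expect_equal(r$hq_ratios, w$hq_ratios, tolerance = 1e-12)
})

test_that("degenerate configurations fail loudly", {
  cfg <- tiny_config()
  cfg$obs_prob[] <- 0
  expect_error(generate_world(cfg), "no observations")
})
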