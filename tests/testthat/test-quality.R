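test_that("deterministic rules exclude on coverage, completeness and definition", {
  obs <- validate_sbr_observations(rbind(
    obs_row("AAA", 2001, 14, source_type = "ADMIN", livebirth_coverage = 0.79),
    obs_row("BBB", 2001, 14, source_type = "HMIS", livebirth_coverage = 0.76),
    obs_row("CCC", 2001, 14, unknown_ga_fraction = 0.51),
    obs_row("DDD", 2001, 14, source_type = "ADMIN", child_death_completeness = 0.94),
    obs_row("EEE", 2001, 14, definition = "UNSPECIFIED"),
    obs_row("FFF", 2001, 14)))                     # no metadata: all rules skip
  res <- apply_deterministic_rules(obs)
  reasons <- setNames(res$excluded$reason, res$excluded$country_code)
  expect_equal(reasons[["AAA"]], "LIVEBIRTH_COVERAGE_LT_80")
  expect_equal(reasons[["CCC"]], "UNKNOWN_GA_GT_50")
  expect_equal(reasons[["DDD"]], "DEATH_COMPLETENESS_LT_95")
  expect_equal(reasons[["EEE"]], "NO_DEFINITION")
  # HMIS coverage threshold is the laxer 75%
  expect_true(all(c("BBB", "FFF") %in% res$kept$country_code))
  expect_equal(nrow(res$kept) + nrow(res$excluded), nrow(obs))
})

test_that("externally flagged observations are excluded with their own reason", {
  obs <- validate_sbr_observations(rbind(obs_row("AAA"), obs_row("BBB")))
  flags <- data.frame(country_code = "BBB", year = 2005L,
                      source_type = "ADMIN", definition = "GA28")
  res <- apply_deterministic_rules(obs, external_flags = flags)
  expect_equal(res$excluded$reason, "EXTERNAL_FLAG")
  expect_equal(res$kept$country_code, "AAA")
})

test_that("the ratio reference is a lognormal fitted by log moments", {
  r10 <- c(0.8, 1.0, 1.25, 1.5, 2.0, 1.1, 0.9, 1.3, 1.6, 1.05)
  ref <- fit_ratio_reference(r10)
  expect_equal(ref$meanlog, mean(log(r10)))        # arithmetic oracle
  expect_equal(ref$sdlog, sd(log(r10)))
  expect_equal(ref$n_source, 10L)

  expect_error(fit_ratio_reference(rep(1.2, 10)), "degenerate")
  expect_error(fit_ratio_reference(r10[1:5]), "at least 10")
  expect_error(fit_ratio_reference(c(r10, -1)), "> 0")

  # parametric recovery within Monte-Carlo tolerance (4 standard errors)
  set.seed(77)
  draws <- rlnorm(500, log(1.2), 0.3)
  rec <- fit_ratio_reference(draws)
  expect_lt(abs(rec$meanlog - log(1.2)), 4 * 0.3 / sqrt(500))
  expect_lt(abs(rec$sdlog - 0.3), 4 * 0.3 / sqrt(2 * 500))
})

test_that("the plausibility probability matches closed forms and quadrature", {
  ref <- fit_ratio_reference(rlnorm(50, log(1.2), 0.3))
  ref$meanlog <- log(1.2); ref$sdlog <- 0.3        # pin exact parameters

  # at the reference median with no observation uncertainty: exactly 1/2
  expect_equal(ratio_plausibility_probability(1.2, 0, ref), 0.5)
  # deep left tail
  expect_lt(ratio_plausibility_probability(0.01, 0, ref), 1e-6)
  # against an independent numerical-integration oracle
  r_obs <- 0.7; r_se <- 0.1
  cv <- r_se / r_obs
  sdl <- sqrt(log1p(cv^2)); mul <- log(r_obs) - sdl^2 / 2
  oracle <- integrate(function(r) dlnorm(r, mul, sdl) * plnorm(r, log(1.2), 0.3),
                      0, Inf, rel.tol = 1e-10)$value
  mc <- ratio_plausibility_probability(r_obs, r_se, ref, n_draws = 1e5)
  expect_lt(abs(mc - oracle), 0.005)

  expect_error(ratio_plausibility_probability(-1, 0, ref), "r_obs")
  expect_error(ratio_plausibility_probability(1, -0.1, ref), "r_se")
})

test_that("the plausibility probability is monotone in the observed ratio", {
  ref <- fit_ratio_reference(rlnorm(100, log(0.8), 0.2))
  p <- vapply(seq(0.2, 1.6, by = 0.2), function(r)
    ratio_plausibility_probability(r, 0.08, ref, seed = 5L), numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("implausible-ratio exclusion is strict at the threshold", {
  ref <- fit_ratio_reference(rlnorm(100, log(0.8), 0.2))
  ref$meanlog <- log(0.8); ref$sdlog <- 0.2
  nmr <- data.frame(country_code = c("AAA", "CCC"), year = 2005L,
                    nmr = 10, nmr_se = 0)
  low_r <- 10 * qlnorm(0.03, ref$meanlog, ref$sdlog)
  obs <- validate_sbr_observations(rbind(
    obs_row("AAA", sbr_observed = low_r),
    obs_row("CCC", sbr_observed = 10 * 0.8)))       # at the reference median
  obs$log_adjusted_mean <- log(obs$sbr_observed)
  obs$def_log_var <- 0
  novar <- list(ADMIN = 0, HMIS = 0, SURVEY = 0, STUDY = 0)
  p_low <- ratio_plausibility_probability(low_r / 10, 0, ref)

  # probability below alpha: excluded with the probability recorded
  res <- exclude_implausible(obs, nmr, ref, source_var_defaults = novar,
                             default_nmr_cv = 0)
  expect_equal(res$excluded$country_code, "AAA")
  expect_equal(res$excluded$reason, "IMPLAUSIBLE_RATIO")
  expect_equal(res$excluded$probability, p_low, tolerance = 1e-12)
  expect_true("CCC" %in% res$kept$country_code)      # median ratio is kept

  # a probability exactly equal to alpha is kept (strict "<")
  p_exact <- res$excluded$probability          # the probability as computed
  res_eq <- exclude_implausible(obs, nmr, ref,
                                thresholds = qc_thresholds(alpha = p_exact),
                                source_var_defaults = novar, default_nmr_cv = 0)
  expect_true("AAA" %in% res_eq$kept$country_code)
  res_above <- exclude_implausible(obs, nmr, ref,
                                   thresholds = qc_thresholds(alpha = p_exact * 1.001),
                                   source_var_defaults = novar,
                                   default_nmr_cv = 0)
  expect_equal(res_above$excluded$country_code, "AAA")
})

test_that("an observation under-reporting stillbirths by 70% is excluded", {
  ref <- fit_ratio_reference(rlnorm(100, log(0.8), 0.15))
  nmr <- data.frame(country_code = "AAA", year = 2005L, nmr = 20)
  true_sbr <- 0.8 * 20
  obs <- validate_sbr_observations(
    obs_row("AAA", sbr_observed = 0.3 * true_sbr,
            n_total_births = 5e4, n_stillbirths = round(0.3 * true_sbr * 50)))
  obs$log_adjusted_mean <- log(obs$sbr_observed)
  obs$def_log_var <- 0
  res <- exclude_implausible(obs, nmr, ref)
  expect_equal(nrow(res$kept), 0)
})

test_that("observations without any NMR are skipped with a warning, not excluded", {
  ref <- fit_ratio_reference(rlnorm(100, log(0.8), 0.2))
  obs <- validate_sbr_observations(obs_row("ZZZ"))
  obs$log_adjusted_mean <- log(obs$sbr_observed); obs$def_log_var <- 0
  empty_nmr <- data.frame(country_code = character(0), year = integer(0),
                          nmr = numeric(0))
  expect_warning(res <- exclude_implausible(obs, empty_nmr, ref), "no NMR")
  expect_equal(nrow(res$kept), 1)
})

test_that("the exclusion report partitions the input and summarises counts", {
  w <- cached_world()
  det <- apply_deterministic_rules(w$observations)
  adj <- adjust_observations(det$kept, w$births)
  ref <- fit_ratio_reference(w$hq_ratios)
  rt <- suppressWarnings(exclude_implausible(adj, w$nmr_lookup, ref))
  excluded <- rbind(det$excluded, rt$excluded)
  expect_equal(nrow(rt$kept) + nrow(excluded), nrow(w$observations))

  path <- withr::local_tempfile(fileext = ".csv")
  s <- write_exclusion_report(w$observations, excluded, path)
  expect_equal(s$n_input, nrow(w$observations))
  expect_equal(s$n_kept + s$n_excluded, s$n_input)
  rep <- read.csv(path, comment.char = "#")
  expect_equal(nrow(rep), nrow(w$observations))
  expect_equal(sum(!rep$kept), nrow(excluded))
})
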