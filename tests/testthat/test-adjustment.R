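test_that("adjustment ratios are estimated as geometric means with sample variance", {
  # identity pairs
  id <- estimate_adjustment_ratio(c(10, 12, 14), c(10, 12, 14))
  expect_equal(id$ratio_mean, 1.0)
  expect_equal(id$ratio_var, 0.0)

  # brute-force oracle over the three per-pair ratios {1.2, 1.5, 1.5}
  a <- estimate_adjustment_ratio(c(12, 15, 18), c(10, 10, 12),
                                 income_class = "HIC")
  ratios <- c(12 / 10, 15 / 10, 18 / 12)
  expect_equal(a$ratio_mean, exp(mean(log(ratios))))
  expect_equal(a$ratio_mean, 1.3924766, tolerance = 1e-6)
  expect_equal(a$ratio_var, var(ratios))
  expect_equal(a$n_pairs, 3L)

  expect_error(estimate_adjustment_ratio(c(1, 2), c(1, 2)), "3 pairs")
  expect_error(estimate_adjustment_ratio(c(1, -2, 3), c(1, 2, 3)), "> 0")
})

test_that("a known 1.5 ratio is recovered from noisy paired data", {
  set.seed(201)
  ga28 <- rlnorm(200, log(8), 0.4)
  alt <- 1.5 * ga28 * rlnorm(200, -0.1^2 / 2, 0.1)   # 10% lognormal noise
  est <- estimate_adjustment_ratio(alt, ga28, income_class = "HIC")
  expect_gt(est$ratio_mean, 1.45)
  expect_lt(est$ratio_mean, 1.55)
})

test_that("the packaged defaults carry the published 22-week ratios", {
  tab <- default_adjustment_table()
  hic <- lookup_adjustment("GA22", "HIC", tab)
  lmic <- lookup_adjustment("GA22", "LMIC_GROUP", tab)
  expect_equal(hic$ratio_mean, 1.5)
  expect_equal(lmic$ratio_mean, 1.2)
  # LIC and UMIC pool with the low/middle income class
  expect_equal(lookup_adjustment("GA22", "LIC", tab)$ratio_mean, 1.2)
  expect_equal(lookup_adjustment("GA22", "UMIC", tab)$ratio_mean, 1.2)
  # GA28 is the identity; UNSPECIFIED signals unadjustable
  id <- lookup_adjustment("GA28", "HIC", tab)
  expect_equal(c(id$ratio_mean, id$ratio_var), c(1, 0))
  expect_error(lookup_adjustment("UNSPECIFIED", "HIC", tab),
               class = "sbr_unadjustable")
})

test_that("applying an adjustment rescales the rate and propagates variance", {
  hic <- lookup_adjustment("GA22", "HIC")
  adj <- apply_adjustment(15.0, hic)
  expect_equal(exp(adj$log_adjusted_mean), 10.0)     # 15 / 1.5

  ga28 <- apply_adjustment(12.3, identity_adjustment())
  expect_equal(exp(ga28$log_adjusted_mean), 12.3)
  expect_equal(ga28$def_log_var, 0)

  # delta method: var(log ratio) ~ ratio_var / ratio_mean^2, cross-checked
  # against a Monte-Carlo oracle on the log of ratio draws
  r <- structure(list(definition = "GA22", income_class = "LMIC_POOL",
                      ratio_mean = 1.2, ratio_var = 0.09, n_pairs = 50),
                 class = "adjustment_ratio")
  a <- apply_adjustment(10, r)
  expect_equal(a$def_log_var, 0.09 / 1.44)
  expect_equal(a$def_log_var, 0.0625)
  # MC oracle: ratio draws on the log scale with matching mean and variance
  set.seed(11)
  cv <- sqrt(0.09) / 1.2
  sdl <- sqrt(log1p(cv^2))
  draws <- rlnorm(1e5, log(1.2) - sdl^2 / 2, sdl)
  expect_equal(a$def_log_var, var(log(draws)), tolerance = 0.05)
})

test_that("adjustment properties: inversion, direction, delta-method accuracy", {
  tab <- default_adjustment_table()
  for (i in seq_len(nrow(tab))) {
    adj <- lookup_adjustment(tab$definition[i],
                             if (tab$income_class[i] == "HIC") "HIC" else "LIC",
                             tab)
    rate <- 17.3
    a <- apply_adjustment(rate, adj)
    expect_equal(invert_adjustment(a$log_adjusted_mean, adj), rate,
                 tolerance = 1e-12)
    if (adj$ratio_mean >= 1)
      expect_lte(exp(a$log_adjusted_mean), rate)
    # MC oracle for the log-scale variance where the ratio CV < 0.3
    cv <- sqrt(adj$ratio_var) / adj$ratio_mean
    if (cv > 0 && cv < 0.3) {
      set.seed(100 + i)
      sdl <- sqrt(log1p(cv^2))
      d <- rlnorm(2e5, log(adj$ratio_mean) - sdl^2 / 2, sdl)
      expect_lt(abs(a$def_log_var - var(log(d))) / var(log(d)), 0.05)
    }
  }
})

test_that("whole-table adjustment appends GA28-scale columns", {
  w <- cached_world()
  det <- apply_deterministic_rules(w$observations)
  adj <- adjust_observations(det$kept, w$births)
  expect_true(all(c("log_adjusted_mean", "def_log_var") %in% names(adj)))
  ga28 <- adj$definition == "GA28"
  expect_equal(adj$log_adjusted_mean[ga28], log(adj$sbr_observed[ga28]))
  expect_true(all(adj$def_log_var[ga28] == 0))
  expect_true(all(adj$def_log_var[!ga28] > 0))
  # adjusting before deterministic QC (UNSPECIFIED present) is an error
  if (any(w$observations$definition == "UNSPECIFIED"))
    expect_error(adjust_observations(w$observations, w$births), "UNSPECIFIED")
})
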