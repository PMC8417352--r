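# Shared synthetic worlds and fits, built once per test run.
.world_cache <- new.env(parent = emptyenv())

tiny_config <- function(seed = 42L) {
  world_config(n_regions = 2, countries_per_region = 2, years = 2000:2009,
               n_hq_ratios = 30, seed = seed)
}

cached_world <- function(key = "tiny", config = tiny_config()) {
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- generate_world(config)
  .world_cache[[key]]
}

# A small fitted model reused across method tests.
cached_tiny_fit <- function() {
  if (is.null(.world_cache$fit)) {
    w <- cached_world()
    .world_cache$fit <- suppressMessages(suppressWarnings(
      sbr_fit(w$observations, w$covariates, w$births,
              nmr_lookup = w$nmr_lookup, hq_ratios = w$hq_ratios,
              mcmc = mcmc_options(chains = 2, warmup = 500, draws = 1500),
              seed = 7L)))
  }
  .world_cache$fit
}

# Inputs assembled for model-level tests (no MCMC).
cached_tiny_inputs <- function() {
  if (is.null(.world_cache$inputs)) {
    w <- cached_world()
    det <- apply_deterministic_rules(w$observations)
    adj <- suppressMessages(adjust_observations(det$kept, w$births))
    cov_s <- smooth_covariate_table(w$covariates)
    design <- build_design_matrix(cov_s)
    .world_cache$inputs <- assemble_model_inputs(adj, design, w$births)
  }
  .world_cache$inputs
}

obs_row <- function(country_code = "AAA", year = 2005L, sbr_observed = 14,
                    definition = "GA28", source_type = "ADMIN",
                    n_total_births = NA, n_stillbirths = NA,
                    nmr_same_source = NA, unknown_ga_fraction = NA,
                    livebirth_coverage = NA, child_death_completeness = NA) {
  data.frame(country_code = country_code, year = year,
             sbr_observed = sbr_observed, definition = definition,
             source_type = source_type, n_total_births = n_total_births,
             n_stillbirths = n_stillbirths, nmr_same_source = nmr_same_source,
             unknown_ga_fraction = unknown_ga_fraction,
             livebirth_coverage = livebirth_coverage,
             child_death_completeness = child_death_completeness,
             stringsAsFactors = FALSE)
}
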