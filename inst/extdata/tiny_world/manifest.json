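{
  "seed": 42,
  "config": {
    "n_regions": 2,
    "countries_per_region": 2,
    "years": [2000, 2001, 2002, 2003, 2004, 2005, 2006, 2007, 2008, 2009],
    "beta_true": [0.5, 0.2, 0, 0, 0, 0],
    "alpha_world": -4.26869794936688,
    "tau_region": 0.15,
    "tau_alpha": 0.2,
    "tau_delta": 0.05,
    "tau_delta_spread": 0.3,
    "obs_prob": [
      [0.02, 0.2, 0.25, 0.1],
      [0.1, 0.3, 0.25, 0.08],
      [0.6, 0.1, 0.05, 0.05],
      [0.9, 0, 0, 0.02]
    ],
    "sigma_source": [0.01, 0.1, 0.15, 0.1],
    "b_survey": -0.1,
    "ga22_fraction": [0.3, 0.15],
    "unspecified_fraction": 0.05,
    "corrupt_fraction": 0.15,
    "underreport_factor": 0.5,
    "sbr_nmr_ratio_true": 0.8,
    "ratio_noise_sd": 0.15,
    "n_hq_ratios": 30,
    "design_effect": 2,
    "covariate_noise_sd": 0.02,
    "sampling_noise": true,
    "seed": 42
  },
  "n_observations": 43
}
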