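# Shared fixture builders; everything is generated in code at test time.

# Small noiseless panel whose grid hits 0, t_peak and tau_true, so the
# duration estimator and trapezoid integration are exact.
noiseless_spec <- function(beta = 0.03, tau = 45, baseline = 1000,
                           n_mol = 1, seed = 1) {
  mols <- dplyr::bind_rows(lapply(seq_len(n_mol), function(i) {
    molecule_spec(paste0("M", i), baseline_intensity = baseline,
                  pulse_amplitude = amplitude_for_str(beta, tau, baseline),
                  t_peak = 15, tau_true = tau)
  }))
  dataset_spec(mols, noise_cv = 0, seed = seed)
}

# Panel for parameter-recovery runs: two molecules with identical STR, one
# clearly different, one inactive.
recovery_spec <- function(seed, noise_cv = 0.08, n_replicates = 6) {
  mk <- function(id, beta) {
    molecule_spec(id, baseline_intensity = 1000,
                  pulse_amplitude = if (beta > 0) {
                    amplitude_for_str(beta, 45, 1000)
                  } else 0,
                  t_peak = 15, tau_true = 45)
  }
  dataset_spec(
    dplyr::bind_rows(mk("eqA", 0.02), mk("eqB", 0.02),
                     mk("far", 0.04), mk("off", 0)),
    noise_cv = noise_cv, n_replicates = n_replicates, seed = seed
  )
}

# Hand-built posterior summary with prescribed draws, for testing the
# pairwise statistics against closed forms.
make_posterior <- function(mu_draws, sigma_draws, id = "X") {
  structure(
    list(molecule_id = id, eap_mu = mean(mu_draws),
         post_sd = stats::sd(mu_draws), r_hat = 1,
         mu_draws = mu_draws, sigma_draws = sigma_draws,
         n_used = 6L, converged = TRUE),
    class = "posterior_summary"
  )
}

fast_mcmc <- function(seed = 1) {
  mcmc_config(n_chains = 4, n_draws = 1500, n_warmup = 500, seed = seed)
}
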