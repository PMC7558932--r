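# fixture builders shared across test files

constant_series <- function(n = 100, rr = 800) {
  ibi_series(rep(rr, n))
}

# a stationary noisy tachogram long enough for the 5-min analysis window
noisy_series <- function(seed, noise_sd = 20, duration = 360, mean_rr = 800) {
  simulate_ibi(mean_rr = mean_rr, noise_sd = noise_sd, duration = duration,
               seed = seed)
}

quick_mcmc <- function(seed = NULL, n_save = 1500) {
  mcmc_config(n_save = n_save, seed = seed)
}
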