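# Shared small fixtures, built once per test run.

# A compact simulated session: 16 channels, 90-s blocks (~3500 fNIRS samples),
# high-SNR preset with full interaction. Used by several suites.
small_session <- local({
  cache <- NULL
  function(seed = 5L, interaction_strength = 1, snr = "high") {
    key <- paste(seed, interaction_strength, snr)
    if (!is.null(cache) && cache$key == key) return(cache$value)
    cfg <- experiment_config(n_channels = 16L, block_duration = 90,
                             seed = seed)
    ps <- study_presets(snr, n_channels = 16L,
                        interaction_strength = interaction_strength)
    sim <- simulate_experiment(cfg, act = ps$act, noise = ps$noise,
                               seed = seed, n_bad_channels = 0L)
    prep <- preprocess_recording(sim$raw, sim$layout, sim$design$labels,
                                 behavior = sim$behavior)
    cache <<- list(key = key, value = list(sim = sim, prep = prep, cfg = cfg))
    cache$value
  }
})

# Data whose sample correlation matrix has exactly the requested eigenvalues
# {2, 0.9, 0.1}: a closed-form 3x3 correlation matrix (unit diagonal) with
# those eigenvalues, imposed exactly on whitened noise.
correlated_triplet <- function(n = 500L, seed = 42L) {
  # C = [[1, a, a], [a, 1, c], [a, c, 1]] with c = 0.1, a = sqrt(0.45)
  # has eigenvalues {2, 0.9, 0.1}.
  a <- sqrt(0.45)
  cmat <- matrix(c(1, a, a,
                   a, 1, 0.1,
                   a, 0.1, 1), 3, 3)
  set.seed(seed)
  z <- matrix(rnorm(n * 3), n, 3)
  z <- scale(z, scale = FALSE)
  z <- z %*% solve(chol(crossprod(z) / (n - 1)))   # exact identity covariance
  z %*% chol(cmat)
}
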