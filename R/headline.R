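#' Headline decoding experiment: separate vs. combined models over a cohort
#'
#' Simulates `n_seeds` participants at the given interaction strength and
#' decodes driving difficulty with the nested cross-validated ridge-logistic
#' pipeline, per WML level and combined over levels. This is the package's
#' compact reproduction of the study's central contrast: with a full
#' difficulty-by-WML interaction the per-level models decode well while the
#' combined model stays at chance; without interaction the combined model
#' matches the per-level models.
#'
#' @param n_seeds number of simulated participants.
#' @param base_seed participant `i` uses seed `base_seed + i`.
#' @param interaction_strength difficulty-by-WML interaction in `[0, 1]`.
#' @param n_channels channels per recording.
#' @param block_duration block length (s); 90 s gives ~700 samples per
#'   per-level model.
#' @param snr preset passed to [study_presets()].
#' @return list with `per_level` (`n_seeds x n_levels` accuracy matrix, %),
#'   `combined` (length-`n_seeds` vector, %), and their means
#'   (`per_level_means`, `per_level_grand_mean`, `combined_mean`).
#' @export
run_headline_cohort <- function(n_seeds = 10L, base_seed = 100L,
                                interaction_strength = 1,
                                n_channels = 16L, block_duration = 90,
                                snr = "high") {
  per_level <- NULL
  combined <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    sd_i <- base_seed + i
    cfg <- experiment_config(n_channels = n_channels,
                             block_duration = block_duration, seed = sd_i)
    ps <- study_presets(snr, n_channels = n_channels,
                        interaction_strength = interaction_strength)
    sim <- simulate_experiment(cfg, act = ps$act, noise = ps$noise,
                               seed = sd_i, n_bad_channels = 0L)
    prep <- preprocess_recording(sim$raw, sim$layout, sim$design$labels,
                                 behavior = sim$behavior)
    pl <- suppressWarnings(nested_cv_decode(prep$hemo, prep$labels,
                                            mode = "per_level"))
    cb <- suppressWarnings(nested_cv_decode(prep$hemo, prep$labels,
                                            mode = "combined"))
    per_level <- rbind(per_level,
                       vapply(pl, function(r) r$accuracy, numeric(1)))
    combined[i] <- cb$accuracy
  }
  list(per_level = per_level, combined = combined,
       per_level_means = colMeans(per_level),
       per_level_grand_mean = mean(per_level),
       combined_mean = mean(combined))
}

#' Label-permutation null for the decoder
#'
#' Simulates one session, preprocesses it, restricts to one WML level's cell
#' pair, and repeatedly decodes with randomly permuted difficulty labels.
#' With no label-feature association the out-of-fold accuracy should scatter
#' around the majority-class rate (~50% in the behaviorally balanced 0-back
#' cell); this is the package's leakage check.
#'
#' @param n_permutations number of label permutations.
#' @param seed seed for the simulated session.
#' @param wml_level which level's cell pair to use (0-back is balanced).
#' @param n_channels,block_duration session size.
#' @return numeric vector of permuted-label accuracies (%).
#' @export
permutation_null <- function(n_permutations = 100L, seed = 11L,
                             wml_level = 0L, n_channels = 16L,
                             block_duration = 90) {
  cfg <- experiment_config(n_channels = n_channels,
                           block_duration = block_duration, seed = seed)
  ps <- study_presets("high", n_channels = n_channels,
                      interaction_strength = 1)
  sim <- simulate_experiment(cfg, act = ps$act, noise = ps$noise,
                             seed = seed, n_bad_channels = 0L)
  prep <- preprocess_recording(sim$raw, sim$layout, sim$design$labels,
                               behavior = sim$behavior)
  lab <- prep$labels[prep$labels$valid, ]
  x <- prep$hemo$hbr[prep$labels$valid, ]
  sub <- which(lab$wml_level == wml_level)
  y <- lab$difficulty[sub] == "construction"
  vapply(seq_len(n_permutations), function(i) {
    yp <- with_seed(derive_seed(seed, 100L + i), sample(y))
    suppressWarnings(nested_cv_core(x[sub, , drop = FALSE], yp))$accuracy
  }, numeric(1))
}
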