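#' Activation and noise presets for simulated studies
#'
#' Bundles an [activation_spec()] and [noise_spec()] for two signal-to-noise
#' regimes. `"default"` is a moderate-SNR regime with physiological noise and
#' motion at realistic relative magnitudes; `"high"` strengthens the
#' difficulty response and weakens physiological/instrumental noise (motion
#' stays large — it is removed by first-PC deletion) so that per-level
#' decoding approaches ceiling, which is the regime used for
#' pattern-recovery checks.
#'
#' @param snr `"default"` or `"high"`.
#' @param n_channels,n_wml_levels passed to [activation_spec()].
#' @param interaction_strength difficulty-by-WML interaction mixing factor.
#' @param ... further arguments passed to [activation_spec()].
#' @return list with `act` and `noise`.
#' @export
study_presets <- function(snr = c("default", "high"), n_channels = 78L,
                          n_wml_levels = 5L, interaction_strength = 0, ...) {
  snr <- match.arg(snr)
  if (snr == "high") {
    act <- activation_spec(n_channels = n_channels,
                           n_wml_levels = n_wml_levels,
                           wml_amp = 1e-4, difficulty_amp = 1.2e-3,
                           interaction_strength = interaction_strength, ...)
    noise <- noise_spec(cardiac_amp = 2e-5, resp_amp = 2e-5, mayer_amp = 2e-5,
                        white_sd = 2e-5, spike_rate_per_min = 6,
                        spike_amp = 3e-4, shift_amp = 2e-4, shift_tau = 20,
                        gain_jitter_sd = 0.05)
  } else {
    act <- activation_spec(n_channels = n_channels,
                           n_wml_levels = n_wml_levels,
                           wml_amp = 1e-4, difficulty_amp = 2.5e-4,
                           interaction_strength = interaction_strength, ...)
    noise <- noise_spec()
  }
  list(act = act, noise = noise)
}

#' Simulate a complete single-participant experiment
#'
#' Runs the full forward model: block design and speed signs, ground-truth
#' hemodynamics, physiological/motion noise, raw optical intensities through
#' the modified Beer-Lambert forward model (optionally with corrupted
#' channels), and driving behavior.
#'
#' @param config an [experiment_config()].
#' @param act an [activation_spec()] (default from [study_presets()]).
#' @param noise a [noise_spec()].
#' @param bspec a [behavior_spec()].
#' @param layout an [optode_layout()].
#' @param seed master seed for all stages.
#' @param n_bad_channels channels corrupted with high-variance drift to
#'   exercise QC rejection.
#' @return list of class `sim_experiment`: `design`, `truth` (noise-free
#'   series), `hemo` (noisy series), `raw`, `behavior`, `layout`, `config`,
#'   `seed`.
#' @export
simulate_experiment <- function(config = experiment_config(),
                                act = NULL, noise = NULL, bspec = NULL,
                                layout = NULL,
                                seed = config$seed,
                                n_bad_channels = 5L) {
  preset <- study_presets("default", n_channels = config$n_channels,
                          n_wml_levels = config$n_wml_levels)
  act <- act %||% preset$act
  noise <- noise %||% preset$noise
  bspec <- bspec %||% behavior_spec(n_wml_levels = config$n_wml_levels)
  layout <- layout %||% optode_layout(config$n_channels)
  design <- generate_design(config, seed = seed)
  truth <- generate_hemodynamics(design, act)
  hemo <- add_noise(truth, noise, seed = seed)
  raw <- forward_mbll(hemo, layout)
  if (n_bad_channels > 0) {
    raw <- inject_bad_channels(raw, k = n_bad_channels, seed = seed)
  }
  behavior <- generate_behavior(design, bspec, seed = seed)
  structure(list(design = design, truth = truth, hemo = hemo, raw = raw,
                 behavior = behavior, layout = layout, config = config,
                 seed = seed),
            class = "sim_experiment")
}

#' Preprocess a raw recording to analysis-ready HbR
#'
#' The standard chain: channel QC by coefficient of variation on the
#' unfiltered raw intensities; optical density; zero-phase least-squares FIR
#' low-pass; modified Beer-Lambert inversion; behavioral segment exclusion.
#' PCA denoising is NOT applied here — it is fitted inside training folds by
#' the decoder (and per condition by the univariate map analysis).
#'
#' @param raw a `raw_intensity` recording.
#' @param layout an [optode_layout()].
#' @param labels label track from the design.
#' @param behavior optional `behavior_track` for segment exclusion.
#' @param cv_threshold CV exclusion threshold (%).
#' @param cutoff low-pass passband edge (Hz).
#' @param tolerance,criterion segment-exclusion parameters.
#' @return list of class `preprocessed`: `hemo` (HbR/HbO series with the QC
#'   channel mask), `labels` (validity updated), `qc`.
#' @export
preprocess_recording <- function(raw, layout, labels, behavior = NULL,
                                 cv_threshold = 20, cutoff = 0.1,
                                 tolerance = 5, criterion = 0.90) {
  qc <- channel_cv(raw, threshold = cv_threshold)
  od <- optical_density(raw)
  od <- lowpass_series(od, cutoff = cutoff)
  hemo <- mbll_invert(od, layout)
  hemo$channel_mask <- hemo$channel_mask & !qc$excluded
  labels <- exclude_invalid_segments(labels, behavior, tolerance = tolerance,
                                     criterion = criterion)
  structure(list(hemo = hemo, labels = labels, qc = qc),
            class = "preprocessed")
}

#' Run configuration for the full pipeline
#'
#' Validates and bundles every stage parameter. Unknown fields are rejected;
#' the configuration is serialized into the result bundle for provenance.
#'
#' @param config an [experiment_config()].
#' @param snr preset name for [study_presets()].
#' @param interaction_strength difficulty-by-WML interaction.
#' @param seed master seed.
#' @param cv_threshold,cutoff,tolerance,criterion preprocessing parameters.
#' @param k_outer,k_inner,eigen_threshold,drop_first decoding parameters.
#' @param lambda_grid ridge penalty grid.
#' @param run_pairwise compute the 45-pairing dissimilarity matrix (the most
#'   expensive stage)?
#' @param n_bad_channels corrupted channels injected into the simulation.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(config = experiment_config(), snr = "default",
                       interaction_strength = 0, seed = config$seed,
                       cv_threshold = 20, cutoff = 0.1,
                       tolerance = 5, criterion = 0.90,
                       k_outer = 5L, k_inner = 5L,
                       eigen_threshold = 0.7, drop_first = TRUE,
                       lambda_grid = lambda_grid_default(),
                       run_pairwise = FALSE, n_bad_channels = 5L,
                       out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"),
            snr %in% c("default", "high"),
            interaction_strength >= 0, interaction_strength <= 1,
            cv_threshold > 0, cutoff > 0, cutoff < config$fs_nirs / 2,
            tolerance > 0, criterion > 0, criterion <= 1,
            k_outer >= 2, k_inner >= 2, eigen_threshold >= 0,
            all(lambda_grid > 0))
  if (!is.null(out_dir) && !dir.exists(dirname(out_dir))) {
    stop(sprintf("output path `%s` does not exist", dirname(out_dir)),
         call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic study end to end
#'
#' Simulate -> preprocess -> behavior metrics -> decode (per-level, combined,
#' optionally all 45 pairwise models) -> summary. Deterministic given the
#' configuration seed.
#'
#' @param rc a [run_config()].
#' @return list of class `pipeline_result` with `per_level`, `combined`,
#'   optional `dissimilarity` + `within_adjacent`, `behavior` (error and
#'   reversal rates), `qc`, and a `summary` list (per-level accuracies, their
#'   mean, combined accuracy, the separate-vs-combined gap, config echo).
#'   With `out_dir` set, writes TSV tables and a JSON summary.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  preset <- study_presets(rc$snr, n_channels = rc$config$n_channels,
                          n_wml_levels = rc$config$n_wml_levels,
                          interaction_strength = rc$interaction_strength)
  sim <- simulate_experiment(rc$config, act = preset$act,
                             noise = preset$noise, seed = rc$seed,
                             n_bad_channels = rc$n_bad_channels)
  prep <- preprocess_recording(sim$raw, sim$layout, sim$design$labels,
                               behavior = sim$behavior,
                               cv_threshold = rc$cv_threshold,
                               cutoff = rc$cutoff, tolerance = rc$tolerance,
                               criterion = rc$criterion)
  scores <- attr(prep$labels, "segment_scores")
  behav <- list(error_rate = error_rate(scores),
                reversal_rate = reversal_rate_by_cell(sim$behavior))
  dec_args <- list(hemo = prep$hemo, labels = prep$labels,
                   k_outer = rc$k_outer, k_inner = rc$k_inner,
                   lambda_grid = rc$lambda_grid,
                   eigen_threshold = rc$eigen_threshold,
                   drop_first = rc$drop_first)
  per_level <- do.call(nested_cv_decode, c(dec_args, mode = "per_level"))
  combined <- do.call(nested_cv_decode, c(dec_args, mode = "combined"))
  out <- list(per_level = per_level, combined = combined,
              behavior = behav, qc = prep$qc, sim = sim, prep = prep,
              config = rc)
  if (rc$run_pairwise) {
    out$dissimilarity <- pairwise_dissimilarity(
      prep$hemo, prep$labels, k_outer = rc$k_outer, k_inner = rc$k_inner,
      lambda_grid = rc$lambda_grid, eigen_threshold = rc$eigen_threshold,
      drop_first = rc$drop_first)
    out$within_adjacent <- within_adjacent_summary(out$dissimilarity)
  }
  per_acc <- vapply(per_level, function(r) r$accuracy, numeric(1))
  out$summary <- list(
    seed = rc$seed, interaction_strength = rc$interaction_strength,
    snr = rc$snr,
    per_level_accuracy = per_acc,
    per_level_accuracy_mean = mean(per_acc),
    per_level_f1 = vapply(per_level, function(r) r$f1, numeric(1)),
    combined_accuracy = combined$accuracy,
    combined_f1 = combined$f1,
    separate_minus_combined = mean(per_acc) - combined$accuracy,
    n_channels_retained = attr(prep$qc, "n_retained"),
    fraction_segments_excluded = mean(!scores$passed),
    within_mean = out$within_adjacent$within_mean %||% NA_real_,
    adjacent_mean = out$within_adjacent$adjacent_mean %||% NA_real_
  )
  class(out) <- "pipeline_result"
  if (!is.null(rc$out_dir)) write_pipeline_result(out, rc$out_dir)
  out
}

# TSV/JSON writers for a pipeline result (provenance: seed + parameters in
# the JSON summary).
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  acc_tab <- data.frame(model = names(res$summary$per_level_accuracy),
                        accuracy_pct = res$summary$per_level_accuracy,
                        f1 = res$summary$per_level_f1)
  acc_tab <- rbind(acc_tab, data.frame(model = "combined",
                                       accuracy_pct = res$summary$combined_accuracy,
                                       f1 = res$summary$combined_f1))
  wt(acc_tab, "decoding_accuracy.tsv")
  wt(res$behavior$error_rate, "error_rate.tsv")
  wt(res$behavior$reversal_rate, "reversal_rate.tsv")
  wt(as.data.frame(res$qc), "qc_report.tsv")
  if (!is.null(res$dissimilarity)) {
    m <- res$dissimilarity
    wt(cbind(condition = rownames(m), as.data.frame(unclass(m))),
       "dissimilarity_matrix.tsv")
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Pipeline result (seed %d, interaction %.2f, %s SNR)\n",
              s$seed, s$interaction_strength, s$snr))
  cat(sprintf("  per-level accuracy: %s (mean %.1f%%)\n",
              paste(sprintf("%.1f", s$per_level_accuracy), collapse = ", "),
              s$per_level_accuracy_mean))
  cat(sprintf("  combined accuracy: %.1f%% (gap %.1f points)\n",
              s$combined_accuracy, s$separate_minus_combined))
  invisible(x)
}

#' Simulate and analyze a cohort of participants
#'
#' Loops single-participant simulations over seeds (one simulated participant
#' per seed), decodes per level, computes per-level univariate predictivity
#' maps, and aggregates them into the accuracy-weighted group map per level.
#'
#' @param n_participants cohort size.
#' @param base_seed participant `i` uses seed `base_seed + i`.
#' @param config an [experiment_config()].
#' @param snr,interaction_strength preset parameters.
#' @param k_outer,k_inner,lambda_grid decoding parameters.
#' @param n_bad_channels corrupted channels per participant.
#' @param ... further arguments passed to [study_presets()] (e.g.
#'   `difficulty_scale_by_level`).
#' @return list of class `cohort_result`: `participants` (per-participant
#'   accuracies and maps), `group_maps` (levels x channels), `weights_used`.
#' @export
simulate_cohort <- function(n_participants = 6L, base_seed = 100L,
                            config = experiment_config(),
                            snr = "high", interaction_strength = 0,
                            k_outer = 5L, k_inner = 5L,
                            lambda_grid = lambda_grid_default(),
                            n_bad_channels = 0L, ...) {
  preset_args <- list(snr = snr, n_channels = config$n_channels,
                      n_wml_levels = config$n_wml_levels,
                      interaction_strength = interaction_strength, ...)
  participants <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    preset <- do.call(study_presets, preset_args)
    sim <- simulate_experiment(config, act = preset$act, noise = preset$noise,
                               seed = base_seed + i,
                               n_bad_channels = n_bad_channels)
    prep <- preprocess_recording(sim$raw, sim$layout, sim$design$labels,
                                 behavior = sim$behavior)
    per_level <- nested_cv_decode(prep$hemo, prep$labels, mode = "per_level",
                                  k_outer = k_outer, k_inner = k_inner,
                                  lambda_grid = lambda_grid)
    r2 <- predictivity_map(prep$hemo, prep$labels)
    participants[[i]] <- list(
      seed = base_seed + i,
      accuracy = vapply(per_level, function(r) r$accuracy, numeric(1)),
      r2 = r2,
      truth = sim$truth$ground_truth)
  }
  n_lev <- config$n_wml_levels
  n_ch <- config$n_channels
  group_maps <- matrix(NA_real_, n_lev, n_ch,
                       dimnames = list(sprintf("level_%d", seq_len(n_lev) - 1L),
                                       NULL))
  for (li in seq_len(n_lev)) {
    r2_mat <- do.call(rbind, lapply(participants, function(p) p$r2[li, ]))
    w <- vapply(participants, function(p) p$accuracy[li], numeric(1))
    group_maps[li, ] <- weighted_group_map(r2_mat, w)
  }
  structure(list(participants = participants, group_maps = group_maps,
                 config = config,
                 interaction_strength = interaction_strength),
            class = "cohort_result")
}

#' Read the published group-level result tables
#'
#' Returns the per-cell values of the study's result tables shipped with the
#' package (steering reversal rates, speed-error rates, per-participant F1
#' scores of the separate models, combined-model accuracy/F1, and the
#' within/adjacent dissimilarity entries), used as worked-example inputs.
#'
#' @return named list of data.frames.
#' @export
published_tables <- function() {
  dir <- system.file("extdata", "published", package = "nirsdecode")
  read1 <- function(f) read.delim(file.path(dir, f), check.names = FALSE)
  list(
    steering = read1("steering_reversal_rate_hz.tsv"),
    error_rate = read1("speed_error_rate.tsv"),
    separate_f1 = read1("separate_model_f1.tsv"),
    combined = read1("combined_model.tsv"),
    within_adjacent = read1("within_adjacent_accuracy.tsv")
  )
}

#' Grand means of the published decoding tables
#'
#' Recomputes, from the shipped per-cell values, the headline summary
#' numbers: the grand mean F1 of the separate (per-level) models, the mean
#' accuracy and F1 of the combined model, and the mean within-level and
#' adjacent-level difficulty decoding accuracies.
#'
#' @return named list of scalars.
#' @export
published_grand_means <- function() {
  tb <- published_tables()
  f1_cells <- as.matrix(tb$separate_f1[, -1])
  wa <- tb$within_adjacent
  list(
    separate_f1_grand_mean = mean(f1_cells),
    separate_f1_level_means = colMeans(f1_cells),
    combined_accuracy_mean = mean(tb$combined$accuracy_pct),
    combined_f1_mean = mean(tb$combined$f1),
    within_mean = mean(wa$accuracy[wa$pair_type == "within"]),
    adjacent_mean = mean(wa$accuracy[wa$pair_type == "adjacent"]),
    steering_mean_construction =
      mean(as.numeric(tb$steering[tb$steering$difficulty == "construction", -1])),
    steering_mean_non_construction =
      mean(as.numeric(tb$steering[tb$steering$difficulty == "non_construction", -1])),
    error_rate_mean_construction =
      mean(as.numeric(tb$error_rate[tb$error_rate$difficulty == "construction", -1])),
    error_rate_mean_non_construction =
      mean(as.numeric(tb$error_rate[tb$error_rate$difficulty == "non_construction", -1]))
  )
}
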