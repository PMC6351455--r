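#' Experiment configuration for the simulated driving session
#'
#' Describes the dual-task session: an n-back speed-regulation task (working
#' memory load, WML) crossed with driving difficulty (construction vs.
#' non-construction road sections) in a block design. Defaults reproduce the
#' study conditions: 78 fNIRS channels sampled at 1.955 Hz, five WML levels
#' (0-back to 4-back), 3-minute blocks, each (level, difficulty) cell driven
#' twice, speed signs roughly every 20 s, behavior recorded at 50 Hz.
#'
#' @param n_channels number of fNIRS channels.
#' @param fs_nirs fNIRS sampling rate in Hz.
#' @param fs_behavior behavioral (speed/steering) sampling rate in Hz.
#' @param n_wml_levels number of n-back levels (levels are `0:(n_wml_levels-1)`).
#' @param block_duration duration of one condition block in seconds.
#' @param reps_per_cell repetitions of each (level, difficulty) cell. Must be
#'   even: the session mirrors its first half after the midpoint break, so each
#'   cell is driven once per session half per `reps_per_cell / 2`.
#' @param sign_interval_mean mean spacing of speed signs in seconds.
#' @param sign_jitter_frac jitter of the sign spacing as a fraction of
#'   `sign_interval_mean`; spacings are uniform on mean * (1 +/- frac).
#' @param seed default seed used by generators when none is supplied.
#'
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_channels = 78L,
                              fs_nirs = 1.955,
                              fs_behavior = 50,
                              n_wml_levels = 5L,
                              block_duration = 180,
                              reps_per_cell = 2L,
                              sign_interval_mean = 20,
                              sign_jitter_frac = 0.25,
                              seed = 1L) {
  stop_if_not_scalar_pos(n_channels, "n_channels")
  stop_if_not_scalar_pos(fs_nirs, "fs_nirs")
  stop_if_not_scalar_pos(fs_behavior, "fs_behavior")
  stop_if_not_scalar_pos(block_duration, "block_duration")
  stop_if_not_scalar_pos(sign_interval_mean, "sign_interval_mean")
  if (!is.numeric(n_wml_levels) || n_wml_levels < 1) {
    stop("`n_wml_levels` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(reps_per_cell) || reps_per_cell < 1) {
    stop("`reps_per_cell` must be >= 1", call. = FALSE)
  }
  if (as.integer(reps_per_cell) %% 2L != 0L) {
    stop("`reps_per_cell` must be even: the session mirrors its first half ",
         "after the midpoint break", call. = FALSE)
  }
  if (sign_jitter_frac < 0 || sign_jitter_frac >= 1) {
    stop("`sign_jitter_frac` must be in [0, 1)", call. = FALSE)
  }
  cfg <- list(
    n_channels = as.integer(n_channels),
    fs_nirs = fs_nirs,
    fs_behavior = fs_behavior,
    n_wml_levels = as.integer(n_wml_levels),
    block_duration = block_duration,
    reps_per_cell = as.integer(reps_per_cell),
    sign_interval_mean = sign_interval_mean,
    sign_jitter_frac = sign_jitter_frac,
    seed = as.integer(seed)
  )
  cfg$n_blocks <- cfg$n_wml_levels * 2L * cfg$reps_per_cell
  cfg$total_duration <- cfg$n_blocks * cfg$block_duration
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment configuration\n")
  cat(sprintf("  %d channels @ %.3f Hz, behavior @ %g Hz\n",
              x$n_channels, x$fs_nirs, x$fs_behavior))
  cat(sprintf("  %d WML levels x 2 difficulties x %d reps, %g s blocks (%g s total)\n",
              x$n_wml_levels, x$reps_per_cell, x$block_duration,
              x$total_duration))
  invisible(x)
}
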