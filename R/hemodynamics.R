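#' Canonical double-gamma hemodynamic response function
#'
#' Standard two-gamma HRF (response peak minus a weighted undershoot), sampled
#' at `fs` and normalized so that the steady-state response to a sustained
#' unit boxcar equals 1. The normalization makes activation amplitudes read
#' directly as sustained concentration changes (mmol/L).
#'
#' @param fs sampling rate (Hz).
#' @param peak time-to-peak parameter (gamma shape, s).
#' @param undershoot undershoot time parameter (gamma shape, s).
#' @param ratio undershoot-to-peak amplitude ratio.
#' @param duration kernel length in seconds.
#' @return numeric kernel vector.
#' @export
hrf_double_gamma <- function(fs, peak = 6, undershoot = 16, ratio = 1 / 6,
                             duration = 32) {
  t <- seq(0, duration, by = 1 / fs)
  h <- dgamma(t, shape = peak, rate = 1) -
    ratio * dgamma(t, shape = undershoot, rate = 1)
  h / sum(h)
}

#' Activation specification: condition-dependent hemodynamic patterns
#'
#' Defines the per-channel response amplitudes of the two task factors. The
#' WML factor drives a fixed spatial pattern scaled linearly with n-back
#' level. The driving-difficulty (construction) factor drives a spatial
#' pattern that may change with WML level: `interaction_strength` mixes a
#' level-independent base pattern (`strength = 0`) with level-specific
#' patterns (`strength = 1`). The level-specific patterns are the vertices of
#' a regular simplex over disjoint channel groups: equal norms, pairwise
#' correlation -1/(n_levels - 1), and exact zero sum — so at full interaction
#' strength no single linear readout separates difficulty across all levels
#' simultaneously, while each level remains separable on its own.
#'
#' @param n_channels number of channels (must match the design).
#' @param n_wml_levels number of WML levels.
#' @param wml_amp sustained HbO amplitude (mmol/L) per n-back level step.
#' @param difficulty_amp sustained HbO amplitude (mmol/L) of the construction
#'   effect (norm of the pattern vector at scale 1).
#' @param interaction_strength mixing factor in `[0, 1]`.
#' @param difficulty_scale_by_level per-level multiplier of the difficulty
#'   pattern (default: 1 at every level). An inverted-U profile such as
#'   `c(0.7, 1, 0.9, 0.6, 0.35)` emulates discriminability peaking at
#'   intermediate WML levels and diminishing at high load.
#' @param hrf_peak,hrf_undershoot,hrf_ratio double-gamma HRF parameters.
#' @param hbr_to_hbo_ratio negative scalar coupling HbR to HbO.
#' @return An object of class `activation_spec` with the pattern matrices
#'   (`wml_pattern`: length `n_channels`; `difficulty_patterns`:
#'   `n_wml_levels x n_channels`, already mixed and scaled).
#' @export
activation_spec <- function(n_channels = 78L,
                            n_wml_levels = 5L,
                            wml_amp = 1e-4,
                            difficulty_amp = 1e-4,
                            interaction_strength = 0,
                            difficulty_scale_by_level = NULL,
                            hrf_peak = 6, hrf_undershoot = 16,
                            hrf_ratio = 1 / 6,
                            hbr_to_hbo_ratio = -1 / 3) {
  stopifnot(n_channels >= 2 * n_wml_levels,
            interaction_strength >= 0, interaction_strength <= 1,
            hbr_to_hbo_ratio < 0)
  if (is.null(difficulty_scale_by_level)) {
    difficulty_scale_by_level <- rep(1, n_wml_levels)
  }
  stopifnot(length(difficulty_scale_by_level) == n_wml_levels,
            all(difficulty_scale_by_level >= 0))

  # WML pattern on the first quarter of channels ("frontal"), unit norm
  wml_idx <- seq_len(max(2L, floor(n_channels / 4)))
  wml_pattern <- numeric(n_channels)
  wml_pattern[wml_idx] <- 1
  wml_pattern <- wml_pattern / sqrt(sum(wml_pattern^2))

  # difficulty channels: the remaining channels, split into one group per
  # level; base pattern = uniform over all difficulty channels
  diff_idx <- setdiff(seq_len(n_channels), wml_idx)
  base <- numeric(n_channels)
  base[diff_idx] <- 1
  base <- base / sqrt(sum(base^2))

  grp <- pmin(ceiling(seq_along(diff_idx) / (length(diff_idx) / n_wml_levels)),
              n_wml_levels)
  groups <- split(diff_idx, grp)
  basis <- vapply(groups, function(g) {
    v <- numeric(n_channels)
    v[g] <- 1
    v / sqrt(sum(v^2))
  }, numeric(n_channels))                       # n_channels x n_levels
  # simplex coefficients: rows of I - J/L sum to zero, equal norms; with a
  # single level there is no between-level contrast to encode
  if (n_wml_levels == 1L) {
    simplex <- matrix(0, 1L, n_channels)
  } else {
    C <- diag(n_wml_levels) - 1 / n_wml_levels
    C <- C / sqrt(sum(C[1, ]^2))
    simplex <- C %*% t(basis)                   # n_levels x n_channels
  }

  s <- interaction_strength
  mixed <- (1 - s) * matrix(base, n_wml_levels, n_channels, byrow = TRUE) +
    s * simplex
  patterns <- mixed * difficulty_scale_by_level * difficulty_amp

  structure(list(
    n_channels = as.integer(n_channels),
    n_wml_levels = as.integer(n_wml_levels),
    wml_amp = wml_amp,
    difficulty_amp = difficulty_amp,
    interaction_strength = s,
    difficulty_scale_by_level = difficulty_scale_by_level,
    wml_pattern = wml_pattern,
    difficulty_patterns = patterns,
    hrf_peak = hrf_peak, hrf_undershoot = hrf_undershoot,
    hrf_ratio = hrf_ratio,
    hbr_to_hbo_ratio = hbr_to_hbo_ratio
  ), class = "activation_spec")
}

# causal convolution of a regressor with a kernel, truncated to length(u)
convolve_regressor <- function(u, h) {
  convolve(u, rev(h), type = "open")[seq_along(u)]
}

#' Generate ground-truth hemodynamics from a session design
#'
#' Convolves the condition boxcars with the double-gamma HRF: the WML
#' regressor (amplitude = n-back level x `wml_amp` x WML pattern) plus one
#' difficulty regressor per level (construction blocks only, level-indexed
#' pattern). HbR is coupled to HbO by `hbr_to_hbo_ratio`. Noise-free; see
#' [add_noise()].
#'
#' @param design a [generate_design()] result.
#' @param act an [activation_spec()].
#' @return An object of class `hemo_series`: `time`, `fs`, `hbo` and `hbr`
#'   (time x channel matrices, mmol/L), `channel_mask`, and a `ground_truth`
#'   list (effective difficulty patterns per level, WML pattern).
#' @export
generate_hemodynamics <- function(design, act) {
  stopifnot(inherits(design, "nirs_design"), inherits(act, "activation_spec"))
  cfg <- design$config
  if (act$n_channels != cfg$n_channels) {
    stop("activation_spec channel count does not match the design",
         call. = FALSE)
  }
  if (act$n_wml_levels != cfg$n_wml_levels) {
    stop("activation_spec WML level count does not match the design",
         call. = FALSE)
  }
  lab <- design$labels
  n <- nrow(lab)
  h <- hrf_double_gamma(cfg$fs_nirs, act$hrf_peak, act$hrf_undershoot,
                        act$hrf_ratio)

  wml_reg <- convolve_regressor(as.numeric(lab$wml_level), h)
  hbo <- (act$wml_amp * wml_reg) %o% act$wml_pattern
  for (lev in seq_len(cfg$n_wml_levels) - 1L) {
    u <- as.numeric(lab$wml_level == lev & lab$difficulty == "construction")
    if (!any(u > 0)) next
    reg <- convolve_regressor(u, h)
    hbo <- hbo + reg %o% act$difficulty_patterns[lev + 1L, ]
  }
  hbr <- act$hbr_to_hbo_ratio * hbo

  structure(list(
    time = lab$time, fs = cfg$fs_nirs,
    hbo = hbo, hbr = hbr,
    channel_mask = rep(TRUE, cfg$n_channels),
    ground_truth = list(
      wml_pattern = act$wml_amp * act$wml_pattern,
      difficulty_patterns = act$difficulty_patterns
    )
  ), class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("Hemoglobin series: %d samples x %d channels @ %.3f Hz (%d unmasked)\n",
              nrow(x$hbr), ncol(x$hbr), x$fs, sum(x$channel_mask)))
  invisible(x)
}
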