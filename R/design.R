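#' Generate the block design and speed-sign schedule of a session
#'
#' Builds the pseudorandomized block sequence of the dual-task session: every
#' (WML level, difficulty) cell appears `reps_per_cell` times, driving
#' difficulty alternates with every change of n-back level, no level is driven
#' twice in a row within a session half, and the sequence of the first half is
#' repeated in reversed order after the midpoint break (so levels and
#' difficulties are palindromic around the break; the level of the last
#' pre-break block necessarily recurs directly after the break). Speed signs
#' are placed along the whole session roughly every `sign_interval_mean`
#' seconds with uniform jitter; consecutive posted speeds always differ.
#'
#' @param config an [experiment_config()].
#' @param seed integer seed; defaults to `config$seed`.
#'
#' @return An object of class `nirs_design`: a list with
#'   * `blocks`: one row per block (`block`, `wml_level`, `difficulty`,
#'     `t_start`, `t_end`, `after_break`),
#'   * `signs`: speed-sign events (`time`, `speed_kmh`),
#'   * `labels`: per-sample label track at `fs_nirs` (`time`, `block`,
#'     `wml_level`, `difficulty`, `segment`, `valid`),
#'   * `config`.
#' @export
generate_design <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  with_seed(derive_seed(seed, 1L), {
    half_levels <- sample_half_level_sequence(config$n_wml_levels,
                                              config$reps_per_cell)
    n_half <- length(half_levels)
    # difficulty alternates with every level change (= every block within a
    # half); starting difficulty is randomized, second half mirrors the first
    start_c <- sample(c(TRUE, FALSE), 1L)
    half_diff <- rep_len(if (start_c) c("construction", "non_construction")
                         else c("non_construction", "construction"), n_half)
    levels_all <- c(half_levels, rev(half_levels))
    diff_all <- c(half_diff, rev(half_diff))

    blocks <- data.frame(
      block = seq_len(config$n_blocks),
      wml_level = levels_all,
      difficulty = diff_all,
      t_start = (seq_len(config$n_blocks) - 1) * config$block_duration,
      t_end = seq_len(config$n_blocks) * config$block_duration,
      after_break = seq_len(config$n_blocks) > n_half,
      stringsAsFactors = FALSE
    )

    signs <- place_speed_signs(config$total_duration,
                               config$sign_interval_mean,
                               config$sign_jitter_frac)

    n_samp <- floor(config$total_duration * config$fs_nirs)
    time <- (seq_len(n_samp) - 1) / config$fs_nirs
    block_idx <- pmin(floor(time / config$block_duration) + 1, config$n_blocks)
    segment <- findInterval(time, signs$time)
    labels <- data.frame(
      time = time,
      block = block_idx,
      wml_level = blocks$wml_level[block_idx],
      difficulty = blocks$difficulty[block_idx],
      segment = segment,
      valid = TRUE,
      stringsAsFactors = FALSE
    )

    structure(list(blocks = blocks, signs = signs, labels = labels,
                   config = config),
              class = "nirs_design")
  })
}

# First-half level sequence: each level `reps` times, no immediate repetition,
# and each level split evenly between odd and even positions so that the
# alternating difficulty assignment is exactly balanced per level once the
# half is mirrored. Rejection sampling; the constraint set is feasible for
# every even `reps` and n_levels >= 2.
sample_half_level_sequence <- function(n_levels, reps, max_tries = 50000L) {
  levels <- seq_len(n_levels) - 1L
  pool <- rep(levels, each = reps)
  if (n_levels == 1L) return(pool)
  n <- length(pool)
  odd <- seq(1L, n, by = 2L)
  for (i in seq_len(max_tries)) {
    cand <- sample(pool)
    if (any(cand[-1] == cand[-n])) next
    tab <- tabulate(cand[odd] + 1L, nbins = n_levels)
    if (all(tab == reps / 2)) return(cand)
  }
  stop("could not satisfy the block-sequence constraints; ",
       "check n_wml_levels and reps_per_cell", call. = FALSE)
}

# Posted speeds walk the 60..140 km/h grid in +/-20 steps (reflecting at the
# ends) so consecutive signs always differ and speed steps stay drivable.
place_speed_signs <- function(total_duration, interval_mean, jitter_frac) {
  lo <- interval_mean * (1 - jitter_frac)
  hi <- interval_mean * (1 + jitter_frac)
  times <- 0
  while (tail(times, 1L) < total_duration) {
    times <- c(times, tail(times, 1L) + runif(1L, lo, hi))
  }
  # no sign in the final stretch: a trailing stub segment shorter than the
  # driver's adaptation time would be unscorable
  times <- times[times < total_duration - interval_mean]
  grid <- seq(60, 140, by = 20)
  speeds <- numeric(length(times))
  speeds[1] <- sample(grid, 1L)
  for (k in seq_along(times)[-1]) {
    prev <- speeds[k - 1]
    step <- if (prev <= min(grid)) 20 else if (prev >= max(grid)) -20 else
      sample(c(-20, 20), 1L)
    speeds[k] <- prev + step
  }
  data.frame(time = times, speed_kmh = speeds)
}

#' @export
print.nirs_design <- function(x, ...) {
  cat(sprintf("Session design: %d blocks (%d levels x 2 difficulties x %d reps), %d speed signs\n",
              nrow(x$blocks), x$config$n_wml_levels, x$config$reps_per_cell,
              nrow(x$signs)))
  invisible(x)
}
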