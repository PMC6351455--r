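#' Behavioral generator specification
#'
#' Parameters of the simulated driver. Per-cell miss probabilities and
#' steering reversal rates default to the group-level rates observed in the
#' study (speed-error rates and steering reversal rates per WML level and
#' difficulty); both are `n_wml_levels x 2` matrices with columns
#' `construction`, `non_construction`.
#'
#' @param n_wml_levels number of WML levels.
#' @param speed_lag first-order tracking time constant of the driver (s).
#' @param speed_noise_sd additive speed noise (km/h).
#' @param miss_probability per-cell probability that a segment's target is
#'   missed (matrix, or a single number recycled).
#' @param reversal_rate per-cell steering reversal rate target (Hz; matrix or
#'   single number).
#' @param steering_noise_sd variability of the steering-angle magnitude
#'   (degrees).
#' @param miss_offset speed offset applied in missed segments (km/h); must
#'   exceed the scoring tolerance.
#' @return An object of class `behavior_spec`.
#' @export
behavior_spec <- function(n_wml_levels = 5L,
                          speed_lag = 0.8,
                          speed_noise_sd = 1,
                          miss_probability = NULL,
                          reversal_rate = NULL,
                          steering_noise_sd = 2,
                          miss_offset = 15) {
  cell_matrix <- function(x, default5, default_flat) {
    if (is.null(x)) {
      x <- if (n_wml_levels == 5L) default5 else
        matrix(default_flat, n_wml_levels, 2L)
    }
    if (length(x) == 1L) x <- matrix(x, n_wml_levels, 2L)
    stopifnot(is.matrix(x), nrow(x) == n_wml_levels, ncol(x) == 2L)
    colnames(x) <- c("construction", "non_construction")
    x
  }
  # study group-level rates per (level, difficulty)
  miss5 <- cbind(c(0.01, 0.05, 0.07, 0.21, 0.17),
                 c(0.01, 0.02, 0.13, 0.05, 0.08))
  rev5 <- cbind(c(0.012, 0.012, 0.017, 0.013, 0.018),
                c(0.011, 0.008, 0.012, 0.009, 0.010))
  miss_probability <- cell_matrix(miss_probability, miss5, 0.08)
  reversal_rate <- cell_matrix(reversal_rate, rev5, c(0.014, 0.010))
  stopifnot(all(miss_probability >= 0), all(miss_probability <= 1),
            all(reversal_rate >= 0), speed_lag > 0, miss_offset > 0)
  structure(list(n_wml_levels = as.integer(n_wml_levels),
                 speed_lag = speed_lag, speed_noise_sd = speed_noise_sd,
                 miss_probability = miss_probability,
                 reversal_rate = reversal_rate,
                 steering_noise_sd = steering_noise_sd,
                 miss_offset = miss_offset),
            class = "behavior_spec")
}

#' Simulate driving behavior for a session design
#'
#' Generates the 50 Hz speed and steering tracks. The driver follows the
#' n-back target speed with a first-order lag; new n-back rules take effect
#' at the first sign passed after a block change, so the scored target is
#' constant within every sign-to-sign segment. In a "missed" segment (drawn
#' per segment with the cell's miss probability) the driver holds a speed
#' offset from the target larger than the scoring tolerance. Steering is a
#' telegraph-sign process whose zero crossings occur at Poisson times with
#' the cell's configured reversal rate, carried by a strictly positive
#' magnitude so the realized crossing count equals the event count.
#'
#' @param design a [generate_design()] result.
#' @param spec a [behavior_spec()].
#' @param seed integer seed.
#' @return A data.frame of class `behavior_track`: `time`, `speed`,
#'   `steering`, `target`, `segment`, `block`, `wml_level`, `difficulty`;
#'   attributes `fs` and `missed_segments`.
#' @export
generate_behavior <- function(design, spec, seed = design$config$seed) {
  stopifnot(inherits(design, "nirs_design"), inherits(spec, "behavior_spec"))
  cfg <- design$config
  if (spec$n_wml_levels != cfg$n_wml_levels) {
    stop("behavior_spec level count does not match the design", call. = FALSE)
  }
  signs <- design$signs
  if (nrow(signs) == 0L) stop("empty sign list", call. = FALSE)
  n <- floor(cfg$total_duration * cfg$fs_behavior)
  time <- (seq_len(n) - 1) / cfg$fs_behavior
  block <- pmin(floor(time / cfg$block_duration) + 1, cfg$n_blocks)
  lev <- design$blocks$wml_level[block]
  diff <- design$blocks$difficulty[block]
  segment <- findInterval(time, signs$time)

  # per-segment target: n-back rule of the block active at the segment's sign
  k <- seq_len(nrow(signs))
  sign_block <- pmin(floor(signs$time / cfg$block_duration) + 1, cfg$n_blocks)
  n_at_sign <- design$blocks$wml_level[sign_block]
  seg_target <- signs$speed_kmh[pmax(k - n_at_sign, 1L)]
  target <- seg_target[segment]

  with_seed(derive_seed(seed, 4L), {
    # segment misses drawn from the cell of the segment's first sample
    seg_first <- match(k, segment)
    seg_lev <- lev[seg_first]
    seg_diff <- diff[seg_first]
    p_miss <- spec$miss_probability[cbind(seg_lev + 1L,
                                          ifelse(seg_diff == "construction",
                                                 1L, 2L))]
    missed <- runif(length(k)) < p_miss
    eff_target <- seg_target +
      ifelse(missed, sample(c(-1, 1), length(k), replace = TRUE) *
               spec$miss_offset, 0)

    # first-order lag toward the effective target
    tgt <- eff_target[segment]
    alpha <- 1 / (spec$speed_lag * cfg$fs_behavior)
    speed <- numeric(n)
    speed[1] <- tgt[1]
    for (i in 2:n) speed[i] <- speed[i - 1] + alpha * (tgt[i] - speed[i - 1])
    if (spec$speed_noise_sd > 0) {
      speed <- speed + rnorm(n, sd = spec$speed_noise_sd)
    }
    speed <- pmax(speed, 0)

    # steering: telegraph process per block with the cell's reversal rate
    steering <- numeric(n)
    state <- 1
    for (b in seq_len(cfg$n_blocks)) {
      i <- which(block == b)
      rate <- spec$reversal_rate[design$blocks$wml_level[b] + 1L,
                                 ifelse(design$blocks$difficulty[b] ==
                                          "construction", 1L, 2L)]
      dur <- length(i) / cfg$fs_behavior
      n_flips <- rpois(1L, rate * dur)
      flips <- sort(runif(n_flips, 0, dur))
      s <- state * (-1)^findInterval(time[i] - time[i[1L]], flips)
      state <- s[length(s)]
      mag <- 3 + abs(rnorm(length(i), sd = spec$steering_noise_sd))
      steering[i] <- s * mag
    }

    out <- data.frame(time = time, speed = speed, steering = steering,
                      target = target, segment = segment, block = block,
                      wml_level = lev, difficulty = diff,
                      stringsAsFactors = FALSE)
    attr(out, "fs") <- cfg$fs_behavior
    attr(out, "missed_segments") <- which(missed)
    class(out) <- c("behavior_track", "data.frame")
    out
  })
}
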