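test_that("n-back target speed follows the sign passed n signs before", {
  signs <- data.frame(time = c(0, 20, 40, 60, 80),
                      speed_kmh = c(100, 140, 80, 120, 60))
  t <- c(5, 25, 45, 65, 85)
  # 0-back: the most recently passed sign
  expect_equal(target_speed_track(signs, 0, t), c(100, 140, 80, 120, 60))
  # 1-back: passing the 80 km/h sign, the target is the previous sign (140)
  expect_equal(target_speed_track(signs, 1, 45), 140)
  # before n signs have been passed the target stays at the first sign
  expect_equal(target_speed_track(signs, 4, c(5, 25, 45, 65)),
               rep(100, 4))
  expect_equal(target_speed_track(signs, 4, 85), 100)  # sign 5 - 4 = 1
  expect_error(target_speed_track(signs[0, ], 1, 5), "empty")
})

test_that("segment scoring applies the +/-5 km/h tolerance and the 90% criterion", {
  fs <- 50
  mk_track <- function(frac_in) {
    n <- 100L
    dev <- rep(3, n)                       # in tolerance
    dev[seq_len(round((1 - frac_in) * n))] <- 10  # out of tolerance
    data.frame(time = (seq_len(n) - 1) / fs, speed = 100 + dev,
               target = 100, segment = 1L)
  }
  expect_true(score_segments(mk_track(1))$passed)        # |dev| = 3 everywhere
  expect_true(score_segments(mk_track(0.90))$passed)     # boundary inclusive
  expect_false(score_segments(mk_track(0.89))$passed)    # < 90% fails
  expect_equal(score_segments(mk_track(0.85))$fraction, 0.85)
})

test_that("error rate is the fraction of failed segments per condition cell", {
  scores <- data.frame(segment = 1:10, fraction = c(rep(1, 9), 0.5),
                       wml_level = rep(c(0, 1), each = 5),
                       difficulty = "construction",
                       passed = c(rep(TRUE, 9), FALSE))
  class(scores) <- c("segment_scores", "data.frame")
  er <- error_rate(scores)
  expect_equal(er$error_rate[er$wml_level == 0], 0)
  expect_equal(er$error_rate[er$wml_level == 1], 0.2)   # 1 of 5 failed
})

test_that("steering reversal rate closed forms and brute-force agreement", {
  fs <- 50
  expect_equal(steering_reversal_rate(rep(4, 500), fs), 0)
  # 0.5 Hz sinusoid over 60 s crosses zero at 2f per second -> 1.0 Hz
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.5 * t + 0.3)
  expect_equal(steering_reversal_rate(x, fs), 1.0, tolerance = 0.02)
  # brute-force oracle: sign changes between successive samples
  set.seed(4)
  y <- rnorm(2000)
  brute <- sum(sign(y)[-1] != sign(y)[-2000]) / (2000 / fs)
  expect_equal(steering_reversal_rate(y, fs), brute)
  # zeros are treated as continuations, not crossings
  z <- c(1, 0, 1, -1, 0, -1, 1)
  expect_equal(steering_reversal_rate(z, 1), 2 / 7)
})

test_that("generated behavior honors configured miss and reversal parameters", {
  cfg <- experiment_config(n_channels = 4L, block_duration = 90, seed = 21)
  d <- generate_design(cfg, seed = 21)
  # no misses, no noise -> every segment passes
  b0 <- generate_behavior(d, behavior_spec(miss_probability = 0,
                                           speed_noise_sd = 0), seed = 21)
  expect_true(all(score_segments(b0)$passed))
  # all misses -> every segment fails
  b1 <- generate_behavior(d, behavior_spec(miss_probability = 1,
                                           speed_noise_sd = 0), seed = 21)
  expect_true(all(!score_segments(b1)$passed))
  lab1 <- exclude_invalid_segments(d$labels, b1)
  expect_true(all(!lab1$valid))
  # configured reversal rate recovered within 3 standard errors (0.014 Hz,
  # 30-min session)
  cfg2 <- experiment_config(n_channels = 4L, block_duration = 90, seed = 22)
  d2 <- generate_design(cfg2, seed = 22)
  b2 <- generate_behavior(d2, behavior_spec(reversal_rate = 0.014), seed = 22)
  rate <- steering_reversal_rate(b2$steering, attr(b2, "fs"))
  dur <- nrow(b2) / attr(b2, "fs")
  se <- sqrt(0.014 / dur)
  expect_lt(abs(rate - 0.014), 3 * se)
})

test_that("behavior generation is deterministic and error rate is resampling-invariant", {
  cfg <- experiment_config(n_channels = 4L, block_duration = 90, seed = 30)
  d <- generate_design(cfg, seed = 30)
  sp <- behavior_spec()
  b1 <- generate_behavior(d, sp, seed = 5)
  b2 <- generate_behavior(d, sp, seed = 5)
  expect_identical(b1$speed, b2$speed)
  expect_identical(b1$steering, b2$steering)
  # noiseless track scored at half the sampling rate gives identical rates
  b0 <- generate_behavior(d, behavior_spec(miss_probability = 0.3,
                                           speed_noise_sd = 0), seed = 6)
  half <- b0[seq(1, nrow(b0), by = 2L), ]
  er_full <- error_rate(score_segments(b0))
  er_half <- error_rate(score_segments(half))
  expect_equal(er_full$error_rate, er_half$error_rate)
})
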