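test_that("channel CV follows the sd/mean definition and the 20% rule", {
  n <- 1000L
  set.seed(1)
  mk <- function(mean_, sd_) mean_ + sd_ * scale(rnorm(n))[, 1]
  raw <- structure(list(
    time = (seq_len(n) - 1) / 1.955, fs = 1.955,
    w760 = cbind(rep(5, n), mk(10, 1), mk(10, 2.5)),
    w850 = cbind(rep(5, n), mk(10, 1), mk(10, 1)),
    baseline = 1), class = "raw_intensity")
  qc <- channel_cv(raw)
  expect_equal(qc$cv_w760, c(0, 10, 25), tolerance = 1e-8)
  expect_equal(qc$excluded, c(FALSE, FALSE, TRUE))   # 25% > 20% -> excluded
  expect_equal(attr(qc, "n_retained"), 2L)
})

test_that("a channel failing at either wavelength is excluded; zero mean warns", {
  n <- 200L
  set.seed(2)
  noisy <- 10 + 3 * scale(rnorm(n))[, 1]       # CV 30%
  raw <- structure(list(
    time = seq_len(n), fs = 1,
    w760 = cbind(rep(10, n), rep(10, n)),
    w850 = cbind(noisy, rep(0, n)),
    baseline = 1), class = "raw_intensity")
  expect_warning(qc <- channel_cv(raw), "zero mean")
  expect_true(qc$excluded[1])   # fails only at 850 nm
  expect_true(qc$excluded[2])   # undefined CV
})

test_that("least-squares FIR low-pass matches its own computed frequency response", {
  fs <- 1.955
  h <- design_lowpass_fir(fs, cutoff = 0.1)
  # designed response: >= 20 dB attenuation at 0.5 Hz, <= 1 dB ripple at 0.02 Hz
  expect_lt(20 * log10(abs(fir_response(h, 0.5))), -20)
  expect_lt(abs(20 * log10(abs(fir_response(h, 0.02)))), 1)
  expect_equal(sum(h), 1)                        # exact unit DC gain
  # realized attenuation of a filtered sinusoid agrees with |H|^2 (zero-phase
  # application applies the filter twice)
  t <- (0:4000) / fs
  x05 <- sin(2 * pi * 0.5 * t)
  y05 <- lowpass(x05, fs)
  expect_lt(max(abs(y05[1000:3000])), abs(fir_response(h, 0.5))^2 * 2 + 1e-6)
  x002 <- sin(2 * pi * 0.02 * t)
  y002 <- lowpass(x002, fs)
  expect_equal(max(abs(y002[1000:3000])), abs(fir_response(h, 0.02))^2,
               tolerance = 0.02)
})

test_that("filtering is linear, preserves constants, and rejects bad cutoffs", {
  fs <- 1.955
  expect_equal(lowpass(rep(3.3, 300), fs), rep(3.3, 300), tolerance = 1e-9)
  set.seed(3)
  x <- rnorm(500); y <- rnorm(500)
  lhs <- lowpass(2 * x - 3 * y, fs)
  rhs <- 2 * lowpass(x, fs) - 3 * lowpass(y, fs)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(design_lowpass_fir(fs, cutoff = 1.0), "Nyquist")
})

test_that("behaviorally invalid segments mask the fNIRS samples", {
  s <- small_session()
  labels <- s$sim$design$labels
  out <- exclude_invalid_segments(labels, s$sim$behavior)
  scores <- attr(out, "segment_scores")
  bad <- scores$segment[!scores$passed]
  expect_true(all(!out$valid[out$segment %in% bad]))
  expect_true(all(out$valid[!(out$segment %in% bad)]))
  expect_warning(same <- exclude_invalid_segments(labels, NULL),
                 "no behavior")
  expect_true(all(same$valid))
})

test_that("miss probabilities near 8% exclude about 8% of segments over seeds", {
  fr <- vapply(1:6, function(sd) {
    cfg <- experiment_config(n_channels = 4L, block_duration = 90, seed = sd)
    d <- generate_design(cfg, seed = sd)
    b <- generate_behavior(d, behavior_spec(miss_probability = 0.08,
                                            speed_noise_sd = 0.5), seed = sd)
    sc <- score_segments(b)
    mean(!sc$passed)
  }, numeric(1))
  expect_gt(mean(fr), 0.05)
  expect_lt(mean(fr), 0.12)
})
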