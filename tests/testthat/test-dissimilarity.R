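test_that("within/adjacent summary reproduces the published means from Table values", {
  tb <- published_tables()$within_adjacent
  within <- tb$accuracy[tb$pair_type == "within"]
  adjacent <- tb$accuracy[tb$pair_type == "adjacent"]
  expect_equal(round(mean(within), 2), 0.75)            # printed within mean
  expect_equal(mean(within), 0.748, tolerance = 1e-12)
  expect_equal(round(mean(adjacent), 2), 0.58)          # printed adjacent mean
  expect_equal(mean(adjacent), 0.5775, tolerance = 1e-12)
})

test_that("within/adjacent summary enumerates the Table pair structure", {
  conds <- c(paste0(0:4, "c"), paste0(0:4, "nc"))
  m <- matrix(NA_real_, 10, 10, dimnames = list(conds, conds))
  within_vals <- c(0.68, 0.87, 0.85, 0.72, 0.62)
  adj_vals <- c(0.64, 0.63, 0.55, 0.49)
  for (l in 0:4) m[paste0(l, "c"), paste0(l, "nc")] <-
      m[paste0(l, "nc"), paste0(l, "c")] <- within_vals[l + 1]
  for (l in 0:3) m[paste0(l, "c"), paste0(l + 1, "nc")] <-
      m[paste0(l + 1, "nc"), paste0(l, "c")] <- adj_vals[l + 1]
  s <- within_adjacent_summary(m)
  expect_equal(s$within_mean, 0.748)
  expect_equal(s$adjacent_mean, 0.5775)
  # constant matrix: within mean equals adjacent mean
  m2 <- matrix(0.6, 10, 10, dimnames = list(conds, conds))
  s2 <- within_adjacent_summary(m2)
  expect_equal(s2$within_mean, s2$adjacent_mean)
})

test_that("pairwise dissimilarity yields 45 symmetric entries on a small session", {
  cfg <- experiment_config(n_channels = 10L, block_duration = 40, seed = 13)
  ps <- study_presets("high", n_channels = 10L, interaction_strength = 1)
  sim <- simulate_experiment(cfg, act = ps$act, noise = ps$noise, seed = 13,
                             n_bad_channels = 0L)
  prep <- preprocess_recording(sim$raw, sim$layout, sim$design$labels,
                               behavior = sim$behavior)
  m <- suppressWarnings(pairwise_dissimilarity(prep$hemo, prep$labels,
                                               k_inner = 3L,
                                               lambda_grid =
                                                 lambda_grid_default(8)))
  expect_equal(dim(m), c(10L, 10L))
  expect_equal(sum(!is.na(m[upper.tri(m)])), 45L)
  expect_true(all(is.na(diag(m))))
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(m[upper.tri(m)] >= 0 & m[upper.tri(m)] <= 1))
  # within-level difficulty pairs are better discriminated than the same
  # level's construction cell against itself shifted (sanity: strong signal)
  s <- within_adjacent_summary(m)
  expect_gt(s$within_mean, 0.75)
})

test_that("statistically identical cells decode at chance", {
  set.seed(14)
  accs <- vapply(1:6, function(i) {
    x <- matrix(rnorm(240 * 6), 240, 6)
    # same generating distribution in both cells, interleaved in blocks as
    # conditions are in a session
    y <- rep(rep(c(TRUE, FALSE), each = 24), 5)
    suppressWarnings(nirsdecode:::nested_cv_core(x, y, denoise = FALSE,
                                                 lambda_grid =
                                                   lambda_grid_default(10)))$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 40)
  expect_lt(mean(accs), 60)
})
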