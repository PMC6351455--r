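const_series <- function(hbo, hbr, n = 50L, nc = 3L, fs = 1.955) {
  structure(list(time = (seq_len(n) - 1) / fs, fs = fs,
                 hbo = matrix(hbo, n, nc), hbr = matrix(hbr, n, nc),
                 channel_mask = rep(TRUE, nc), ground_truth = NULL),
            class = "hemo_series")
}

test_that("printed extinction matrix is invertible (direct determinant arithmetic)", {
  eps <- extinction_default()
  det_oracle <- 1486.59 * 1798.64 - 3843.71 * 2526.39
  expect_equal(det(eps), det_oracle)
  expect_lt(det_oracle, -7.0e6)
  expect_gt(det_oracle, -7.1e6)
})

test_that("forward model -> optical density -> inversion recovers concentrations to 1e-9", {
  lay <- optode_layout(3L, distance_cm = 3.5)
  s <- const_series(1e-3, -5e-4)
  raw <- forward_mbll(s, lay)
  od <- optical_density(raw, reference = "baseline")
  rec <- mbll_invert(od, lay)
  expect_lt(max(abs(rec$hbo - 1e-3)) / 1e-3, 1e-9)
  expect_lt(max(abs(rec$hbr - (-5e-4))) / 5e-4, 1e-9)
})

test_that("zero concentration changes give constant intensity and zero OD", {
  lay <- optode_layout(3L)
  s <- const_series(0, 0)
  raw <- forward_mbll(s, lay, baseline_intensity = 2.5)
  expect_true(all(raw$w760 == 2.5))
  expect_true(all(raw$w850 == 2.5))
  od <- optical_density(raw)
  expect_true(all(abs(od$w760) < 1e-15))
  rec <- mbll_invert(od, lay)
  expect_true(all(abs(rec$hbo) < 1e-15))
})

test_that("optical-density change is linear in source-detector distance", {
  s <- const_series(5e-4, -2e-4)
  od1 <- optical_density(forward_mbll(s, optode_layout(3L, 2)),
                         reference = "baseline")
  od2 <- optical_density(forward_mbll(s, optode_layout(3L, 4)),
                         reference = "baseline")
  expect_equal(od2$w760, 2 * od1$w760, tolerance = 1e-12)
  expect_equal(od2$w850, 2 * od1$w850, tolerance = 1e-12)
})

test_that("optical density closed forms hold with the mean reference", {
  raw <- structure(list(time = 0:3, fs = 1,
                        w760 = matrix(1, 4, 1), w850 = matrix(1, 4, 1),
                        baseline = 1), class = "raw_intensity")
  od <- optical_density(raw)
  expect_true(all(od$w760 == 0))
  # I = I0/2 at one sample -> dA = log10(2) there (baseline reference)
  raw$w760[2, 1] <- 0.5
  od2 <- optical_density(raw, reference = "baseline")
  expect_equal(od2$w760[2, 1], log10(2))
})

test_that("invalid inputs are rejected or flagged", {
  s <- const_series(0, 0)
  expect_error(forward_mbll(s, optode_layout(3L, -1)), "distance")
  expect_error(forward_mbll(s, optode_layout(3L), baseline_intensity = 0),
               "baseline")
  raw <- forward_mbll(s, optode_layout(3L))
  raw$w760[5, 2] <- -1
  expect_warning(od <- optical_density(raw), "non-positive")
  expect_false(od$channel_ok[2])
  expect_true(all(is.na(od$w760[, 2])))
  bad_eps <- matrix(1, 2, 2, dimnames = dimnames(extinction_default()))
  expect_error(mbll_invert(optical_density(forward_mbll(s, optode_layout(3L))),
                           optode_layout(3L), eps = bad_eps), "singular")
})

test_that("injected bad channels exceed the CV threshold and are excluded", {
  s <- small_session()
  raw_bad <- inject_bad_channels(s$sim$raw, k = 4L, seed = 3)
  qc <- channel_cv(raw_bad)
  bad <- attr(raw_bad, "bad_channels")
  expect_length(bad, 4L)
  expect_true(all(qc$excluded[bad]))
  expect_equal(attr(qc, "n_retained") + sum(qc$excluded), 16L)
})
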