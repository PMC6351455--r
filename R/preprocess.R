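#' Optical density change from raw intensities
#'
#' Converts intensities to optical-density changes
#' `dA(t) = log10(I0 / I(t))` per channel and wavelength. By default `I0` is
#' the channel's temporal mean intensity (the baseline of a real recording is
#' unknown); `reference = "baseline"` uses the recording's stored baseline
#' instead, making the conversion the exact inverse of [forward_mbll()].
#' With the mean reference, recovered concentration changes are exact up to a
#' constant per-channel offset (their temporal mean). Channels containing
#' non-positive intensities at either wavelength are flagged and excluded
#' from the OD matrices (set to `NA`).
#'
#' @param raw a `raw_intensity` recording.
#' @param reference `"mean"` (temporal mean intensity) or `"baseline"` (the
#'   recording's stored `baseline`, simulator output only).
#' @return An object of class `od_series`: `time`, `fs`, per-wavelength OD
#'   matrices `w760`, `w850`, and `channel_ok` logical vector.
#' @export
optical_density <- function(raw, reference = c("mean", "baseline")) {
  stopifnot(inherits(raw, "raw_intensity"))
  reference <- match.arg(reference)
  if (reference == "baseline" && is.null(raw$baseline)) {
    stop("recording carries no stored baseline", call. = FALSE)
  }
  nc <- ncol(raw$w760)
  ok <- rep(TRUE, nc)
  out <- list(time = raw$time, fs = raw$fs)
  for (w in c("w760", "w850")) {
    ints <- raw[[w]]
    bad <- apply(ints <= 0 | !is.finite(ints), 2L, any)
    ok <- ok & !bad
    ints[, bad] <- 1                       # placeholder; masked below
    i0 <- if (reference == "baseline") rep_len(raw$baseline, nc) else
      colMeans(ints)
    od <- log10(sweep(1 / ints, 2L, i0, `*`))
    od[, bad] <- NA_real_
    out[[w]] <- od
  }
  if (any(!ok)) {
    warning(sprintf("%d channel(s) with non-positive intensity excluded",
                    sum(!ok)))
  }
  out$channel_ok <- ok
  structure(out, class = "od_series")
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per channel and sample, the 2 x 2 linear system
#' `dA(lambda) / (d * DPF(lambda)) = eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR`
#' for the chromophore concentration changes. With `d` in cm and extinction
#' coefficients in M^-1 cm^-1 the solution is in mol/L; it is scaled by 1e3 to
#' the package's working unit, mmol/L.
#'
#' @param od an `od_series` (see [optical_density()]).
#' @param layout an [optode_layout()].
#' @param eps extinction matrix ([extinction_default()]); must be nonsingular.
#' @param dpf DPF pair ([dpf_default()]).
#' @return A `hemo_series` with `hbo`, `hbr` (mmol/L) and `channel_mask` taken
#'   from the OD channel flags.
#' @export
mbll_invert <- function(od, layout, eps = extinction_default(),
                        dpf = dpf_default()) {
  stopifnot(inherits(od, "od_series"))
  if (abs(det(eps)) < 1e-12) stop("extinction matrix is singular", call. = FALSE)
  nc <- ncol(od$w760)
  stopifnot(nrow(layout) == nc)
  einv <- solve(eps)
  # scaled OD per wavelength: dA / (d * DPF)
  s760 <- sweep(od$w760, 2L, layout$distance_cm * dpf[["w760"]], `/`)
  s850 <- sweep(od$w850, 2L, layout$distance_cm * dpf[["w850"]], `/`)
  hbo <- (einv["hbo", "w760"] * s760 + einv["hbo", "w850"] * s850) * 1e3
  hbr <- (einv["hbr", "w760"] * s760 + einv["hbr", "w850"] * s850) * 1e3
  structure(list(time = od$time, fs = od$fs, hbo = hbo, hbr = hbr,
                 channel_mask = od$channel_ok,
                 ground_truth = NULL),
            class = "hemo_series")
}

#' Channel quality control by coefficient of variation
#'
#' Computes the per-channel, per-wavelength coefficient of variation
#' `CV% = 100 * sd / mean` from the unfiltered raw intensities over the whole
#' session. A channel is excluded if either wavelength exceeds the threshold
#' or if its CV is undefined (zero mean).
#'
#' @param raw a `raw_intensity` recording (unfiltered).
#' @param threshold exclusion threshold in percent.
#' @return A data.frame of class `qc_report`: `channel`, `cv_w760`, `cv_w850`,
#'   `excluded`; attribute `n_retained`.
#' @export
channel_cv <- function(raw, threshold = 20) {
  stopifnot(inherits(raw, "raw_intensity"))
  cv_one <- function(m) {
    mu <- colMeans(m)
    s <- apply(m, 2L, sd)
    cv <- 100 * s / mu
    cv[mu == 0] <- NA_real_
    cv
  }
  cv760 <- cv_one(raw$w760)
  cv850 <- cv_one(raw$w850)
  undef <- !is.finite(cv760) | !is.finite(cv850)
  if (any(undef)) {
    warning(sprintf("CV undefined for %d channel(s) (zero mean); excluded",
                    sum(undef)))
  }
  excluded <- undef | cv760 > threshold | cv850 > threshold
  excluded[is.na(excluded)] <- TRUE
  rep_df <- data.frame(channel = seq_along(cv760), cv_w760 = cv760,
                       cv_w850 = cv850, excluded = excluded)
  attr(rep_df, "n_retained") <- sum(!excluded)
  attr(rep_df, "threshold") <- threshold
  class(rep_df) <- c("qc_report", "data.frame")
  rep_df
}

#' Design a least-squares linear-phase FIR low-pass filter
#'
#' Type-I (odd-length, symmetric) FIR whose amplitude response minimizes the
#' integrated squared error against an ideal low-pass over a dense frequency
#' grid, with a don't-care transition band; the kernel is normalized to exact
#' unit DC gain.
#'
#' @param fs sampling rate (Hz).
#' @param cutoff passband edge (Hz); must be below Nyquist.
#' @param n_taps odd filter length.
#' @param transition_width width of the don't-care band (Hz).
#' @return numeric kernel of length `n_taps` (class `fir_filter`, with the
#'   design parameters as attributes).
#' @export
design_lowpass_fir <- function(fs, cutoff = 0.1, n_taps = 101L,
                               transition_width = 0.03) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency",
                             call. = FALSE)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  m <- (n_taps - 1L) / 2L
  wp <- 2 * pi * cutoff / fs
  ws <- min(2 * pi * (cutoff + transition_width) / fs, pi)
  grid <- seq(0, pi, length.out = 2048L)
  keep <- grid <= wp | grid >= ws
  w <- grid[keep]
  d <- as.numeric(w <= wp)
  # amplitude A(w) = a0 + 2 sum_m a_m cos(m w)
  A <- cbind(1, 2 * cos(outer(w, seq_len(m))))
  a <- qr.solve(A, d)
  h <- c(rev(a[-1]), a[1], a[-1])
  h <- h / sum(h)
  structure(h, class = "fir_filter", fs = fs, cutoff = cutoff,
            n_taps = n_taps, transition_width = transition_width)
}

#' Frequency response of an FIR kernel
#'
#' @param h FIR kernel.
#' @param freq frequencies (Hz) at which to evaluate.
#' @param fs sampling rate (Hz); defaults to the kernel's design rate.
#' @return complex response values.
#' @export
fir_response <- function(h, freq, fs = attr(h, "fs")) {
  k <- seq_along(h) - 1
  vapply(freq, function(f) {
    sum(h * exp(-1i * 2 * pi * f / fs * k))
  }, complex(1))
}

#' Zero-phase low-pass filtering
#'
#' Applies the least-squares FIR low-pass forward and backward (implemented
#' as a single convolution with the kernel's autocorrelation, which for a
#' symmetric kernel is exactly the forward-backward result) with reflection
#' padding at the edges. DC gain is exactly 1, so constant signals pass
#' unchanged.
#'
#' @param x numeric vector or time x channel matrix.
#' @param fs sampling rate (Hz).
#' @param cutoff passband edge (Hz).
#' @param n_taps FIR length (odd).
#' @param h optional pre-designed kernel (overrides `cutoff` / `n_taps`).
#' @return filtered data, same shape as `x`.
#' @export
lowpass <- function(x, fs, cutoff = 0.1, n_taps = 101L, h = NULL) {
  if (is.null(h)) h <- design_lowpass_fir(fs, cutoff, n_taps)
  g <- convolve(h, h, type = "open")   # zero-phase kernel, length 2L-1
  g <- g / sum(g)
  pad <- length(h)
  filt1 <- function(v) {
    n <- length(v)
    if (n < 2L) return(v)
    p <- min(pad, n - 1L)
    vp <- c(v[(p + 1L):2L], v, v[(n - 1L):(n - p)])
    full <- convolve(vp, rev(g), type = "open")
    full[(p + length(h)):(p + length(h) + n - 1L)]
  }
  if (is.matrix(x)) apply(x, 2L, filt1) else filt1(x)
}

#' Low-pass filter a hemoglobin or optical-density series
#'
#' @param series a `hemo_series` or `od_series`.
#' @param cutoff passband edge (Hz).
#' @param n_taps FIR length.
#' @return the series with all component matrices filtered.
#' @export
lowpass_series <- function(series, cutoff = 0.1, n_taps = 101L) {
  h <- design_lowpass_fir(series$fs, cutoff, n_taps)
  for (comp in intersect(c("hbo", "hbr", "w760", "w850"), names(series))) {
    keep_ok <- apply(is.finite(series[[comp]]), 2L, all)
    filt <- series[[comp]]
    filt[, keep_ok] <- lowpass(series[[comp]][, keep_ok, drop = FALSE],
                               series$fs, h = h)
    series[[comp]] <- filt
  }
  series
}

#' Mask fNIRS samples in behaviorally invalid segments
#'
#' A segment (the stretch between two successive speed signs) is invalid when
#' the fraction of 50 Hz behavior samples within the speed tolerance is below
#' the criterion; all fNIRS samples in invalid segments are masked. Scoring
#' is delegated to [score_segments()], the single source of truth shared with
#' the behavioral error-rate analysis.
#'
#' @param labels a label track (from [generate_design()]) with a `segment`
#'   column.
#' @param behavior a `behavior_track` (see [generate_behavior()]), or `NULL`.
#' @param tolerance speed tolerance (km/h).
#' @param criterion minimum in-tolerance fraction for a segment to be kept.
#' @return `labels` with its `valid` column updated; attribute
#'   `segment_scores` carries the per-segment scores.
#' @export
exclude_invalid_segments <- function(labels, behavior, tolerance = 5,
                                     criterion = 0.90) {
  if (is.null(behavior)) {
    warning("no behavior track supplied; no segments excluded")
    return(labels)
  }
  scores <- score_segments(behavior, tolerance = tolerance,
                           criterion = criterion)
  bad <- scores$segment[!scores$passed]
  labels$valid <- labels$valid & !(labels$segment %in% bad)
  attr(labels, "segment_scores") <- scores
  labels
}
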