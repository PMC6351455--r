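#' Molar extinction coefficients for HbO and HbR
#'
#' 2 x 2 matrix of molar extinction coefficients (M^-1 cm^-1) at the two
#' recording wavelengths, rows = wavelengths (760, 850 nm), columns =
#' chromophores (HbO, HbR); Gratzer spectrum values as used by nirsLAB.
#'
#' @return numeric matrix with dimnames.
#' @export
extinction_default <- function() {
  matrix(c(1486.59, 3843.71,
           2526.39, 1798.64),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("w760", "w850"), c("hbo", "hbr")))
}

#' Differential path-length factors
#'
#' Dimensionless correction for the photon path exceeding the geometric
#' emitter-detector distance. The two listed values are assigned to the two
#' wavelengths in listed order (7.25 to 760 nm, 6.38 to 850 nm).
#'
#' @return named numeric vector `c(w760 = 7.25, w850 = 6.38)`.
#' @export
dpf_default <- function() c(w760 = 7.25, w850 = 6.38)

#' Optode layout
#'
#' Emitter-detector channel table with source-detector distances (cm) and 2D
#' scalp coordinates. The default layout arranges channels on a grid with a
#' mean distance of 3.5 cm.
#'
#' @param n_channels number of channels.
#' @param distance_cm source-detector distance, recycled per channel.
#' @return data.frame of class `optode_layout` with columns `channel`,
#'   `emitter`, `detector`, `distance_cm`, `x`, `y`.
#' @export
optode_layout <- function(n_channels = 78L, distance_cm = 3.5) {
  stopifnot(n_channels >= 1, all(distance_cm > 0))
  ncol_grid <- ceiling(sqrt(n_channels))
  idx <- seq_len(n_channels) - 1L
  out <- data.frame(
    channel = seq_len(n_channels),
    emitter = idx %/% 2L + 1L,
    detector = idx %/% 2L + idx %% 2L + 1L,
    distance_cm = rep_len(distance_cm, n_channels),
    x = (idx %% ncol_grid) * 3.5,
    y = (idx %/% ncol_grid) * 3.5
  )
  class(out) <- c("optode_layout", "data.frame")
  out
}

#' Forward modified Beer-Lambert model: hemoglobin to raw intensities
#'
#' Computes the optical-density change per wavelength,
#' `dA(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF(lambda)`
#' (concentrations in mmol/L are converted to M for the extinction
#' coefficients in M^-1 cm^-1, distances in cm), and raw intensities
#' `I(t) = I0 * 10^(-dA(t))`. Exact inverse of [mbll_invert()] composed with
#' [optical_density()].
#'
#' @param series a `hemo_series` (mmol/L).
#' @param layout an [optode_layout()]; distances must be positive.
#' @param eps extinction matrix, see [extinction_default()].
#' @param dpf wavelength DPF pair, see [dpf_default()].
#' @param baseline_intensity positive baseline intensity `I0` (recycled per
#'   channel).
#' @return An object of class `raw_intensity`: `time`, `fs`, and per-wavelength
#'   intensity matrices `w760`, `w850` (time x channel).
#' @export
forward_mbll <- function(series, layout, eps = extinction_default(),
                         dpf = dpf_default(), baseline_intensity = 1) {
  stopifnot(inherits(series, "hemo_series"))
  if (any(layout$distance_cm <= 0)) {
    stop("source-detector distances must be positive", call. = FALSE)
  }
  if (any(baseline_intensity <= 0)) {
    stop("baseline intensity must be positive", call. = FALSE)
  }
  nc <- ncol(series$hbo)
  stopifnot(nrow(layout) == nc)
  i0 <- rep_len(baseline_intensity, nc)
  conc_m <- list(hbo = series$hbo * 1e-3, hbr = series$hbr * 1e-3)  # mmol/L -> M
  out <- list(time = series$time, fs = series$fs, baseline = i0)
  for (w in rownames(eps)) {
    da <- (conc_m$hbo * eps[w, "hbo"] + conc_m$hbr * eps[w, "hbr"]) *
      matrix(layout$distance_cm * dpf[[w]], nrow(series$hbo), nc, byrow = TRUE)
    out[[w]] <- sweep(10^(-da), 2L, i0, `*`)
  }
  structure(out, class = "raw_intensity")
}

#' Inject misbehaving channels into a raw recording
#'
#' Multiplies `k` randomly chosen channels (both wavelengths) by a large slow
#' sinusoidal drift so their coefficient of variation exceeds the 20% QC
#' threshold; used to exercise channel rejection.
#'
#' @param raw a `raw_intensity` recording.
#' @param k number of channels to corrupt.
#' @param seed integer seed.
#' @param drift_frac fractional amplitude of the drift (0.5 gives CV ~ 35%).
#' @return The recording with an attribute `bad_channels` listing the
#'   corrupted channel indices.
#' @export
inject_bad_channels <- function(raw, k = 5L, seed = 1L, drift_frac = 0.5) {
  stopifnot(inherits(raw, "raw_intensity"))
  nc <- ncol(raw$w760)
  k <- min(k, nc)
  with_seed(derive_seed(seed, 3L), {
    bad <- sample(nc, k)
    period <- max(raw$time) / 3
    drift <- 1 + drift_frac * sin(2 * pi * raw$time / period)
    for (w in c("w760", "w850")) {
      raw[[w]][, bad] <- raw[[w]][, bad] * drift
    }
    attr(raw, "bad_channels") <- sort(bad)
  })
  raw
}

#' @export
print.raw_intensity <- function(x, ...) {
  cat(sprintf("Raw intensity recording: %d samples x %d channels x 2 wavelengths @ %.3f Hz\n",
              nrow(x$w760), ncol(x$w760), x$fs))
  invisible(x)
}
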