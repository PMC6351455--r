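#' Noise specification for simulated hemodynamics
#'
#' Physiological oscillations (cardiac ~1.1 Hz, respiration ~0.3 Hz, Mayer
#' waves ~0.1 Hz) with per-channel random phases, instrumental white noise,
#' and motion artifacts. Motion is a common-mode process shared across
#' channels through a per-channel gain vector: Poisson-timed spikes
#' (exponentially decaying transients) each followed by a persistent random
#' baseline shift — the rank-one structure that first-PC deletion targets.
#' The cardiac frequency exceeds the Nyquist rate of the 1.955 Hz recording;
#' sinusoids are evaluated directly at the sample times, so it aliases as in
#' a real recording. All amplitudes are sustained HbO-scale values (mmol/L);
#' zero amplitudes give exactly noiseless output.
#'
#' @param cardiac_freq,cardiac_amp cardiac oscillation frequency (Hz), amplitude.
#' @param resp_freq,resp_amp respiration frequency (Hz), amplitude.
#' @param mayer_freq,mayer_amp Mayer-wave frequency (Hz), amplitude.
#' @param white_sd white-noise standard deviation.
#' @param spike_rate_per_min motion-spike rate (events per minute).
#' @param spike_amp motion-spike amplitude.
#' @param shift_amp baseline-shift half-range (shifts drawn uniform +/- this).
#' @param spike_tau decay time constant of a motion spike (s).
#' @param shift_tau slow decay time constant of a baseline shift (s); keeps
#'   the motion variance bounded over a session instead of accumulating as a
#'   random walk.
#' @param gain_jitter_sd sd of the per-channel motion gain around 1.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(cardiac_freq = 1.1, cardiac_amp = 5e-5,
                       resp_freq = 0.3, resp_amp = 3e-5,
                       mayer_freq = 0.1, mayer_amp = 5e-5,
                       white_sd = 3e-5,
                       spike_rate_per_min = 4, spike_amp = 2e-4,
                       shift_amp = 1.5e-4, spike_tau = 2, shift_tau = 25,
                       gain_jitter_sd = 0.1) {
  amps <- c(cardiac_amp, resp_amp, mayer_amp, white_sd, spike_amp, shift_amp)
  if (any(amps < 0)) stop("noise amplitudes must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "noise_spec")
}

#' Add physiological, instrumental and motion noise to a hemoglobin series
#'
#' @param series a `hemo_series` (see [generate_hemodynamics()]).
#' @param noise a [noise_spec()].
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @return The series with noise added to both chromophores (HbR receives the
#'   physiological oscillations at half amplitude, motion at full amplitude).
#' @export
add_noise <- function(series, noise, seed = 1L) {
  stopifnot(inherits(series, "hemo_series"), inherits(noise, "noise_spec"))
  if (!all(is.finite(series$hbo)) || !all(is.finite(series$hbr))) {
    stop("series must be finite", call. = FALSE)
  }
  n <- length(series$time)
  nc <- ncol(series$hbo)
  with_seed(derive_seed(seed, 2L), {
    osc <- function(freq, amp) {
      if (amp == 0) return(NULL)
      phase <- runif(nc, 0, 2 * pi)
      amp * sin(outer(2 * pi * freq * series$time, phase, `+`))
    }
    build <- function(phys_scale) {
      out <- matrix(0, n, nc)
      for (comp in list(c(noise$cardiac_freq, noise$cardiac_amp),
                        c(noise$resp_freq, noise$resp_amp),
                        c(noise$mayer_freq, noise$mayer_amp))) {
        o <- osc(comp[1], comp[2] * phys_scale)
        if (!is.null(o)) out <- out + o
      }
      if (noise$white_sd > 0) {
        out <- out + matrix(rnorm(n * nc, sd = noise$white_sd), n, nc)
      }
      out
    }
    series$hbo <- series$hbo + build(1)
    series$hbr <- series$hbr + build(0.5)

    if (noise$spike_amp > 0 || noise$shift_amp > 0) {
      dur <- n / series$fs
      n_ev <- rpois(1L, noise$spike_rate_per_min * dur / 60)
      if (n_ev > 0) {
        ev_t <- sort(runif(n_ev, 0, dur))
        m <- numeric(n)
        for (t0 in ev_t) {
          after <- series$time >= t0
          dt <- series$time[after] - t0
          m[after] <- m[after] +
            sample(c(-1, 1), 1L) * noise$spike_amp *
              exp(-dt / noise$spike_tau) +
            runif(1L, -noise$shift_amp, noise$shift_amp) *
              exp(-dt / noise$shift_tau)
        }
        gain <- 1 + rnorm(nc, sd = noise$gain_jitter_sd)
        motion <- m %o% gain
        series$hbo <- series$hbo + motion
        series$hbr <- series$hbr + motion
      }
    }
  })
  series
}
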