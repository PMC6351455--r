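#' Target speed track of the n-back speed-regulation task
#'
#' The participant must drive at the speed posted `n` signs before the most
#' recently passed sign. Until `n` signs have been passed, the target is the
#' posted speed of the first sign. With `n = 0` the target is the current
#' sign's speed.
#'
#' @param signs data.frame of sign events with columns `time` (strictly
#'   increasing) and `speed_kmh`.
#' @param n n-back level (>= 0).
#' @param time numeric vector of sample times at which to evaluate the target.
#' @return numeric vector of target speeds (km/h), one per element of `time`.
#' @export
target_speed_track <- function(signs, n, time) {
  if (is.null(signs) || nrow(signs) == 0L) stop("empty sign list", call. = FALSE)
  stopifnot(n >= 0, !is.unsorted(signs$time, strictly = TRUE))
  passed <- findInterval(time, signs$time)       # number of signs passed
  idx <- pmax(passed - n, 1L)
  signs$speed_kmh[idx]
}

#' Score speed-keeping per segment
#'
#' Splits the track into segments (between successive speed signs) and
#' computes, per segment, the fraction of samples with
#' `|speed - target| <= tolerance`. A segment passes iff the fraction is at
#' least `criterion` (the 90% boundary counts as passed; failure is defined
#' as driving within tolerance less than 90% of the segment).
#'
#' @param track a `behavior_track` (data.frame with `time`, `speed`, `target`,
#'   `segment`, and optionally `wml_level`, `difficulty`).
#' @param tolerance speed tolerance (km/h).
#' @param criterion minimum passing fraction.
#' @return data.frame of class `segment_scores`: `segment`, `fraction`,
#'   `passed`, plus `wml_level` / `difficulty` when present in the track.
#' @export
score_segments <- function(track, tolerance = 5, criterion = 0.90) {
  stopifnot(all(c("speed", "target", "segment") %in% names(track)))
  segs <- sort(unique(track$segment))
  segs <- segs[segs >= 1]
  in_tol <- abs(track$speed - track$target) <= tolerance
  out <- lapply(segs, function(s) {
    i <- which(track$segment == s)
    if (length(i) == 0L) {
      warning(sprintf("segment %d has no samples; skipped", s))
      return(NULL)
    }
    row <- data.frame(segment = s, fraction = mean(in_tol[i]))
    for (col in c("wml_level", "difficulty")) {
      if (col %in% names(track)) row[[col]] <- track[[col]][i[1L]]
    }
    row
  })
  out <- do.call(rbind, out)
  out$passed <- out$fraction >= criterion
  class(out) <- c("segment_scores", "data.frame")
  out
}

#' Speed-error rate per condition cell
#'
#' Fraction of failed segments per (WML level, difficulty) cell.
#'
#' @param scores a [score_segments()] result with `wml_level` and `difficulty`.
#' @return data.frame `wml_level`, `difficulty`, `n_segments`, `error_rate`
#'   (`NA` for empty cells).
#' @export
error_rate <- function(scores) {
  stopifnot(nrow(scores) > 0,
            all(c("wml_level", "difficulty") %in% names(scores)))
  agg <- aggregate(cbind(failed = !scores$passed, n = 1L),
                   by = list(wml_level = scores$wml_level,
                             difficulty = scores$difficulty), FUN = sum)
  data.frame(wml_level = agg$wml_level, difficulty = agg$difficulty,
             n_segments = agg$n, error_rate = agg$failed / agg$n)
}

#' Steering reversal rate
#'
#' Number of times the steering angle crosses the centered (zero) position
#' per second. A crossing is a sign change between successive samples, with
#' an optional hysteresis band of `epsilon` degrees (a crossing counts only
#' once the angle leaves the band on the other side). Samples exactly at zero
#' continue the previous sign and are never counted as crossings.
#'
#' @param steering numeric steering-angle series (degrees).
#' @param fs sampling rate (Hz).
#' @param epsilon half-width of the hysteresis band (degrees); 0 = literal
#'   zero crossings.
#' @return crossings per second (Hz).
#' @export
steering_reversal_rate <- function(steering, fs, epsilon = 0) {
  n <- length(steering)
  if (n < 2L) stop("steering series too short for a rate", call. = FALSE)
  duration <- n / fs
  s <- sign(steering)
  if (epsilon > 0) s[abs(steering) <= epsilon] <- 0
  s <- s[s != 0]
  if (length(s) < 2L) return(0)
  sum(s[-1] != s[-length(s)]) / duration
}

#' Steering reversal rate per condition cell
#'
#' @param track a `behavior_track` with `steering`, `wml_level`, `difficulty`.
#' @param fs sampling rate (Hz); defaults to the track's rate.
#' @param epsilon hysteresis band (degrees).
#' @return data.frame `wml_level`, `difficulty`, `reversal_rate_hz`.
#' @export
reversal_rate_by_cell <- function(track, fs = attr(track, "fs"), epsilon = 0) {
  cells <- unique(track[, c("wml_level", "difficulty")])
  cells <- cells[order(cells$wml_level, cells$difficulty), ]
  cells$reversal_rate_hz <- mapply(function(l, d) {
    i <- track$wml_level == l & track$difficulty == d
    steering_reversal_rate(track$steering[i], fs, epsilon)
  }, cells$wml_level, cells$difficulty)
  rownames(cells) <- NULL
  cells
}
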