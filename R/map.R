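#' Channel-wise univariate predictivity (Tjur's coefficient of discrimination)
#'
#' Fits a single-feature logistic regression of the difficulty labels on one
#' channel's HbR series and returns Tjur's R-squared: the mean fitted
#' probability among construction samples minus the mean fitted probability
#' among non-construction samples. Varies between 0 (no predictivity) and 1
#' (perfect predictivity); a constant channel yields exactly 0.
#'
#' @param x single-channel HbR series (numeric vector).
#' @param y difficulty labels: logical/0-1, `TRUE` = construction.
#' @return Tjur R-squared (scalar).
#' @export
univariate_tjur <- function(x, y) {
  y <- as.numeric(as.logical(y))
  stopifnot(length(x) == length(y))
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (sd(x) == 0) return(0)
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  p <- fitted(fit)
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Per-participant, per-level univariate predictivity maps
#'
#' Applies PCA denoising (first PC deleted, eigenvalue rule) to the valid
#' samples of each WML level and computes [univariate_tjur()] per retained
#' channel.
#'
#' @param hemo a `hemo_series` (HbR used).
#' @param labels label track with `difficulty`, `wml_level`, `valid`.
#' @param channels channel subset (defaults to the series' channel mask).
#' @param denoise apply the per-condition PCA denoising first?
#' @param eigen_threshold,drop_first PCA settings.
#' @return matrix `n_levels x n_channels` of Tjur R-squared values (`NA` for
#'   channels outside the subset), rownames `level_0 ...`.
#' @export
predictivity_map <- function(hemo, labels, channels = NULL, denoise = TRUE,
                             eigen_threshold = 0.7, drop_first = TRUE) {
  x_all <- if (inherits(hemo, "hemo_series")) hemo$hbr else as.matrix(hemo)
  if (inherits(hemo, "hemo_series") && is.null(channels)) {
    channels <- which(hemo$channel_mask)
  }
  if (is.null(channels)) channels <- seq_len(ncol(x_all))
  keep <- labels$valid
  lab <- labels[keep, , drop = FALSE]
  x_all <- x_all[keep, , drop = FALSE]
  levels_ <- sort(unique(lab$wml_level))
  out <- matrix(NA_real_, length(levels_), ncol(x_all),
                dimnames = list(sprintf("level_%d", levels_), NULL))
  for (li in seq_along(levels_)) {
    sub <- lab$wml_level == levels_[li]
    xs <- x_all[sub, channels, drop = FALSE]
    if (denoise) {
      den <- try_denoiser(xs, eigen_threshold, drop_first)
      if (!is.null(den)) xs <- pca_denoise_apply(den, xs)
    }
    y <- lab$difficulty[sub] == "construction"
    out[li, channels] <- apply(xs, 2L, univariate_tjur, y = y)
  }
  out
}

#' Accuracy-weighted group-average predictivity map
#'
#' Averages per-participant Tjur R-squared values per channel, weighting each
#' participant by their multivariate decoding accuracy:
#' `R2_avg(i) = sum_n R2_uvr(i, n) * Accuracy(n) / sum_n Accuracy(n)`.
#' Channels a participant lacks (QC-excluded, `NA`) are omitted from that
#' channel's sums, so the result is a convex combination of the contributing
#' participants' values.
#'
#' @param r2 participants x channels matrix of Tjur R-squared values (may
#'   contain `NA`).
#' @param weights positive per-participant accuracy weights.
#' @return per-channel weighted average; `NA` where no participant
#'   contributes.
#' @export
weighted_group_map <- function(r2, weights) {
  r2 <- as.matrix(r2)
  stopifnot(length(weights) == nrow(r2), all(weights > 0))
  w <- matrix(weights, nrow(r2), ncol(r2))
  w[is.na(r2)] <- NA
  num <- colSums(r2 * w, na.rm = TRUE)
  den <- colSums(w, na.rm = TRUE)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Ranked channel report for group predictivity maps
#'
#' Sorts channels by group-average predictivity per WML level and attaches
#' layout positions. Negative Tjur values (possible in pathological fits) are
#' clamped to 0 in the `r2_display` column; the raw value is retained.
#'
#' @param group_maps levels x channels matrix of group R-squared averages.
#' @param layout an [optode_layout()].
#' @return data.frame with `level`, `rank`, `channel`, `r2_avg`,
#'   `r2_display`, `x`, `y`; attribute `uninformative` flags levels whose map
#'   is constant.
#' @export
map_report <- function(group_maps, layout) {
  group_maps <- as.matrix(group_maps)
  stopifnot(ncol(group_maps) == nrow(layout))
  rows <- list()
  uninformative <- character(0)
  for (li in seq_len(nrow(group_maps))) {
    v <- group_maps[li, ]
    lev <- rownames(group_maps)[li] %||% sprintf("level_%d", li - 1L)
    if (length(unique(v[!is.na(v)])) <= 1L) uninformative <- c(uninformative, lev)
    ord <- order(v, decreasing = TRUE, na.last = TRUE)
    rows[[li]] <- data.frame(
      level = lev, rank = seq_along(ord), channel = layout$channel[ord],
      r2_avg = v[ord], r2_display = pmax(v[ord], 0),
      x = layout$x[ord], y = layout$y[ord])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "uninformative") <- uninformative
  out
}
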