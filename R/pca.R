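#' Fit a PCA denoiser on training data
#'
#' Standardizes each channel on the training data, eigendecomposes the
#' training correlation matrix, and selects the components to keep for
#' reconstruction: the first principal component (assumed dominated by motion
#' artifacts) is always deleted, and of the remaining components only those
#' with eigenvalues above the threshold (Kaiser/Jolliffe rule, 0.7 on the
#' correlation scale) are retained. Set `drop_first = FALSE` and
#' `eigen_threshold = 0` for the retain-all identity transform. A
#' covariance-matrix variant is available via `use_correlation = FALSE`.
#'
#' @param x time x channel training matrix (at least 2 channels).
#' @param eigen_threshold minimum eigenvalue of a retained component.
#' @param drop_first delete the first principal component?
#' @param use_correlation standardize channels (correlation-based PCA)?
#' @return An object of class `pca_denoiser`: centering/scaling vectors,
#'   eigenvectors, eigenvalues, retained component indices.
#' @export
pca_denoise_fit <- function(x, eigen_threshold = 0.7, drop_first = TRUE,
                            use_correlation = TRUE) {
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  center <- colMeans(x)
  scale_ <- if (use_correlation) apply(x, 2L, sd) else rep(1, ncol(x))
  scale_[scale_ == 0] <- 1
  z <- sweep(sweep(x, 2L, center), 2L, scale_, `/`)
  e <- eigen(crossprod(z) / (nrow(z) - 1L), symmetric = TRUE)
  keep <- seq_len(ncol(x))
  if (drop_first) keep <- keep[-1L]
  keep <- keep[e$values[keep] > eigen_threshold]
  if (length(keep) == 0L) {
    stop("no principal components retained; lower `eigen_threshold`",
         call. = FALSE)
  }
  structure(list(center = center, scale = scale_,
                 vectors = e$vectors, values = e$values,
                 retained = keep,
                 drop_first = drop_first,
                 eigen_threshold = eigen_threshold),
            class = "pca_denoiser")
}

#' Apply a fitted PCA denoiser
#'
#' Projects data (training or held-out) onto the training-derived components,
#' reconstructs from the retained set only, and restores the original scale.
#'
#' @param denoiser a [pca_denoise_fit()] result.
#' @param x time x channel matrix with the same channels as the training data.
#' @return denoised matrix, same shape as `x`.
#' @export
pca_denoise_apply <- function(denoiser, x) {
  stopifnot(inherits(denoiser, "pca_denoiser"),
            ncol(x) == length(denoiser$center))
  z <- sweep(sweep(x, 2L, denoiser$center), 2L, denoiser$scale, `/`)
  v <- denoiser$vectors[, denoiser$retained, drop = FALSE]
  recon <- z %*% v %*% t(v)
  sweep(sweep(recon, 2L, denoiser$scale, `*`), 2L, denoiser$center, `+`)
}

#' @export
print.pca_denoiser <- function(x, ...) {
  cat(sprintf("PCA denoiser: %d/%d components retained (threshold %.2f%s)\n",
              length(x$retained), length(x$values), x$eigen_threshold,
              if (x$drop_first) ", first PC deleted" else ""))
  invisible(x)
}
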