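#' Contiguous outer cross-validation folds
#'
#' Partitions the valid samples, in temporal order, into `k` contiguous
#' near-equal blocks; when the sample count is not divisible by `k` the
#' remainder is distributed one extra sample to each of the earliest folds.
#'
#' @param idx vector of (valid) sample indices in temporal order.
#' @param k number of folds.
#' @return list of `k` index vectors.
#' @export
make_outer_folds <- function(idx, k = 5L) {
  n <- length(idx)
  if (k > n) stop("more folds than samples", call. = FALSE)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(idx, rep(seq_len(k), times = sizes))
}

#' Fit an L2-penalized (ridge) logistic regression
#'
#' Minimizes the mean binomial negative log-likelihood plus
#' `lambda/2 * ||w||^2` (intercept unpenalized) by damped Newton iterations,
#' to a gradient norm below `tol`.
#'
#' @param x samples x features matrix (finite).
#' @param y binary response (0/1 or logical); both classes must be present.
#' @param lambda ridge penalty (>= 0).
#' @param tol convergence tolerance on the L2 norm of the gradient.
#' @param max_iter maximum Newton iterations.
#' @param init optional warm-start coefficient vector `c(intercept, w)`.
#' @return An object of class `ridge_logistic`: `intercept`, `weights`,
#'   `lambda`, `converged`, `n_iter`.
#' @export
fit_ridge_logistic <- function(x, y, lambda, tol = 1e-6, max_iter = 200L,
                               init = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(all(is.finite(x)), all(y %in% c(0, 1)), lambda >= 0)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  n <- nrow(x)
  p <- ncol(x)
  beta <- if (is.null(init)) numeric(p + 1L) else init
  pen <- c(0, rep(lambda, p))
  objective <- function(b) {
    eta <- b[1L] + drop(x %*% b[-1L])
    # numerically stable log(1 + exp(-y_pm * eta))
    m <- ifelse(y == 1, -eta, eta)
    mean(ifelse(m > 30, m, log1p(exp(m)))) + lambda / 2 * sum(b[-1L]^2)
  }
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- beta[1L] + drop(x %*% beta[-1L])
    mu <- plogis(eta)
    grad <- c(mean(mu - y), drop(crossprod(x, mu - y)) / n) + pen * beta
    if (sqrt(sum(grad^2)) < tol) {
      converged <- TRUE
      break
    }
    wts <- pmax(mu * (1 - mu), 1e-10)
    xa <- cbind(1, x)
    hess <- crossprod(xa, xa * wts) / n + diag(pen, p + 1L)
    step <- drop(solve(hess, grad))
    f0 <- objective(beta)
    t_ <- 1
    repeat {
      cand <- beta - t_ * step
      if (objective(cand) <= f0 || t_ < 1e-8) break
      t_ <- t_ / 2
    }
    beta <- cand
  }
  structure(list(intercept = beta[1L], weights = beta[-1L], lambda = lambda,
                 converged = converged, n_iter = iter),
            class = "ridge_logistic")
}

#' Predict class probabilities and classes
#'
#' Logistic probability per sample; samples with `p >= 0.5` are assigned to
#' the positive class (construction) — the boundary is inclusive.
#'
#' @param object a fitted `ridge_logistic` model.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return list with `probability` and logical `class` vectors.
#' @export
predict.ridge_logistic <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == length(object$weights))
  p <- plogis(object$intercept + drop(newdata %*% object$weights))
  list(probability = p, class = p >= 0.5)
}

#' Default penalty grid
#'
#' 50 log-spaced ridge penalties spanning 1e-4 to 1e4.
#' @param n grid size.
#' @param lo,hi grid range.
#' @return increasing numeric vector.
#' @export
lambda_grid_default <- function(n = 50L, lo = 1e-4, hi = 1e4) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# Fit the PCA denoiser, returning NULL (with a warning) when the training
# fold's correlation spectrum leaves no retainable component; callers treat
# such folds as degenerate.
try_denoiser <- function(x, eigen_threshold, drop_first) {
  tryCatch(
    pca_denoise_fit(x, eigen_threshold = eigen_threshold,
                    drop_first = drop_first),
    error = function(e) {
      warning("training fold left no retainable principal component; ",
              "denoising skipped for this fold", call. = FALSE)
      NULL
    })
}

# z-scoring helpers: statistics from the training fold only
train_scaler <- function(x) {
  center <- colMeans(x)
  scale_ <- apply(x, 2L, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  list(center = center, scale = scale_)
}
apply_scaler <- function(sc, x) {
  sweep(sweep(x, 2L, sc$center), 2L, sc$scale, `/`)
}

#' Select the ridge penalty by inner cross-validation
#'
#' Runs an inner k-fold cross-validation (contiguous folds) on the training
#' data: per inner fold the PCA denoiser and feature scaler are fitted on the
#' inner-training samples only, a warm-started ridge path is fitted over the
#' penalty grid, and each penalty is scored by out-of-sample accuracy on the
#' inner-validation samples. Returns the largest penalty whose mean
#' inner-fold accuracy is within one standard error of the best (the
#' one-standard-error rule); ties — exact or at the resolution of the
#' inner-validation noise — go to the stronger penalty. Inner folds whose
#' training part contains a single class are skipped with a warning.
#'
#' @param x training samples x channels matrix.
#' @param y binary training response.
#' @param k_inner number of inner folds.
#' @param lambda_grid increasing penalty grid.
#' @param denoise apply train-fold PCA denoising inside the inner loop?
#' @param eigen_threshold,drop_first PCA denoiser settings.
#' @return the selected penalty (scalar); attribute `mean_accuracy` carries
#'   the per-penalty inner-CV accuracies.
#' @export
select_lambda <- function(x, y, k_inner = 5L,
                          lambda_grid = lambda_grid_default(),
                          denoise = TRUE, eigen_threshold = 0.7,
                          drop_first = TRUE) {
  stopifnot(length(lambda_grid) >= 1L)
  if (length(lambda_grid) == 1L) return(lambda_grid)
  folds <- make_outer_folds(seq_len(nrow(x)), k_inner)
  ord <- order(lambda_grid, decreasing = TRUE)  # fit from strongest penalty
  acc <- matrix(NA_real_, length(folds), length(lambda_grid))
  for (f in seq_along(folds)) {
    val <- folds[[f]]
    tr <- setdiff(seq_len(nrow(x)), val)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L || length(unique(y[val])) < 1L) {
      warning(sprintf("inner fold %d degenerate (single class); skipped", f))
      next
    }
    xtr <- x[tr, , drop = FALSE]
    xval <- x[val, , drop = FALSE]
    if (denoise) {
      den <- try_denoiser(xtr, eigen_threshold, drop_first)
      if (!is.null(den)) {
        xtr <- pca_denoise_apply(den, xtr)
        xval <- pca_denoise_apply(den, xval)
      }
    }
    sc <- train_scaler(xtr)
    xtr <- apply_scaler(sc, xtr)
    xval <- apply_scaler(sc, xval)
    init <- NULL
    for (j in ord) {
      fit <- fit_ridge_logistic(xtr, ytr, lambda_grid[j], init = init)
      init <- c(fit$intercept, fit$weights)
      acc[f, j] <- mean(predict(fit, xval)$class == (y[val] == 1))
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  if (all(is.nan(mean_acc))) {
    warning("every inner fold degenerate; defaulting to the strongest penalty")
    return(structure(max(lambda_grid), mean_accuracy = mean_acc))
  }
  best_j <- which.max(mean_acc)
  k_eff <- sum(!is.na(acc[, best_j]))
  se_best <- if (k_eff > 1) sd(acc[, best_j], na.rm = TRUE) / sqrt(k_eff) else 0
  sel <- max(which(mean_acc >= mean_acc[best_j] - se_best - 1e-12))
  structure(lambda_grid[sel], mean_accuracy = mean_acc)
}

#' Confusion counts for binary difficulty decoding
#'
#' @param truth logical/0-1 vector, `TRUE` = construction.
#' @param pred logical/0-1 vector of predicted classes.
#' @return An object of class `confusion_counts` with `TPc`, `TPnc`, `FPc`,
#'   `FPnc` (true/false positives per class; `FPc` counts samples wrongly
#'   assigned to construction, `FPnc` samples wrongly assigned to
#'   non-construction).
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.logical(truth)
  pred <- as.logical(pred)
  structure(list(TPc = sum(truth & pred),
                 TPnc = sum(!truth & !pred),
                 FPc = sum(!truth & pred),
                 FPnc = sum(truth & !pred)),
            class = "confusion_counts")
}

#' Decoding accuracy in percent
#'
#' `100 * (TPc + TPnc) / (TPc + TPnc + FPc + FPnc)`.
#'
#' @param counts a [confusion_counts()] object.
#' @return accuracy in percent.
#' @export
accuracy <- function(counts) {
  tot <- counts$TPc + counts$TPnc + counts$FPc + counts$FPnc
  if (tot == 0) stop("empty confusion counts", call. = FALSE)
  100 * (counts$TPc + counts$TPnc) / tot
}

#' F1 score for the construction class
#'
#' `2 TPc / (2 TPc + FPc + FPnc)` — the harmonic mean of precision and recall
#' for the construction class.
#'
#' @param counts a [confusion_counts()] object.
#' @return F1 in `[0, 1]`; defined as 0 (with a warning) when the denominator
#'   vanishes.
#' @export
f1_construction <- function(counts) {
  den <- 2 * counts$TPc + counts$FPc + counts$FPnc
  if (den == 0) {
    warning("no construction samples predicted or present; F1 defined as 0")
    return(0)
  }
  2 * counts$TPc / den
}

# Core nested CV on one binary problem. x: samples x channels (already
# low-pass filtered HbR, masked samples removed); y: logical.
nested_cv_core <- function(x, y, k_outer = 5L, k_inner = 5L,
                           lambda_grid = lambda_grid_default(),
                           denoise = TRUE, eigen_threshold = 0.7,
                           drop_first = TRUE) {
  n <- nrow(x)
  folds <- make_outer_folds(seq_len(n), k_outer)
  prob <- rep(NA_real_, n)
  pred <- rep(NA, n)
  lambdas <- rep(NA_real_, length(folds))
  skipped <- integer(0)
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    tr <- setdiff(seq_len(n), test)
    if (length(unique(y[tr])) < 2L) {
      skipped <- c(skipped, f)
      next
    }
    xtr <- x[tr, , drop = FALSE]
    lam <- select_lambda(xtr, y[tr], k_inner = k_inner,
                         lambda_grid = lambda_grid, denoise = denoise,
                         eigen_threshold = eigen_threshold,
                         drop_first = drop_first)
    xte <- x[test, , drop = FALSE]
    if (denoise) {
      den <- try_denoiser(xtr, eigen_threshold, drop_first)
      if (!is.null(den)) {
        xtr <- pca_denoise_apply(den, xtr)
        xte <- pca_denoise_apply(den, xte)
      }
    }
    sc <- train_scaler(xtr)
    fit <- fit_ridge_logistic(apply_scaler(sc, xtr), y[tr], lam)
    pr <- predict(fit, apply_scaler(sc, xte))
    prob[test] <- pr$probability
    pred[test] <- pr$class
    lambdas[f] <- lam
  }
  if (length(skipped) == length(folds)) {
    stop("every outer fold lacked a class", call. = FALSE)
  }
  scored <- !is.na(pred)
  counts <- confusion_counts(y[scored], pred[scored])
  structure(list(probability = prob, class = pred, truth = y,
                 counts = counts,
                 accuracy = accuracy(counts),
                 f1 = f1_construction(counts),
                 lambdas = lambdas, skipped_folds = skipped,
                 n_scored = sum(scored)),
            class = "decoding_result")
}

#' Nested cross-validated decoding of driving difficulty
#'
#' Decodes construction vs. non-construction from multichannel HbR samples
#' with L2-penalized logistic regression in a nested cross-validation: five
#' contiguous outer folds estimate out-of-fold performance; within each outer
#' training set an inner five-fold loop (with train-fold PCA denoising and
#' z-scoring) selects the ridge penalty. `mode = "per_level"` fits one model
#' per WML level; `mode = "combined"` pools all levels into one model.
#'
#' @param hemo a `hemo_series` (the HbR matrix is used) or a samples x
#'   channels HbR matrix.
#' @param labels label track with `difficulty`, `wml_level`, `valid`.
#' @param mode `"per_level"` or `"combined"`.
#' @param channels optional logical/integer channel subset (e.g. QC-retained).
#' @param k_outer,k_inner fold counts.
#' @param lambda_grid penalty grid.
#' @param denoise,eigen_threshold,drop_first PCA denoising settings.
#' @return For `"combined"`, a `decoding_result` (out-of-fold probabilities,
#'   confusion counts, accuracy %, F1). For `"per_level"`, a named list of
#'   `decoding_result`s, one per level.
#' @export
nested_cv_decode <- function(hemo, labels, mode = c("per_level", "combined"),
                             channels = NULL,
                             k_outer = 5L, k_inner = 5L,
                             lambda_grid = lambda_grid_default(),
                             denoise = TRUE, eigen_threshold = 0.7,
                             drop_first = TRUE) {
  mode <- match.arg(mode)
  x <- if (inherits(hemo, "hemo_series")) hemo$hbr else as.matrix(hemo)
  if (inherits(hemo, "hemo_series") && is.null(channels)) {
    channels <- which(hemo$channel_mask)
  }
  if (!is.null(channels)) x <- x[, channels, drop = FALSE]
  stopifnot(nrow(x) == nrow(labels))
  keep <- labels$valid
  x <- x[keep, , drop = FALSE]
  lab <- labels[keep, , drop = FALSE]
  y <- lab$difficulty == "construction"
  run <- function(sub) {
    nested_cv_core(x[sub, , drop = FALSE], y[sub], k_outer = k_outer,
                   k_inner = k_inner, lambda_grid = lambda_grid,
                   denoise = denoise, eigen_threshold = eigen_threshold,
                   drop_first = drop_first)
  }
  if (mode == "combined") {
    res <- run(seq_len(nrow(x)))
    res$model <- "combined"
    return(res)
  }
  levels_ <- sort(unique(lab$wml_level))
  out <- lapply(levels_, function(lev) {
    res <- run(which(lab$wml_level == lev))
    res$model <- sprintf("level_%d", lev)
    res
  })
  names(out) <- sprintf("level_%d", levels_)
  out
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding result [%s]: accuracy %.1f%%, F1 %.3f (%d samples)\n",
              x$model %||% "binary", x$accuracy, x$f1, x$n_scored))
  invisible(x)
}
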