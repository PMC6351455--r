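#' Pairwise condition dissimilarity matrix
#'
#' Trains a nested cross-validated decoder for every unordered pair of the
#' `2 * n_levels` experimental conditions (each WML level under construction
#' and non-construction; 45 pairings for five levels) and stores the
#' out-of-fold accuracy (as a fraction in `[0, 1]`) symmetrically. Higher
#' accuracy means the two conditions evoke more dissimilar multichannel HbR
#' patterns. The diagonal is `NA`.
#'
#' @inheritParams nested_cv_decode
#' @return A symmetric matrix of class `dissimilarity_matrix` with dimnames
#'   `0c ... 4c, 0nc ... 4nc`; empty cells produce `NA` rows/columns with a
#'   warning.
#' @export
pairwise_dissimilarity <- function(hemo, labels, channels = NULL,
                                   k_outer = 5L, k_inner = 5L,
                                   lambda_grid = lambda_grid_default(),
                                   denoise = TRUE, eigen_threshold = 0.7,
                                   drop_first = TRUE) {
  x <- if (inherits(hemo, "hemo_series")) hemo$hbr else as.matrix(hemo)
  if (inherits(hemo, "hemo_series") && is.null(channels)) {
    channels <- which(hemo$channel_mask)
  }
  if (!is.null(channels)) x <- x[, channels, drop = FALSE]
  keep <- labels$valid
  x <- x[keep, , drop = FALSE]
  lab <- labels[keep, , drop = FALSE]
  levels_ <- sort(unique(lab$wml_level))
  conds <- c(sprintf("%dc", levels_), sprintf("%dnc", levels_))
  cond_of <- sprintf("%d%s", lab$wml_level,
                     ifelse(lab$difficulty == "construction", "c", "nc"))
  m <- matrix(NA_real_, length(conds), length(conds),
              dimnames = list(conds, conds))
  empty <- conds[!(conds %in% cond_of)]
  if (length(empty) > 0) {
    warning(sprintf("empty condition cell(s): %s", paste(empty, collapse = ", ")))
  }
  pairs <- utils::combn(conds, 2L)
  for (pcol in seq_len(ncol(pairs))) {
    a <- pairs[1L, pcol]
    b <- pairs[2L, pcol]
    if (a %in% empty || b %in% empty) next
    sub <- which(cond_of %in% c(a, b))
    y <- cond_of[sub] == a
    res <- nested_cv_core(x[sub, , drop = FALSE], y, k_outer = k_outer,
                          k_inner = k_inner, lambda_grid = lambda_grid,
                          denoise = denoise,
                          eigen_threshold = eigen_threshold,
                          drop_first = drop_first)
    m[a, b] <- m[b, a] <- res$accuracy / 100
  }
  class(m) <- c("dissimilarity_matrix", class(m))
  m
}

#' Within-level vs. adjacent-level difficulty discriminability
#'
#' Summarizes a condition dissimilarity matrix: the mean decoding accuracy of
#' driving difficulty within the same WML level (pairs `lc` vs `lnc`) and for
#' adjacent WML levels (pairs `lc` vs `(l+1)nc`). Missing entries are
#' excluded with a warning.
#'
#' @param m a [pairwise_dissimilarity()] matrix.
#' @return list with `within` (per-level vector and `mean`) and `adjacent`
#'   (per-pair vector and `mean`).
#' @export
within_adjacent_summary <- function(m) {
  conds <- rownames(m)
  levs <- sort(as.integer(sub("c$|nc$", "", conds[grepl("c$", conds)])))
  levs <- unique(levs)
  within <- vapply(levs, function(l) m[sprintf("%dc", l), sprintf("%dnc", l)],
                   numeric(1))
  names(within) <- sprintf("%dc_vs_%dnc", levs, levs)
  adj_levs <- levs[-length(levs)]
  adjacent <- vapply(adj_levs, function(l) m[sprintf("%dc", l),
                                             sprintf("%dnc", l + 1L)],
                     numeric(1))
  names(adjacent) <- sprintf("%dc_vs_%dnc", adj_levs, adj_levs + 1L)
  if (anyNA(c(within, adjacent))) {
    warning("missing entries excluded from the within/adjacent means")
  }
  list(within = within, within_mean = mean(within, na.rm = TRUE),
       adjacent = adjacent, adjacent_mean = mean(adjacent, na.rm = TRUE))
}
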