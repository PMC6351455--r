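test_that("outer folds are contiguous, near-equal, and partition the samples", {
  f <- make_outer_folds(1:10, 5)
  expect_equal(lengths(f), rep(2L, 5), ignore_attr = TRUE)
  f2 <- make_outer_folds(1:11, 5)
  expect_equal(unname(lengths(f2)), c(3L, 2L, 2L, 2L, 2L))
  expect_equal(sort(unname(unlist(f2))), 1:11)
  expect_true(all(vapply(f2, function(i) all(diff(i) == 1), logical(1))))
  expect_error(make_outer_folds(1:3, 5), "folds")
})

test_that("ridge logistic matches a full-batch gradient-descent oracle", {
  set.seed(42)
  x <- matrix(rnorm(15), 5, 3)
  y <- c(0, 1, 0, 1, 1)
  lam <- 0.1
  fit <- fit_ridge_logistic(x, y, lam)
  expect_true(fit$converged)
  b <- numeric(4)
  for (i in 1:200000) {
    mu <- plogis(b[1] + drop(x %*% b[-1]))
    g <- c(mean(mu - y), drop(crossprod(x, mu - y)) / 5) + c(0, lam * b[-1])
    b <- b - 0.5 * g
  }
  expect_lt(max(abs(c(fit$intercept, fit$weights) - b)), 1e-4)
})

test_that("ridge logistic agrees with glmnet on the same objective", {
  set.seed(43)
  x <- matrix(rnorm(200), 50, 4)
  y <- rbinom(50, 1, plogis(x[, 1] - x[, 2]))
  fit <- fit_ridge_logistic(x, y, 0.05)
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 0.05,
                      standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(c(g$a0, as.numeric(g$beta)) -
                      c(fit$intercept, fit$weights))), 1e-5)
})

test_that("penalty limit shrinks weights to zero and probabilities to prevalence", {
  set.seed(44)
  x <- matrix(rnorm(300), 100, 3)
  y <- rbinom(100, 1, 0.7)
  fit <- fit_ridge_logistic(x, y, 1e8)
  expect_lt(sqrt(sum(fit$weights^2)), 1e-6)
  p <- predict(fit, x)$probability
  expect_equal(mean(p), mean(y), tolerance = 1e-3)
})

test_that("a separable toy is fit perfectly at small penalty", {
  x <- cbind(c(-2, -1.5, -1, 1, 1.5, 2), c(0.3, -0.2, 0.1, -0.1, 0.2, -0.3))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_ridge_logistic(x, y, 1e-6)
  expect_equal(mean(predict(fit, x)$class == (y == 1)), 1)
  expect_error(fit_ridge_logistic(x, rep(1, 6), 0.1), "both classes")
})

test_that("classification boundary p >= 0.5 is inclusive and monotone", {
  fit <- structure(list(intercept = 0, weights = c(0, 0), lambda = 1,
                        converged = TRUE, n_iter = 0L),
                   class = "ridge_logistic")
  pr <- predict(fit, matrix(rnorm(10), 5, 2))
  expect_true(all(pr$probability == 0.5))
  expect_true(all(pr$class))          # boundary assigned to construction
  fit$weights <- c(1, 0)
  xs <- cbind(seq(-3, 3, length.out = 20), 0)
  p <- predict(fit, xs)$probability
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("accuracy and F1 formulas match brute-force recomputation", {
  cc <- structure(list(TPc = 3, TPnc = 3, FPc = 1, FPnc = 1),
                  class = "confusion_counts")
  expect_equal(accuracy(cc), 75)
  expect_equal(f1_construction(structure(list(TPc = 5, TPnc = 0, FPc = 0,
                                              FPnc = 0),
                                         class = "confusion_counts")), 1)
  expect_equal(f1_construction(structure(list(TPc = 0, TPnc = 0, FPc = 3,
                                              FPnc = 2),
                                         class = "confusion_counts")), 0)
  expect_equal(f1_construction(structure(list(TPc = 3, TPnc = 0, FPc = 1,
                                              FPnc = 2),
                                         class = "confusion_counts")), 6 / 9)
  set.seed(45)
  for (i in 1:20) {
    truth <- rbinom(40, 1, 0.5) == 1
    pred <- rbinom(40, 1, 0.5) == 1
    if (!any(truth) || all(truth)) next
    cnt <- confusion_counts(truth, pred)
    expect_equal(cnt$TPc + cnt$TPnc + cnt$FPc + cnt$FPnc, 40)
    expect_equal(accuracy(cnt), 100 * mean(truth == pred))
    f1_brute <- {
      prec <- cnt$TPc / (cnt$TPc + cnt$FPc)
      rec <- cnt$TPc / (cnt$TPc + cnt$FPnc)
      if (cnt$TPc == 0) 0 else 2 * prec * rec / (prec + rec)
    }
    expect_equal(suppressWarnings(f1_construction(cnt)), f1_brute)
  }
  expect_equal(accuracy(structure(list(TPc = 0, TPnc = 0, FPc = 5, FPnc = 5),
                                  class = "confusion_counts")), 0)
})

test_that("lambda selection honors the grid, ties, and noise behavior", {
  set.seed(46)
  x <- matrix(rnorm(600), 200, 3)
  y <- rbinom(200, 1, 0.5)
  expect_equal(as.numeric(select_lambda(x, y, lambda_grid = 3.3)), 3.3)
  # pure noise: the strongest penalty is the modal choice and the selection
  # never systematically prefers weak penalties
  grid <- lambda_grid_default(20)
  sel <- vapply(1:20, function(i) {
    set.seed(100 + i)
    xn <- matrix(rnorm(450), 150, 3)
    yn <- rbinom(150, 1, 0.5)
    lam <- suppressWarnings(select_lambda(xn, yn, lambda_grid = grid,
                                          denoise = FALSE))
    which(grid == as.numeric(lam))
  }, integer(1))
  expect_gte(mean(sel == length(grid)), 0.5)   # strongest penalty is modal
  expect_gte(stats::median(sel), length(grid) / 2)
  # strong signal: the chosen penalty is within one standard error of the
  # best inner accuracy (the selection contract)
  xs <- matrix(rnorm(600), 200, 3)
  ys <- as.numeric(plogis(3 * xs[, 1]) > runif(200))
  lam <- suppressWarnings(select_lambda(xs, ys, lambda_grid = grid,
                                        denoise = FALSE))
  acc <- attr(lam, "mean_accuracy")
  expect_gte(acc[which(grid == as.numeric(lam))], max(acc, na.rm = TRUE) - 0.05)
})

test_that("training weights are unaffected by test-fold labels (no leakage)", {
  s <- small_session()
  lab <- s$prep$labels[s$prep$labels$valid, ]
  x <- s$prep$hemo$hbr[s$prep$labels$valid, ]
  sub <- which(lab$wml_level == 1)
  y <- lab$difficulty[sub] == "construction"
  folds <- make_outer_folds(seq_along(sub), 5)
  tr <- setdiff(seq_along(sub), folds[[1]])
  lam <- 1
  f1 <- fit_ridge_logistic(scale(x[sub[tr], ]), y[tr], lam)
  y_shuffled <- y
  y_shuffled[folds[[1]]] <- sample(y[folds[[1]]])
  f2 <- fit_ridge_logistic(scale(x[sub[tr], ]), y_shuffled[tr], lam)
  expect_identical(f1$weights, f2$weights)
})

test_that("nested CV decodes a clean synthetic session far above chance per level", {
  s <- small_session()
  res <- suppressWarnings(nested_cv_decode(s$prep$hemo, s$prep$labels,
                                           mode = "per_level"))
  expect_length(res, 5L)
  acc <- vapply(res, function(r) r$accuracy, numeric(1))
  expect_true(all(acc > 70))
  # metrics agree with brute-force recomputation from the prediction lists
  r <- res[[2]]
  scored <- !is.na(r$class)
  expect_equal(r$accuracy, 100 * mean(r$class[scored] == r$truth[scored]))
  expect_equal(r$counts$TPc + r$counts$TPnc + r$counts$FPc + r$counts$FPnc,
               r$n_scored)
})
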