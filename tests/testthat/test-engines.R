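# independent oracle: ANOVA F per feature from the textbook definition
brute_force_f <- function(X, Y) {
  apply(X, 2, function(x) {
    fit <- stats::aov(x ~ factor(Y))
    summary(fit)[[1]]$`F value`[1]
  })
}

test_that("filter_k_best matches brute-force ANOVA F ranking", {
  set.seed(11)
  X <- matrix(rnorm(30 * 5), 30, 5)
  Y <- rep(c(1, -1), 15)
  X[, 2] <- X[, 2] + Y * 1.5
  X[, 4] <- X[, 4] + Y * 0.7
  expect_equal(anova_f(X, Y), unname(brute_force_f(X, Y)), tolerance = 1e-10)
  expect_identical(filter_k_best(X, Y, 2), order(-brute_force_f(X, Y))[1:2])
  # k = p returns everything; a constant feature ranks last
  expect_setequal(filter_k_best(X, Y, 5), 1:5)
  Xc <- cbind(X, const = 5)
  expect_equal(anova_f(Xc, Y)[6], 0)
  expect_false(6 %in% filter_k_best(Xc, Y, 5))
  # scale invariance of the F ranking under feature-wise affine maps
  Xs <- sweep(sweep(X, 2, c(2, 0.1, 5, 1, 3), "*"), 2, c(1, -4, 0, 2, 7), "+")
  expect_equal(anova_f(Xs, Y), anova_f(X, Y), tolerance = 1e-8)
})

test_that("t-test selection matches the t distribution and Bonferroni rule", {
  set.seed(12)
  X <- matrix(rnorm(40 * 3), 40, 3)
  Y <- rep(c(1, -1), 20)
  X[, 1] <- X[, 1] + Y * 3 # huge shift
  p <- ttest_pvalues(X, Y)
  # oracle: stats::t.test with pooled variance
  p_oracle <- apply(X, 2, function(x) {
    stats::t.test(x[Y > 0], x[Y < 0], var.equal = TRUE)$p.value
  })
  expect_equal(p, unname(p_oracle), tolerance = 1e-12)
  expect_identical(ttest_bonferroni(X, Y, 0.001), 1L)
  # identical class means on all features -> empty set
  Y0 <- rep(c(1, -1), 20)
  Xsame <- matrix(rep(rep(1:20, each = 2), 2), 40, 2) # class means equal by construction
  expect_length(ttest_bonferroni(Xsame, Y0), 0)
  # single feature reduces to the plain t-test
  x1 <- matrix(rnorm(40), 40, 1)
  expect_equal(
    length(ttest_bonferroni(x1, Y0, 0.05)) > 0,
    stats::t.test(x1[Y0 > 0], x1[Y0 < 0], var.equal = TRUE)$p.value <= 0.05
  )
})

test_that("enet solution satisfies the KKT conditions of the printed functional", {
  set.seed(13)
  X <- scale(matrix(rnorm(25 * 40), 25, 40))
  Y <- rep(c(1, -1), length.out = 25)
  for (alpha in c(0.3, 0.7, 1)) {
    tau <- 0.15 * tau_max(X, Y, alpha)
    fit <- fit_enet(X, Y, tau, alpha, tol = 1e-10)
    beta <- fit$beta
    g <- as.numeric(2 * crossprod(X, X %*% beta - Y))
    active <- beta != 0
    if (any(active)) {
      resid <- g[active] + alpha * tau * sign(beta[active]) +
        2 * (1 - alpha) * tau * beta[active]
      expect_lt(max(abs(resid)), 1e-6)
    }
    if (any(!active)) {
      expect_true(all(abs(g[!active]) <= alpha * tau + 1e-6))
    }
  }
})

test_that("enet univariate closed form and the tau-kill bound hold", {
  set.seed(14)
  x <- matrix(rnorm(60), 60, 1)
  x <- x / sqrt(sum(x^2)) # x'x = 1
  y <- rnorm(60)
  for (alpha in c(0.25, 0.5, 1)) {
    for (tau in c(0.05, 0.4, 2)) {
      got <- unname(fit_enet(x, y, tau, alpha, tol = 1e-10)$beta)
      xy <- sum(x * y)
      soft <- sign(xy) * max(abs(xy) - alpha * tau / 2, 0)
      expect_equal(got, soft / (1 + (1 - alpha) * tau), tolerance = 1e-7)
    }
    # tau at or above 2||X'Y||_inf / alpha zeroes everything
    X <- scale(matrix(rnorm(120), 20, 6))
    Y <- rep(c(1, -1), 10)
    fit <- fit_enet(X, Y, tau_max(X, Y, alpha) * 1.0001, alpha)
    expect_identical(unname(fit$beta), rep(0, 6))
  }
})

test_that("enet LASSO solution agrees with an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(15)
  X <- matrix(rnorm(10 * 20), 10, 20)
  Y <- rnorm(10)
  tau <- 0.3
  ours <- fit_enet(X, Y, tau, alpha = 1, tol = 1e-12)$beta
  # glmnet minimizes (1/2n)||y - Xb||^2 + lambda ||b||_1
  # our ||Xb - y||^2 + tau ||b||_1 matches at lambda = tau / (2n)
  g <- glmnet::glmnet(X, Y,
    alpha = 1, lambda = tau / (2 * nrow(X)),
    intercept = FALSE, standardize = FALSE, thresh = 1e-16
  )
  expect_equal(unname(ours), as.numeric(g$beta), tolerance = 1e-6)
})

test_that("objective trace is monotone non-increasing", {
  set.seed(16)
  X <- scale(matrix(rnorm(40 * 30), 40, 30))
  Y <- rep(c(1, -1), 20)
  fit <- fit_enet(X, Y, 0.05 * tau_max(X, Y), alpha = 0.5)
  expect_true(all(diff(fit$obj_trace) <= 1e-12))
})

test_that("classifiers obey their basic contracts", {
  set.seed(17)
  n <- 30
  X <- matrix(rnorm(n * 4), n, 4)
  Y <- rep(c(1, -1), 15)
  X[, 1] <- X[, 1] + 3 * Y # separable direction

  # kNN with k = 1 has zero training error
  knn1 <- train_classifier(classifier_knn(k = 1), X, Y)
  expect_equal(mean(knn1(X) != Y), 0)
  # separable data: linear SVM training error 0
  svm_fit <- train_classifier("lsvm", X, Y)
  expect_equal(mean(svm_fit(X) != Y), 0)
  # ridge -> OLS as lambda -> 0 on full-rank tall X
  ols <- train_classifier("ols", X, Y)
  rls <- train_classifier(classifier_rls(lambda = 1e-10), X, Y)
  Xnew <- matrix(rnorm(20 * 4), 20, 4)
  expect_identical(ols(Xnew), rls(Xnew))
  # OLS refuses p > n and points to ridge
  Xwide <- matrix(rnorm(10 * 15), 10, 15)
  expect_error(
    train_classifier("ols", Xwide, rep(c(1, -1), 5)),
    "rls"
  )
  # majority baseline predicts the larger training class
  maj <- train_classifier(classifier_majority(), X, c(rep(1, 20), rep(-1, 10)))
  expect_identical(unique(maj(Xnew)), 1)
})

test_that("ridge predictor coefficients match the closed-form normal equations", {
  set.seed(18)
  X <- matrix(rnorm(50 * 3), 50, 3)
  Y <- rep(c(1, -1), 25)
  lambda <- 2.5
  # oracle: direct solve of (X'X + lambda I) b = X'(y - ybar)
  b <- solve(crossprod(X) + diag(lambda, 3), crossprod(X, Y - mean(Y)))
  pred <- train_classifier(classifier_rls(lambda = lambda), X, Y)
  Xnew <- matrix(rnorm(30 * 3), 30, 3)
  expect_identical(pred(Xnew), ifelse(Xnew %*% b + mean(Y) >= 0, 1, -1)[, 1])
})
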