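#' Elastic-net (l1l2) fit of the regression functional
#'
#' Minimizes, by a monotone accelerated proximal-gradient method,
#'
#' \deqn{\|X\beta - Y\|_2^2 + \alpha\tau \|\beta\|_1 + (1-\alpha)\tau \|\beta\|_2^2}
#'
#' over the coefficient vector. `alpha = 1` is the LASSO special case
#' \eqn{\|X\beta-Y\|_2^2 + \tau\|\beta\|_1}. The selected variables are the
#' nonzero components of the minimizer. `X` is expected to be
#' column-standardized on the training data by the caller (the cross-
#' validation driver does this); the solver itself fits exactly what it is
#' given.
#'
#' @param X Numeric n x p matrix (samples in rows).
#' @param Y Numeric response, typically the +1/-1 labels.
#' @param tau Regularization weight, >= 0.
#' @param alpha l1 share in (0, 1]; 1 = LASSO.
#' @param beta0 Warm-start coefficients (default zeros).
#' @param max_iter Iteration cap.
#' @param tol Stopping tolerance on the maximum KKT violation, relative to
#'   the gradient scale `max(1, 2 max|X'Y|)` of the problem.
#' @param lip Optional precomputed `2 * sigma_max(X)^2`, reused along a tau
#'   path.
#' @return An object of class `enet_fit`: `beta` (named), `selected`
#'   (feature names with nonzero beta), `tau`, `alpha`, `iterations`,
#'   `kkt_gap`, `objective`, `obj_trace`, `lip`.
#' @examples
#' X <- scale(matrix(rnorm(200), 20, 10))
#' y <- rep(c(1, -1), 10)
#' fit <- fit_enet(X, y, tau = 1, alpha = 0.5)
#' fit$selected
#' @export
fit_enet <- function(X, Y, tau, alpha = 1, beta0 = NULL,
                     max_iter = 50000L, tol = 1e-7, lip = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(tau >= 0, alpha > 0, alpha <= 1)
  if (is.null(beta0)) beta0 <- numeric(ncol(X))
  if (is.null(lip)) lip <- 2 * spectral_sq_cpp(X)
  grad_scale <- max(1, 2 * max(abs(crossprod(X, as.numeric(Y)))))
  res <- enet_solve_cpp(
    X, as.numeric(Y), tau, alpha, as.numeric(beta0),
    lip, as.integer(max_iter), tol * grad_scale
  )
  if (!res$converged) {
    abort(sprintf(
      "elastic-net solver did not converge in %d iterations (KKT gap %.3g > tol %.3g)",
      max_iter, res$kkt_gap, tol
    ))
  }
  beta <- setNames(as.numeric(res$beta), colnames(X))
  structure(
    list(
      beta = beta, selected = names(beta)[beta != 0],
      tau = tau, alpha = alpha,
      iterations = res$iterations, kkt_gap = res$kkt_gap,
      objective = res$objective, obj_trace = as.numeric(res$obj_trace),
      lip = res$lip_base
    ),
    class = "enet_fit"
  )
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf(
    "<enet_fit> tau = %.4g, alpha = %.2f: %d/%d nonzero (KKT gap %.2g, %d iter)\n",
    x$tau, x$alpha, length(x$selected), length(x$beta), x$kkt_gap, x$iterations
  ))
  invisible(x)
}

#' @export
tidy.enet_fit <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta), selected = x$beta != 0)
}

#' @export
glance.enet_fit <- function(x, ...) {
  tibble(
    tau = x$tau, alpha = x$alpha, n_selected = length(x$selected),
    objective = x$objective, kkt_gap = x$kkt_gap, iterations = x$iterations
  )
}

#' Smallest tau that zeroes every coefficient
#'
#' At `tau >= 2 * max|X'Y| / alpha` the zero vector satisfies the optimality
#' conditions of the l1l2 functional, so the solution is identically zero.
#'
#' @inheritParams fit_enet
#' @return A scalar.
#' @export
tau_max <- function(X, Y, alpha = 1) {
  2 * max(abs(crossprod(as.matrix(X), as.numeric(Y)))) / alpha
}

#' One-way ANOVA F statistics per feature
#'
#' @param X n x p matrix (samples in rows).
#' @param Y +1/-1 class labels.
#' @return Numeric vector of F values; a feature with zero within-class
#'   variance gets `Inf` when the class means differ and 0 otherwise.
#' @export
anova_f <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.numeric(Y)
  n <- nrow(X)
  idx1 <- Y > 0
  n1 <- sum(idx1)
  n2 <- n - n1
  m1 <- colMeans(X[idx1, , drop = FALSE])
  m2 <- colMeans(X[!idx1, , drop = FALSE])
  m <- colMeans(X)
  ss_between <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ss_within <- colSums((t(t(X[idx1, , drop = FALSE]) - m1))^2) +
    colSums((t(t(X[!idx1, , drop = FALSE]) - m2))^2)
  f <- (ss_between / 1) / (ss_within / (n - 2))
  f[ss_within == 0 & ss_between > 0] <- Inf
  f[ss_within == 0 & ss_between == 0] <- 0
  unname(f)
}

#' Top-k features by one-way ANOVA F
#'
#' Ranks features by the F statistic of a one-way ANOVA between the two
#' classes and returns the `k` largest; ties are broken toward the smaller
#' feature index.
#'
#' @inheritParams anova_f
#' @param k Number of features to keep (`k <= p`).
#' @return Integer indices of the selected features, in rank order.
#' @export
filter_k_best <- function(X, Y, k) {
  p <- ncol(as.matrix(X))
  if (k < 1 || k > p) abort(sprintf("k must be in 1..%d", p))
  f <- anova_f(X, Y)
  order(-f, seq_along(f))[seq_len(k)]
}

#' Bonferroni-corrected two-sample t-test selection
#'
#' Per-feature pooled-variance two-sample t-test; a feature is selected when
#' its p-value times the number of features is at most `level`.
#'
#' @inheritParams anova_f
#' @param level Family-wise significance level (default 0.05).
#' @return Integer indices of selected features.
#' @export
ttest_bonferroni <- function(X, Y, level = 0.05) {
  which(ttest_pvalues(X, Y) * ncol(as.matrix(X)) <= level)
}

#' Per-feature two-sample t-test p-values
#'
#' @inheritParams anova_f
#' @return Numeric vector of two-sided p-values (pooled variance). Features
#'   with zero pooled variance get p = 0 when the class means differ and
#'   p = 1 otherwise.
#' @export
ttest_pvalues <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.numeric(Y)
  idx1 <- Y > 0
  n1 <- sum(idx1)
  n2 <- sum(!idx1)
  if (n1 < 2 || n2 < 2) abort("need at least two samples per class")
  m1 <- colMeans(X[idx1, , drop = FALSE])
  m2 <- colMeans(X[!idx1, , drop = FALSE])
  v1 <- apply(X[idx1, , drop = FALSE], 2, var)
  v2 <- apply(X[!idx1, , drop = FALSE], 2, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
  p[se == 0 & m1 != m2] <- 0
  p[se == 0 & m1 == m2] <- 1
  unname(p)
}

# ---- selector specifications -------------------------------------------------
# A selector spec carries a hyperparameter grid (ordered strongest-first so
# that ties in internal CV resolve toward stronger regularization) and a
# fit function (X_std, Y, params, cache) -> list(selected = int indices,
# model = optional fitted object usable for prediction).

new_selector <- function(method, grid, fit, uses_model = FALSE) {
  structure(list(method = method, grid = grid, fit = fit, uses_model = uses_model),
    class = "kdvs_selector"
  )
}

#' @export
print.kdvs_selector <- function(x, ...) {
  cat(sprintf(
    "<selector:%s> %d hyperparameter setting(s)\n", x$method,
    length(x$grid)
  ))
  invisible(x)
}

#' Selector specifications
#'
#' Constructors for the variable-selection engines used inside nested
#' cross-validation. Each carries its hyperparameter grid; the grids are
#' ordered from stronger to weaker regularization so that internal-CV ties
#' resolve toward the sparser model.
#'
#' * `selector_enet()` -- nonzero coefficients of the l1l2 functional; grid
#'   over `tau` (geometric, from `tau_max` down `decades` decades) crossed
#'   with `alpha`.
#' * `selector_lasso()` -- `selector_enet()` with `alpha = 1`.
#' * `selector_filter_k_best()` -- top-k ANOVA F filter, grid over `k`.
#' * `selector_ttest()` -- Bonferroni-corrected t-test at `level` (no grid).
#' * `selector_all()` -- keeps every feature (degenerate baseline).
#'
#' @param alpha l1 share values in (0, 1].
#' @param n_tau Points on the geometric tau grid.
#' @param decades Span of the tau grid below `tau_max`.
#' @param tol Relative KKT tolerance passed to [fit_enet()]; the default
#'   1e-4 is selection-level accuracy (the nonzero pattern is already
#'   stable there), keeping repeated CV fits cheap.
#' @param k Candidate top-k values.
#' @param level Significance level for the t-test selector.
#' @return A selector specification for [nested_cv()].
#' @name selectors
NULL

#' @rdname selectors
#' @export
selector_enet <- function(alpha = c(0.1, 0.5, 0.9, 1.0), n_tau = 20, decades = 4,
                          tol = 1e-4) {
  ratios <- 10^seq(0, -decades, length.out = n_tau)
  grid <- list()
  for (a in sort(alpha, decreasing = TRUE)) {
    for (r in ratios) {
      grid[[length(grid) + 1L]] <- list(tau_ratio = r, alpha = a)
    }
  }
  # order strongest-first: largest tau_ratio first within alpha, alpha
  # order secondary (sparser = larger alpha first)
  ord <- order(
    -vapply(grid, `[[`, numeric(1), "tau_ratio"),
    -vapply(grid, `[[`, numeric(1), "alpha")
  )
  grid <- grid[ord]
  fit <- function(X, Y, params, cache) {
    tmax <- cache$tau_max
    tau <- params$tau_ratio * tmax
    key <- sprintf("a%.6f", params$alpha)
    warm <- cache$warm[[key]]
    f <- fit_enet(X, Y,
      tau = tau, alpha = params$alpha,
      beta0 = warm, lip = cache$lip, tol = tol
    )
    cache$warm[[key]] <- f$beta
    list(selected = which(f$beta != 0), model = f)
  }
  new_selector("enet", grid, fit, uses_model = TRUE)
}

#' @rdname selectors
#' @export
selector_lasso <- function(n_tau = 20, decades = 4, tol = 1e-4) {
  s <- selector_enet(alpha = 1, n_tau = n_tau, decades = decades, tol = tol)
  s$method <- "lasso"
  s
}

#' @rdname selectors
#' @export
selector_filter_k_best <- function(k = c(10, 50, 100)) {
  grid <- lapply(sort(k), function(kk) list(k = kk))
  fit <- function(X, Y, params, cache) {
    list(selected = filter_k_best(X, Y, min(params$k, ncol(X))), model = NULL)
  }
  new_selector("filter_k_best", grid, fit)
}

#' @rdname selectors
#' @export
selector_ttest <- function(level = 0.05) {
  fit <- function(X, Y, params, cache) {
    list(selected = ttest_bonferroni(X, Y, level = params$level), model = NULL)
  }
  new_selector("ttest_bonferroni", list(list(level = level)), fit)
}

#' @rdname selectors
#' @export
selector_all <- function() {
  fit <- function(X, Y, params, cache) {
    list(selected = seq_len(ncol(X)), model = NULL)
  }
  new_selector("all", list(list()), fit)
}

# ---- classifier specifications ----------------------------------------------
# A classifier spec: grid (strongest regularization first) and
# train(X_std, Y, params) -> predictor closure(Xnew_std) -> +1/-1.

new_classifier <- function(name, grid, train) {
  structure(list(name = name, grid = grid, train = train),
    class = "kdvs_classifier"
  )
}

#' @export
print.kdvs_classifier <- function(x, ...) {
  cat(sprintf(
    "<classifier:%s> %d hyperparameter setting(s)\n", x$name, length(x$grid)
  ))
  invisible(x)
}

#' Classifier specifications
#'
#' Constructors for the classification engines paired with a selector in
#' nested cross-validation. All operate on the selected feature columns of
#' the (training-standardized) matrix; linear methods predict by the sign of
#' the linear score.
#'
#' * `classifier_knn()` -- k-nearest neighbours (Euclidean), grid over `k`
#'   (larger k first: smoother model preferred on ties).
#' * `classifier_lr()` -- logistic regression, class = sign of the logit.
#' * `classifier_lsvm()` -- linear support vector machine (`e1071::svm`),
#'   grid over `cost` (smaller cost first).
#' * `classifier_ols()` -- ordinary least squares on the +1/-1 response;
#'   errors when p > n, directing to `classifier_rls()`.
#' * `classifier_rls()` -- ridge (regularized least squares), grid over
#'   `lambda` (larger first).
#' * `classifier_model()` -- reuses the selector's own fitted linear model
#'   (the l1l2 coefficients): prediction is the sign of `X beta` plus the
#'   training-label mean offset. Only valid with `selector_enet()` /
#'   `selector_lasso()`.
#' * `classifier_majority()` -- constant majority-class predictor
#'   (baseline).
#'
#' @param k Neighbour counts for kNN.
#' @param cost LSVM cost values.
#' @param lambda Ridge weights.
#' @return A classifier specification for [nested_cv()].
#' @name classifiers
NULL

#' @rdname classifiers
#' @export
classifier_knn <- function(k = c(1, 3, 5, 7)) {
  grid <- lapply(sort(k, decreasing = TRUE), function(kk) list(k = kk))
  train <- function(X, Y, params, model = NULL) {
    k_use <- min(params$k, nrow(X))
    Xtr <- X
    Ytr <- Y
    function(Xnew) {
      cl <- class::knn(Xtr, Xnew, factor(Ytr, levels = c(-1, 1)),
        k = k_use, use.all = TRUE
      )
      as.numeric(as.character(cl))
    }
  }
  new_classifier("knn", grid, train)
}

#' @rdname classifiers
#' @export
classifier_lr <- function() {
  train <- function(X, Y, params, model = NULL) {
    y01 <- as.integer(Y > 0)
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y01,
      family = stats::binomial()
    ))
    coefs <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    function(Xnew) ifelse(cbind(1, Xnew) %*% coefs > 0, 1, -1)[, 1]
  }
  new_classifier("lr", list(list()), train)
}

#' @rdname classifiers
#' @export
classifier_lsvm <- function(cost = 1) {
  grid <- lapply(sort(cost), function(cc) list(cost = cc))
  train <- function(X, Y, params, model = NULL) {
    fit <- e1071::svm(X, factor(Y, levels = c(-1, 1)),
      kernel = "linear", cost = params$cost, scale = FALSE
    )
    function(Xnew) as.numeric(as.character(predict(fit, Xnew)))
  }
  new_classifier("lsvm", grid, train)
}

#' @rdname classifiers
#' @export
classifier_ols <- function() {
  train <- function(X, Y, params, model = NULL) {
    if (ncol(X) > nrow(X)) {
      abort("OLS needs p <= n; use classifier_rls() (ridge) instead")
    }
    linear_ls_predictor(X, Y, lambda = 0)
  }
  new_classifier("ols", list(list()), train)
}

#' @rdname classifiers
#' @export
classifier_rls <- function(lambda = 10^seq(2, -2, length.out = 5)) {
  grid <- lapply(sort(lambda, decreasing = TRUE), function(l) list(lambda = l))
  train <- function(X, Y, params, model = NULL) {
    linear_ls_predictor(X, Y, lambda = params$lambda)
  }
  new_classifier("rls", grid, train)
}

linear_ls_predictor <- function(X, Y, lambda) {
  # min ||Xb - yc||^2 + lambda ||b||^2 on centred response; sign score + ybar
  ybar <- mean(Y)
  A <- crossprod(X) + diag(lambda, ncol(X))
  b <- tryCatch(solve(A, crossprod(X, Y - ybar)), error = function(e) {
    abort("normal equations singular; use classifier_rls() with lambda > 0")
  })
  function(Xnew) ifelse(Xnew %*% b + ybar >= 0, 1, -1)[, 1]
}

#' @rdname classifiers
#' @export
classifier_model <- function() {
  train <- function(X, Y, params, model = NULL) {
    if (is.null(model)) {
      abort("classifier_model() requires a coefficient-based selector (enet/lasso)")
    }
    beta <- model$beta
    ybar <- mean(Y)
    function(Xnew) ifelse(Xnew %*% beta + ybar >= 0, 1, -1)[, 1]
  }
  new_classifier("model", list(list()), train)
}

#' @rdname classifiers
#' @export
classifier_majority <- function() {
  train <- function(X, Y, params, model = NULL) {
    maj <- if (sum(Y > 0) >= sum(Y < 0)) 1 else -1
    function(Xnew) rep(maj, nrow(Xnew))
  }
  new_classifier("majority", list(list()), train)
}

#' Train a classifier outside cross-validation
#'
#' Convenience wrapper fitting one classifier specification (first grid
#' entry unless `params` given) on a full training set.
#'
#' @param classifier A classifier specification, or its name
#'   (`"knn"`, `"lr"`, `"lsvm"`, `"ols"`, `"rls"`).
#' @param X n x p training matrix.
#' @param Y +1/-1 labels.
#' @param params Optional named list of hyperparameters.
#' @return A predictor function mapping a matrix of rows to +1/-1 labels.
#' @export
train_classifier <- function(classifier, X, Y, params = NULL) {
  if (is.character(classifier)) {
    classifier <- switch(classifier,
      knn = classifier_knn(), lr = classifier_lr(), lsvm = classifier_lsvm(),
      ols = classifier_ols(), rls = classifier_rls(),
      abort(sprintf("unknown classifier '%s'", classifier))
    )
  }
  X <- as.matrix(X)
  Y <- as.numeric(Y)
  if (!nrow(X) || length(unique(Y)) < 2L) {
    abort("training data must be nonempty with both classes present")
  }
  if (is.null(params)) params <- classifier$grid[[1]]
  classifier$train(X, Y, params)
}
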