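#' Cross-validation configuration
#'
#' The unbiased two-nested scheme: the data are split into `B` stratified
#' chunks (external split); for each external split the remaining `B - 1`
#' chunks are tuned by `B - 1`-fold internal cross-validation, the winning
#' model is refit on all training chunks and scored on the held-out chunk.
#' The aggregate signature keeps the features appearing in at least
#' `frequency_cutoff` of the `B` per-split lists.
#'
#' @param B External chunk count (default 9, giving 8-fold internal CV).
#' @param frequency_cutoff Minimum number of external lists a feature must
#'   appear in; the default is the 50% majority `floor(B/2) + 1`, i.e.
#'   5-out-of-9 at the default `B`.
#' @param seed Integer seed driving the split assignment.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(B = 9, frequency_cutoff = NULL, seed = 1) {
  B <- as.integer(B)
  if (is.null(frequency_cutoff)) frequency_cutoff <- B %/% 2L + 1L
  frequency_cutoff <- as.integer(frequency_cutoff)
  if (B < 2L) abort("B must be at least 2")
  if (frequency_cutoff < 1L || frequency_cutoff > B) {
    abort("frequency_cutoff must lie in 1..B")
  }
  structure(list(B = B, frequency_cutoff = frequency_cutoff, seed = as.integer(seed)),
    class = "cv_config"
  )
}

# Stratified chunk assignment: within each class, shuffle then deal
# round-robin, so every chunk holds both classes whenever counts allow.
stratified_chunks <- function(labels, B) {
  chunk <- integer(length(labels))
  for (cl in c(-1, 1)) {
    idx <- sample(which(labels == cl))
    chunk[idx] <- rep_len(seq_len(B), length(idx))
  }
  chunk
}

standardize_train <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(
    X = sweep(sweep(X, 2, mu), 2, sdv, "/"),
    center = mu, scale = sdv
  )
}

apply_standardization <- function(X, std) {
  sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}

selector_cache <- function(X, Y, selector) {
  cache <- new.env(parent = emptyenv())
  if (selector$method %in% c("enet", "lasso")) {
    cache$tau_max <- tau_max(X, Y, alpha = 1)
    cache$lip <- 2 * spectral_sq_cpp(X)
    cache$warm <- list()
  }
  cache
}

fit_combo <- function(Xtr, Ytr, selector, classifier, sel_params, cls_params,
                      cache = NULL) {
  if (is.null(cache)) cache <- selector_cache(Xtr, Ytr, selector)
  sel <- selector$fit(Xtr, Ytr, sel_params, cache)
  if (!length(sel$selected)) {
    # empty selection: fall back to the majority-class predictor
    maj <- if (sum(Ytr > 0) >= sum(Ytr < 0)) 1 else -1
    return(list(
      selected = integer(0),
      predict = function(Xnew) rep(maj, nrow(Xnew))
    ))
  }
  if (classifier$name == "model") {
    pred <- classifier$train(Xtr, Ytr, cls_params, model = sel$model)
    return(list(selected = sel$selected, predict = pred))
  }
  Xsel <- Xtr[, sel$selected, drop = FALSE]
  pred_sel <- classifier$train(Xsel, Ytr, cls_params, model = sel$model)
  list(
    selected = sel$selected,
    predict = function(Xnew) pred_sel(Xnew[, sel$selected, drop = FALSE])
  )
}

#' Two-nested cross-validation of a selector/classifier pipeline
#'
#' For each of the `B` external splits, hyperparameters (the cross of the
#' selector and classifier grids) are chosen by internal `B - 1`-fold
#' cross-validation on the training portion only; the winning combination is
#' refit on the whole training portion and scored on the held-out chunk.
#' Standardization (center/unit variance) is computed on each training set
#' and applied to its test set, so no held-out sample influences selection
#' or fitting. Ties in internal CV resolve toward the earlier grid entry,
#' i.e. the more strongly regularized model.
#'
#' @param dataset An [expr_dataset()].
#' @param selector A selector specification (see [selectors]).
#' @param classifier A classifier specification (see [classifiers]).
#' @param config A [cv_config()].
#' @param chunks Optional integer vector in `1..B`, one per sample, fixing
#'   the external chunk assignment (defaults to a seeded stratified split).
#' @return An object of class `cv_result`: `splits` (tibble with one row per
#'   external split: `split`, `test_error`, `n_test`, `selected` list-column
#'   of probeset ids, `hyperparams` list-column), `error_mean`, `error_sd`,
#'   `aggregate` (tibble from [aggregate_by_frequency()]), `signature`
#'   (character vector), `confusion` (pooled test-prediction counts), and
#'   the configuration used.
#' @export
nested_cv <- function(dataset, selector, classifier, config = cv_config(),
                      chunks = NULL) {
  X_all <- t(dataset$values) # samples x features
  Y_all <- unname(dataset$labels)
  B <- config$B
  if (nrow(X_all) < B) abort("need at least B samples")
  set.seed(config$seed)
  chunk <- if (is.null(chunks)) {
    stratified_chunks(Y_all, B)
  } else {
    stopifnot(length(chunks) == length(Y_all), all(chunks %in% seq_len(B)))
    as.integer(chunks)
  }
  if (any(tabulate(chunk[Y_all > 0], B) == 0) ||
    any(tabulate(chunk[Y_all < 0], B) == 0)) {
    abort("an external chunk contains a single class; use a smaller B")
  }

  combos <- expand_combos(selector, classifier)
  splits <- vector("list", B)
  conf <- c(TP = 0, FP = 0, TN = 0, FN = 0)

  for (b in seq_len(B)) {
    test_idx <- which(chunk == b)
    train_idx <- which(chunk != b)
    Xtr_raw <- X_all[train_idx, , drop = FALSE]
    Ytr <- Y_all[train_idx]
    inner_chunk <- chunk[train_idx] # the other B-1 chunks ARE the inner folds
    inner_ids <- sort(unique(inner_chunk))

    inner_err <- matrix(NA_real_, length(combos), length(inner_ids))
    for (fi in seq_along(inner_ids)) {
      f <- inner_ids[fi]
      itr <- inner_chunk != f
      std <- standardize_train(Xtr_raw[itr, , drop = FALSE])
      Xi <- std$X
      Yi <- Ytr[itr]
      Xv <- apply_standardization(Xtr_raw[!itr, , drop = FALSE], std)
      Yv <- Ytr[!itr]
      cache <- selector_cache(Xi, Yi, selector)
      for (ci in seq_along(combos)) {
        cmb <- combos[[ci]]
        fitted <- fit_combo(Xi, Yi, selector, classifier, cmb$sel, cmb$cls, cache)
        inner_err[ci, fi] <- mean(fitted$predict(Xv) != Yv)
      }
    }
    mean_inner <- rowMeans(inner_err)
    best <- which.min(mean_inner) # first minimum = strongest regularization

    std <- standardize_train(Xtr_raw)
    Xtr <- std$X
    Xte <- apply_standardization(X_all[test_idx, , drop = FALSE], std)
    Yte <- Y_all[test_idx]
    fitted <- fit_combo(Xtr, Ytr, selector, classifier,
      combos[[best]]$sel, combos[[best]]$cls)
    pred <- fitted$predict(Xte)
    conf["TP"] <- conf["TP"] + sum(pred == 1 & Yte == 1)
    conf["TN"] <- conf["TN"] + sum(pred == -1 & Yte == -1)
    conf["FP"] <- conf["FP"] + sum(pred == 1 & Yte == -1)
    conf["FN"] <- conf["FN"] + sum(pred == -1 & Yte == 1)
    splits[[b]] <- tibble(
      split = b,
      test_error = mean(pred != Yte),
      n_test = length(test_idx),
      selected = list(colnames(X_all)[fitted$selected]),
      hyperparams = list(c(combos[[best]]$sel, combos[[best]]$cls))
    )
  }
  splits <- bind_rows(splits)
  aggregate <- aggregate_by_frequency(splits$selected, config$frequency_cutoff)
  structure(
    list(
      splits = splits,
      error_mean = mean(splits$test_error),
      error_sd = sd(splits$test_error),
      aggregate = aggregate,
      signature = aggregate$feature,
      confusion = confusion_counts(conf["TP"], conf["FP"], conf["TN"], conf["FN"]),
      chunks = chunk,
      config = config,
      selector = selector$method, classifier = classifier$name
    ),
    class = "cv_result"
  )
}

expand_combos <- function(selector, classifier) {
  out <- list()
  for (s in selector$grid) {
    for (cl in classifier$grid) {
      out[[length(out) + 1L]] <- list(sel = s, cls = cl)
    }
  }
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s + %s, B = %d: test error %.1f%% +/- %.1f%%, %d feature(s) at cutoff %d/%d\n",
    x$selector, x$classifier, x$config$B, 100 * x$error_mean,
    100 * x$error_sd, length(x$signature), x$config$frequency_cutoff, x$config$B
  ))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) {
  mutate(x$splits, n_selected = lengths(.data$selected))
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble(
    selector = x$selector, classifier = x$classifier, B = x$config$B,
    error_mean = x$error_mean, error_sd = x$error_sd,
    n_signature = length(x$signature),
    mcc = mcc(x$confusion)
  )
}

#' Frequency-based aggregation of per-split feature lists
#'
#' A feature enters the aggregate list when it occurs in at least `cutoff`
#' of the `B` per-split selections; the output is ordered by occurrence
#' count (descending) then by feature identifier (ascending), so it is
#' deterministic.
#'
#' @param split_lists List of character vectors (or integer vectors), one
#'   per external split.
#' @param cutoff Minimum occurrence count, in `1..B`.
#' @return A tibble with columns `feature` and `count`, filtered to
#'   `count >= cutoff`.
#' @export
aggregate_by_frequency <- function(split_lists, cutoff) {
  if (cutoff < 1 || cutoff > length(split_lists)) {
    abort("cutoff must lie in 1..B")
  }
  universe <- unique(unlist(split_lists))
  if (!length(universe)) {
    return(tibble(feature = character(), count = integer()))
  }
  counts <- rowSums(vapply(
    split_lists, function(l) universe %in% l,
    logical(length(universe))
  ))
  out <- tibble(feature = universe, count = as.integer(counts))
  out <- arrange(out, desc(.data$count), .data$feature)
  filter(out, .data$count >= cutoff)
}

#' Confusion counts
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return A named numeric vector of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = as.numeric(TP), FP = as.numeric(FP), TN = as.numeric(TN), FN = as.numeric(FN))
  if (any(v < 0)) abort("confusion counts must be non-negative")
  structure(v, class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \times TN - FP \times FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#'
#' ranges in \[-1, +1\]; by convention the score is 0 whenever a factor of
#' the denominator vanishes.
#'
#' @param counts A [confusion_counts()] vector (or anything with named
#'   elements TP, FP, TN, FN).
#' @return A scalar in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- counts[["TP"]]
  fp <- counts[["FP"]]
  tn <- counts[["TN"]]
  fn <- counts[["FN"]]
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(denom)
}
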