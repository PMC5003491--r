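#' Build per-term expression submatrices
#'
#' Local integration: for every term of the knowledge map, collect the rows
#' of the expression matrix belonging to its probesets. A term mapping to
#' fewer than `min_size` probesets is emitted with status `skipped_small`
#' and takes no further part in feature selection; probesets unknown to the
#' dataset are dropped with a warning. By construction the overlap of any
#' two submatrices equals the probeset overlap of their terms.
#'
#' @param dataset An [expr_dataset()].
#' @param km A [build_knowledge_map()] result.
#' @param min_size Minimum probeset count for a term to be processed
#'   (default 6: terms with ps < 6 are skipped).
#' @return A tibble with one row per mapped term: `term_id`, `domain`, `ps`,
#'   `status` (`"processed"`/`"skipped_small"`), and a `probesets`
#'   list-column.
#' @export
build_submatrices <- function(dataset, km, min_size = 6) {
  known <- rownames(dataset$values)
  map <- km$map
  missing <- setdiff(unique(map$probeset_id), known)
  if (length(missing)) {
    warn(sprintf(
      "%d mapped probeset(s) absent from the dataset were dropped",
      length(missing)
    ))
    map <- filter(map, .data$probeset_id %in% known)
  }
  out <- summarise(group_by(map, .data$term_id, .data$domain),
    probesets = list(sort(.data$probeset_id)), .groups = "drop"
  )
  out <- mutate(out,
    ps = lengths(.data$probesets),
    status = ifelse(.data$ps < min_size, "skipped_small", "processed")
  )
  arrange(
    out[, c("term_id", "domain", "ps", "status", "probesets")],
    .data$term_id
  )
}

# Per-term seed derived from (global seed, term id) so term results do not
# depend on execution order. Plain polynomial string hash, kept below 2^31.
term_seed <- function(seed, term_id) {
  h <- 0
  for (code in utf8ToInt(term_id)) h <- (h * 131 + code) %% 2147480009
  as.integer((h + as.numeric(seed)) %% 2147480009)
}

#' Knowledge retrieval: per-term cross-validated feature selection
#'
#' Runs an independent [nested_cv()] on every processed term submatrix
#' (default engine: l1l2 selection with prediction by the fitted linear
#' model), recording the mean and SD of the test error over the external
#' splits and the frequency-aggregated selection. Each term uses a random
#' stream derived from (`config$seed`, term id), so results are identical
#' regardless of the order in which terms are processed, and one term's
#' failure does not abort the others.
#'
#' @param dataset An [expr_dataset()].
#' @param submatrices Output of [build_submatrices()].
#' @param config A [cv_config()].
#' @param selector,classifier Engine specifications; defaults are
#'   `selector_enet(alpha = 0.5, n_tau = 8, decades = 2)` and
#'   [classifier_model()] (see the package vignette for the rationale of
#'   the leaner per-term grid).
#' @param annotation Optional [platform_annotation()] used to attach gene
#'   symbols to the selected probesets.
#' @return A tibble of term results: `term_id`, `domain`, `ps`, `status`
#'   (`processed`, `skipped_small` or `failed`), `error_mean`, `error_sd`,
#'   list-columns `selected` (probesets past the frequency cutoff) and
#'   `selected_genes`.
#' @export
knowledge_retrieval <- function(dataset, submatrices, config = cv_config(),
                                selector = NULL, classifier = NULL,
                                annotation = NULL) {
  if (is.null(selector)) selector <- selector_enet(alpha = 0.5, n_tau = 8, decades = 2)
  if (is.null(classifier)) classifier <- classifier_model()
  rows <- vector("list", nrow(submatrices))
  for (i in seq_len(nrow(submatrices))) {
    row <- submatrices[i, ]
    if (row$status != "processed") {
      rows[[i]] <- mutate(row,
        error_mean = NA_real_, error_sd = NA_real_,
        selected = list(character()), selected_genes = list(character())
      )
      next
    }
    sub <- expr_dataset(
      dataset$values[row$probesets[[1]], , drop = FALSE],
      unname(dataset$labels)
    )
    cfg <- config
    cfg$seed <- term_seed(config$seed, row$term_id)
    res <- tryCatch(
      nested_cv(sub, selector, classifier, cfg),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      rows[[i]] <- mutate(row,
        status = "failed",
        error_mean = NA_real_, error_sd = NA_real_,
        selected = list(character()), selected_genes = list(character())
      )
      next
    }
    sel <- res$signature
    genes <- if (!is.null(annotation)) {
      sort(unique(annotation$gene_symbol[annotation$probeset_id %in% sel]))
    } else {
      character()
    }
    rows[[i]] <- mutate(row,
      error_mean = res$error_mean, error_sd = res$error_sd,
      selected = list(sel), selected_genes = list(genes)
    )
  }
  bind_rows(rows)
}

#' Error threshold from a reference run
#'
#' The retention threshold is the reference pipeline's mean test error plus
#' its standard deviation; e.g. a reference error of 23.1% with SD 8.6%
#' gives a 31.7% threshold.
#'
#' @param reference_mean,reference_sd Non-negative scalars (same units).
#' @return `reference_mean + reference_sd`.
#' @export
compute_threshold <- function(reference_mean, reference_sd) {
  if (reference_mean < 0 || reference_sd < 0) {
    abort("mean and SD must be non-negative")
  }
  reference_mean + reference_sd
}

#' Post-process term results by classification error
#'
#' Retains the processed terms whose mean test error is strictly below the
#' threshold; skipped and failed terms are never retained.
#'
#' @param term_results A [knowledge_retrieval()] tibble.
#' @param threshold Error threshold in \[0, 1\].
#' @return The retained subset of `term_results`.
#' @export
postprocess <- function(term_results, threshold) {
  if (threshold < 0 || threshold > 1) abort("threshold must lie in [0, 1]")
  filter(
    term_results,
    .data$status == "processed" & !is.na(.data$error_mean) &
      .data$error_mean < threshold
  )
}

#' Pool per-domain results into single term and gene lists
#'
#' @param per_domain_results List of retained-term tibbles (at most one per
#'   domain; a term id may not appear under two domains).
#' @return A list with `terms` (bound tibble, unique term ids tagged by
#'   domain) and `genes` (deduplicated union of the selected gene symbols).
#' @export
pool_domains <- function(per_domain_results) {
  per_domain_results <- per_domain_results[
    !vapply(per_domain_results, is.null, logical(1))
  ]
  if (!length(per_domain_results)) {
    return(list(terms = tibble(term_id = character(), domain = character()), genes = character()))
  }
  terms <- bind_rows(per_domain_results)
  if (anyDuplicated(terms$term_id)) {
    abort(sprintf(
      "term '%s' appears in more than one domain list",
      terms$term_id[duplicated(terms$term_id)][1]
    ))
  }
  genes <- sort(unique(unlist(terms$selected_genes)))
  list(terms = terms, genes = genes)
}

#' Run the full knowledge-driven pipeline
#'
#' Local integration ([build_submatrices()]), per-term knowledge retrieval
#' ([knowledge_retrieval()]), and error-threshold post-processing
#' ([postprocess()]), pooled over the three GO domains. With
#' `threshold = "auto"` the threshold is the mean test error plus SD of a
#' reference l1l2 run on the full expression matrix (same CV
#' configuration); a numeric threshold is used as given.
#'
#' @inheritParams knowledge_retrieval
#' @param km A [build_knowledge_map()] result.
#' @param annotation A [platform_annotation()].
#' @param threshold `"auto"` or a number in \[0, 1\].
#' @param min_size Minimum term size (probesets) to process.
#' @param reference Optional precomputed reference [nested_cv()] result to
#'   reuse (skips the full-matrix run).
#' @param reference_selector Selector for the auto-threshold reference run;
#'   defaults to the per-term default engine.
#' @return An object of class `kdvs_result`: `term_results` (all terms),
#'   `retained` (past the threshold), `genes`, `threshold`,
#'   `reference` (the reference `cv_result` or `NULL`), `config`.
#' @export
run_kdvs <- function(dataset, km, annotation, config = cv_config(),
                     selector = NULL, classifier = NULL,
                     threshold = "auto", min_size = 6,
                     reference = NULL, reference_selector = NULL) {
  submatrices <- build_submatrices(dataset, km, min_size = min_size)
  term_results <- knowledge_retrieval(
    dataset, submatrices, config,
    selector = selector, classifier = classifier, annotation = annotation
  )
  if (identical(threshold, "auto")) {
    if (is.null(reference)) {
      if (is.null(reference_selector)) {
        reference_selector <- selector %||% selector_enet(alpha = 0.5, n_tau = 8, decades = 2)
      }
      reference <- nested_cv(
        dataset, reference_selector,
        classifier %||% classifier_model(), config
      )
    }
    threshold <- compute_threshold(reference$error_mean, reference$error_sd)
  } else {
    reference <- NULL
  }
  retained <- postprocess(term_results, threshold)
  pooled <- pool_domains(split(retained, retained$domain))
  structure(
    list(
      term_results = term_results, retained = pooled$terms,
      genes = pooled$genes, threshold = threshold,
      reference = reference, config = config
    ),
    class = "kdvs_result"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.kdvs_result <- function(x, ...) {
  n_proc <- sum(x$term_results$status == "processed")
  cat(sprintf(
    "<kdvs_result> %d terms (%d processed, %d skipped): %d retained at error < %.1f%%, %d gene(s)\n",
    nrow(x$term_results), n_proc, nrow(x$term_results) - n_proc,
    nrow(x$retained), 100 * x$threshold, length(x$genes)
  ))
  invisible(x)
}

#' @export
tidy.kdvs_result <- function(x, ...) {
  mutate(x$term_results,
    retained = .data$term_id %in% x$retained$term_id,
    n_selected = lengths(.data$selected)
  )
}

#' @export
glance.kdvs_result <- function(x, ...) {
  tibble(
    n_terms = nrow(x$term_results),
    n_processed = sum(x$term_results$status == "processed"),
    n_skipped = sum(x$term_results$status == "skipped_small"),
    n_retained = nrow(x$retained),
    n_genes = length(x$genes),
    threshold = x$threshold,
    reference_error = if (is.null(x$reference)) NA_real_ else x$reference$error_mean,
    reference_sd = if (is.null(x$reference)) NA_real_ else x$reference$error_sd
  )
}
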