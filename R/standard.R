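#' Run the standard signature-then-enrichment pipeline (signature step)
#'
#' Applies [nested_cv()] with the given selector/classifier on the *full*
#' expression matrix, aggregates the per-split selections by frequency, and
#' maps the aggregate probeset signature to gene symbols through the
#' platform annotation (deduplicated).
#'
#' @inheritParams nested_cv
#' @param annotation A [platform_annotation()].
#' @return A list of class `standard_signature`: `cv` (the [nested_cv()]
#'   result), `probesets`, `genes`.
#' @export
run_standard_pipeline <- function(dataset, selector, classifier,
                                  config = cv_config(), annotation) {
  cv <- nested_cv(dataset, selector, classifier, config)
  probesets <- cv$signature
  genes <- sort(unique(annotation$gene_symbol[
    annotation$probeset_id %in% probesets
  ]))
  structure(
    list(cv = cv, probesets = probesets, genes = genes),
    class = "standard_signature"
  )
}

#' @export
print.standard_signature <- function(x, ...) {
  cat(sprintf(
    "<standard_signature> %s + %s: error %.1f%% +/- %.1f%%; %d probesets -> %d genes\n",
    x$cv$selector, x$cv$classifier, 100 * x$cv$error_mean,
    100 * x$cv$error_sd, length(x$probesets), length(x$genes)
  ))
  invisible(x)
}

#' Enrichment configuration
#'
#' @param level Significance level on the corrected p-value (default 0.05).
#' @param correction `"bonferroni"` (multiplier = number of terms actually
#'   tested) or `"none"`.
#' @param min_genes Minimum signature genes a term must contain to be
#'   tested (default 3).
#' @return A list of class `enrichment_config`.
#' @export
enrichment_config <- function(level = 0.05, correction = c("bonferroni", "none"),
                              min_genes = 3) {
  correction <- match.arg(correction)
  if (level <= 0 || level >= 1) abort("level must lie in (0, 1)")
  if (min_genes < 1) abort("min_genes must be >= 1")
  structure(list(level = level, correction = correction, min_genes = as.integer(min_genes)),
    class = "enrichment_config"
  )
}

#' Hypergeometric over-representation test of a gene signature
#'
#' For every term containing at least `min_genes` signature genes, computes
#' the one-sided upper-tail hypergeometric probability of drawing at least
#' the observed overlap when `s` genes are sampled from a universe of `N`
#' genes of which `K` belong to the term. Only over-represented terms
#' (signature fraction `overlap/s` exceeding the background fraction `K/N`)
#' are reported; the corrected p is `min(1, p * number of tested terms)`
#' under Bonferroni, and terms with corrected p at most `level` are
#' returned sorted by corrected p.
#'
#' @param signature Character vector of gene symbols; genes outside the
#'   universe are dropped with a warning.
#' @param km A [build_knowledge_map()] result.
#' @param annotation A [platform_annotation()]; its genes are the default
#'   reference universe.
#' @param config An [enrichment_config()].
#' @param universe Optional character vector overriding the reference set.
#' @return A tibble of enriched terms: `term_id`, `domain`, `overlap`,
#'   `term_size`, `signature_size`, `universe_size`, `p_raw`, `p_adj`.
#' @export
enrich <- function(signature, km, annotation, config = enrichment_config(),
                   universe = NULL) {
  if (is.null(universe)) universe <- unique(annotation$gene_symbol)
  universe <- unique(as.character(universe))
  if (!length(universe)) abort("reference universe is empty")
  signature <- unique(as.character(signature))
  outside <- setdiff(signature, universe)
  if (length(outside)) {
    warn(sprintf(
      "%d signature gene(s) outside the reference universe dropped",
      length(outside)
    ))
    signature <- intersect(signature, universe)
  }
  N <- length(universe)
  s <- length(signature)
  tg <- term_genes(km, annotation)
  tg <- filter(tg, .data$gene_symbol %in% universe)
  per_term <- summarise(group_by(tg, .data$term_id, .data$domain),
    term_size = dplyr::n(),
    overlap = sum(.data$gene_symbol %in% signature),
    .groups = "drop"
  )
  tested <- filter(per_term, .data$overlap >= config$min_genes)
  if (!nrow(tested)) {
    return(tibble(
      term_id = character(), domain = character(), overlap = integer(),
      term_size = integer(), signature_size = integer(),
      universe_size = integer(), p_raw = numeric(), p_adj = numeric()
    ))
  }
  tested <- mutate(tested,
    p_raw = phyper(.data$overlap - 1L, .data$term_size,
      N - .data$term_size, s,
      lower.tail = FALSE
    ),
    over = s > 0 & (.data$overlap / s) > (.data$term_size / N)
  )
  multiplier <- if (config$correction == "bonferroni") nrow(tested) else 1
  tested <- mutate(tested,
    p_adj = pmin(1, .data$p_raw * multiplier),
    signature_size = s, universe_size = N
  )
  out <- filter(tested, .data$over & .data$p_adj <= config$level)
  out <- arrange(out, .data$p_adj, .data$p_raw, .data$term_id)
  out[, c(
    "term_id", "domain", "overlap", "term_size", "signature_size",
    "universe_size", "p_raw", "p_adj"
  )]
}
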