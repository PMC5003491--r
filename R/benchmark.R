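#' Default accepted evidence codes for benchmark construction
#'
#' Experimental codes (EXP, IDA, IPI, IMP, IGI, IEP) plus Traceable Author
#' Statement (TAS) and Inferred by Curator (IC).
#' @export
accepted_evidence_codes <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC")

#' Build benchmark gene and term lists from annotation evidence
#'
#' Starting from one or more plain gene-symbol lists (files or character
#' vectors), restricts to associations bearing an accepted evidence code;
#' when the same gene-term pair is annotated more than once only the most
#' recent association is kept. The benchmark genes are the input genes with
#' at least one surviving association; the benchmark terms are all GO ids
#' reached by surviving associations, split by aspect/domain.
#'
#' @param gene_lists Character vector of file paths (one symbol per line)
#'   and/or a list of character vectors of symbols.
#' @param gaf_records A [parse_gaf()] tibble.
#' @param accepted_codes Evidence codes to accept (default
#'   [accepted_evidence_codes]).
#' @return An object of class `benchmark_lists`: `genes` (character) and
#'   `terms` (named list with elements BP, MF, CC).
#' @export
build_benchmark <- function(gene_lists, gaf_records,
                            accepted_codes = accepted_evidence_codes) {
  known_codes <- c(accepted_evidence_codes, "IEA", "ISS", "ISO", "ISA",
    "ISM", "IGC", "IBA", "IBD", "IKR", "IRD", "RCA", "NAS", "ND", "HTP",
    "HDA", "HMP", "HGI", "HEP")
  unknown <- setdiff(accepted_codes, known_codes)
  if (length(unknown)) {
    warn(sprintf("unknown evidence code(s) in accepted set: %s",
      paste(unknown, collapse = ", ")))
  }
  if (is.character(gene_lists)) gene_lists <- as.list(gene_lists)
  genes_in <- unique(toupper(unlist(lapply(gene_lists, function(g) {
    if (length(g) == 1L && file.exists(g)) {
      g <- readLines(g)
    }
    trimws(g[nzchar(trimws(g))])
  }))))
  recs <- filter(gaf_records, !.data$negated,
    toupper(.data$gene_symbol) %in% genes_in)
  recs <- mutate(recs, gene_symbol = toupper(.data$gene_symbol))
  # duplicate gene-term pairs: keep the most recent association only
  recs <- arrange(recs, .data$gene_symbol, .data$go_id, desc(.data$date))
  recs <- distinct(recs, .data$gene_symbol, .data$go_id, .keep_all = TRUE)
  kept <- filter(recs, .data$evidence_code %in% accepted_codes)
  terms <- lapply(c(BP = "P", MF = "F", CC = "C"), function(a) {
    sort(unique(kept$go_id[kept$aspect == a]))
  })
  structure(
    list(genes = sort(unique(kept$gene_symbol)), terms = terms),
    class = "benchmark_lists"
  )
}

#' @export
print.benchmark_lists <- function(x, ...) {
  cat(sprintf(
    "<benchmark_lists> %d genes; terms: BP %d, MF %d, CC %d (total %d)\n",
    length(x$genes), length(x$terms$BP), length(x$terms$MF),
    length(x$terms$CC), sum(lengths(x$terms))
  ))
  invisible(x)
}

#' Per-domain and total term counts of a benchmark
#'
#' @param benchmark A [build_benchmark()] result, or a named list of term
#'   id vectors per domain.
#' @return A tibble with one row per domain plus a `total` row.
#' @export
benchmark_summary <- function(benchmark) {
  terms <- if (inherits(benchmark, "benchmark_lists")) benchmark$terms else benchmark
  per <- tibble(
    domain = names(terms),
    n_terms = as.integer(lengths(terms))
  )
  bind_rows(per, tibble(domain = "total", n_terms = sum(per$n_terms)))
}

#' Score a selection against a benchmark set
#'
#' Counts TP = selected and in the benchmark, FP = selected only,
#' FN = benchmark only, TN = the rest of the universe, then computes
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN) and
#' F-measure = 2PR/(P+R) (0 when P = R = 0).
#'
#' @param selected,benchmark Character vectors (subsets of `universe`).
#' @param universe Character vector of all scoreable items.
#' @param normalize_case Uppercase items before comparison (for gene
#'   symbols; default `FALSE`).
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `f_measure`.
#' @export
score_selection <- function(selected, benchmark, universe,
                            normalize_case = FALSE) {
  if (!length(universe)) abort("universe must be nonempty")
  if (normalize_case) {
    selected <- toupper(selected)
    benchmark <- toupper(benchmark)
    universe <- toupper(universe)
  }
  universe <- unique(universe)
  selected <- intersect(unique(selected), universe)
  benchmark <- intersect(unique(benchmark), universe)
  tp <- length(intersect(selected, benchmark))
  fp <- length(setdiff(selected, benchmark))
  fn <- length(setdiff(benchmark, selected))
  tn <- length(universe) - tp - fp - fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- f_measure(precision, recall)
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall, f_measure = f
  )
}

#' Harmonic-mean F-measure
#'
#' @param precision,recall Scalars in \[0, 1\].
#' @return `2 * P * R / (P + R)`, or 0 when both are 0.
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall > 0,
    2 * precision * recall / (precision + recall), 0
  )
}

#' ROC curve over the retention-error threshold
#'
#' Sweeps the retention threshold over the sorted unique term errors (plus
#' 0 and 1); at each threshold the retained set is the terms with error
#' strictly below it, and sensitivity = TP/(TP+FN) and
#' 1 - specificity = FP/(TN+FP) are computed against the benchmark over the
#' universe of processed terms. The point with the highest F-measure is
#' flagged.
#'
#' @param term_results A [knowledge_retrieval()] tibble (uses `term_id`,
#'   `status`, `error_mean`).
#' @param benchmark_terms Character vector of benchmark term ids.
#' @param universe_terms Universe for TN; defaults to all processed terms.
#' @return A tibble of class `kdvs_roc`: `threshold`, `sensitivity`,
#'   `one_minus_specificity`, `f_measure`, `best` (logical).
#' @export
roc_over_threshold <- function(term_results, benchmark_terms,
                               universe_terms = NULL) {
  proc <- filter(term_results, .data$status == "processed" & !is.na(.data$error_mean))
  if (is.null(universe_terms)) universe_terms <- proc$term_id
  if (!length(benchmark_terms)) abort("benchmark term list is empty")
  thresholds <- sort(unique(c(0, proc$error_mean, 1)))
  # a term is retained when error < threshold, so sweep just above each value
  thresholds <- sort(unique(c(thresholds, pmin(1, proc$error_mean + 1e-12))))
  pts <- bind_rows(lapply(thresholds, function(th) {
    sel <- proc$term_id[proc$error_mean < th]
    m <- score_selection(sel, benchmark_terms, universe_terms)
    tibble(
      threshold = th,
      sensitivity = if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0,
      one_minus_specificity = if (m$tn + m$fp > 0) m$fp / (m$tn + m$fp) else 0,
      f_measure = m$f_measure
    )
  }))
  pts <- mutate(pts, best = seq_len(dplyr::n()) == which.max(.data$f_measure))
  class(pts) <- c("kdvs_roc", class(pts))
  pts
}

#' Compare pipeline outputs against a benchmark
#'
#' Builds the comparison table of GO-term and gene selection metrics for
#' the knowledge-driven result (cumulative and per-domain) and any number
#' of standard-pipeline variants. F-measures are reported x 10^-3 alongside
#' the raw value, and each method row carries its F-measure ratio to the
#' first standard method (GO terms), the "fold gain" of embedding the
#' ontology into selection.
#'
#' @param kdvs_result A [run_kdvs()] result (or `NULL`).
#' @param standard_terms Named list: per standard method, the character
#'   vector of enriched term ids.
#' @param standard_genes Named list: per standard method, the signature
#'   gene symbols.
#' @param benchmark A [build_benchmark()] result (or a list with `genes`
#'   and per-domain `terms`).
#' @param term_universe,gene_universe Universes for TN accounting; default
#'   to the processed terms / union of scored genes.
#' @return A tibble, one row per (method, item type): confusion counts,
#'   precision, recall, `f_measure`, `f_measure_x1000`, and
#'   `f_ratio_vs_standard` on GO-term rows.
#' @export
evaluate_pipelines <- function(kdvs_result = NULL, standard_terms = list(),
                               standard_genes = list(), benchmark,
                               term_universe = NULL, gene_universe = NULL) {
  bench_terms <- sort(unique(unlist(benchmark$terms)))
  bench_genes <- benchmark$genes
  rows <- list()
  if (!is.null(kdvs_result)) {
    if (is.null(term_universe)) {
      term_universe <- kdvs_result$term_results$term_id[
        kdvs_result$term_results$status == "processed"
      ]
    }
    all_terms <- kdvs_result$retained$term_id
    rows[["kdvs_all"]] <- mutate(
      score_selection(all_terms, bench_terms, term_universe),
      method = "kdvs_all_domains", item = "go_terms"
    )
    for (d in unique(kdvs_result$retained$domain)) {
      dom_terms <- kdvs_result$retained$term_id[kdvs_result$retained$domain == d]
      dom_bench <- benchmark$terms[[d]]
      if (is.null(dom_bench)) dom_bench <- character()
      rows[[paste0("kdvs_", d)]] <- mutate(
        score_selection(dom_terms, dom_bench, term_universe),
        method = paste0("kdvs_", d), item = "go_terms"
      )
    }
  }
  for (nm in names(standard_terms)) {
    rows[[paste0("std_t_", nm)]] <- mutate(
      score_selection(
        standard_terms[[nm]], bench_terms,
        term_universe %||% unique(c(standard_terms[[nm]], bench_terms))
      ),
      method = nm, item = "go_terms"
    )
  }
  gene_rows <- list()
  if (!is.null(kdvs_result)) gene_rows[["kdvs_all_domains"]] <- kdvs_result$genes
  for (nm in names(standard_genes)) gene_rows[[nm]] <- standard_genes[[nm]]
  if (length(gene_rows)) {
    if (is.null(gene_universe)) {
      gene_universe <- unique(c(unlist(gene_rows), bench_genes))
    }
    for (nm in names(gene_rows)) {
      rows[[paste0("g_", nm)]] <- mutate(
        score_selection(gene_rows[[nm]], bench_genes, gene_universe,
          normalize_case = TRUE
        ),
        method = nm, item = "genes"
      )
    }
  }
  out <- bind_rows(rows)
  out <- mutate(out, f_measure_x1000 = 1000 * .data$f_measure)
  std_names <- names(standard_terms)
  ref_f <- if (length(std_names)) {
    out$f_measure[out$method == std_names[1] & out$item == "go_terms"][1]
  } else {
    NA_real_
  }
  out <- mutate(out,
    f_ratio_vs_standard = ifelse(
      .data$item == "go_terms" & !is.na(ref_f) & ref_f > 0,
      .data$f_measure / ref_f, NA_real_
    )
  )
  out[, c(
    "method", "item", "tp", "fp", "fn", "tn", "precision", "recall",
    "f_measure", "f_measure_x1000", "f_ratio_vs_standard"
  )]
}

#' F-measure fold ratio between two pipelines
#'
#' @param f_numerator,f_denominator F-measures on a common scale.
#' @return `f_numerator / f_denominator`.
#' @export
f_ratio <- function(f_numerator, f_denominator) {
  if (f_denominator <= 0) abort("denominator F-measure must be positive")
  f_numerator / f_denominator
}
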