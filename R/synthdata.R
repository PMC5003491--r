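#' Simulation configuration
#'
#' Parameters of the self-contained synthetic study: a random three-domain
#' ontology, gene/probeset annotation, and a case/control expression matrix
#' in which every probeset of every gene annotated to a *planted* term
#' carries a class-conditional mean shift of `delta` noise standard
#' deviations. The defaults describe a study that a full knowledge-driven
#' run completes in minutes: 60 cases / 60 controls, 300 genes with 1-2
#' probesets each, 30 terms per domain with 5-40 genes, 3 planted terms per
#' domain, shift `delta = 1.5`, noise SD 1 on a log2-intensity-like baseline
#' of 8.
#'
#' @param n_cases,n_controls Sample counts per class.
#' @param n_genes Genes on the simulated platform.
#' @param probesets_per_gene Length-2 integer range; each gene gets a count
#'   drawn uniformly from it.
#' @param n_terms_per_domain Terms generated in each of BP/MF/CC.
#' @param term_size_range Length-2 range of genes per term.
#' @param n_planted_terms Discriminant terms planted per domain.
#' @param effect_size Mean shift `delta`, in units of `noise_sd`.
#' @param noise_sd Gaussian noise SD `sigma`.
#' @param baseline Background mean `mu0`.
#' @param seed Integer seed; the whole study is reproducible given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 60, n_controls = 60, n_genes = 300,
                       probesets_per_gene = c(1, 2), n_terms_per_domain = 30,
                       term_size_range = c(5, 40), n_planted_terms = 3,
                       effect_size = 1.5, noise_sd = 1, baseline = 8,
                       seed = 1) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes),
    probesets_per_gene = as.integer(probesets_per_gene),
    n_terms_per_domain = as.integer(n_terms_per_domain),
    term_size_range = as.integer(term_size_range),
    n_planted_terms = as.integer(n_planted_terms),
    effect_size = effect_size, noise_sd = noise_sd, baseline = baseline,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (min(n_cases, n_controls, n_genes, n_terms_per_domain) < 1L) {
      abort("all counts must be positive")
    }
    if (effect_size < 0) abort("effect_size must be >= 0")
    if (term_size_range[1] < 1L) abort("term sizes must be >= 1")
    if (n_planted_terms > n_terms_per_domain) {
      abort("n_planted_terms cannot exceed n_terms_per_domain")
    }
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a complete synthetic study
#'
#' Generates, reproducibly from `config$seed`: a random DAG ontology with
#' `n_terms_per_domain` terms in each of BP/MF/CC; a platform annotation of
#' `n_genes` genes with 1-2 probesets each; a complete gene-association
#' table (GAF-style records, experimental evidence codes); and an
#' expression matrix where background values are i.i.d.
#' `Normal(baseline, noise_sd^2)` and every probeset of every gene annotated
#' to a planted term has its *case* mean shifted by
#' `effect_size * noise_sd`.
#'
#' Planted terms draw their genes from a dedicated disease-module pool and
#' non-planted terms from the complement, so non-planted terms never carry
#' planted signal and the ground truth stays identifiable; terms within
#' each group may still overlap (as GO terms do). The emitted association
#' table is *complete* -- memberships are final, with nothing implicit left
#' to propagate -- so knowledge maps for simulated studies should be built
#' with `propagate = FALSE`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study` with elements `dataset`
#'   ([expr_dataset()]), `ontology` ([parse_obo()]-shaped), `gaf`
#'   ([parse_gaf()]-shaped tibble), `annotation`
#'   ([platform_annotation()]), `truth` (list: `terms` named by domain,
#'   `genes`, `probesets`), and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  domains <- c("BP", "MF", "CC")
  aspects <- c(BP = "P", MF = "F", CC = "C")

  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  n_ps <- sample(
    seq(config$probesets_per_gene[1], config$probesets_per_gene[2]),
    config$n_genes,
    replace = TRUE
  )
  annotation <- platform_annotation(
    probeset_id = unlist(lapply(seq_along(genes), function(i) {
      sprintf("%s_at%d", genes[i], seq_len(n_ps[i]))
    })),
    gene_symbol = rep(genes, n_ps)
  )

  # planted terms first: their genes come from a dedicated pool so that
  # non-planted terms never contain shifted genes
  term_rows <- list()
  edge_rows <- list()
  membership <- list()
  planted <- list()
  planted_gene_pool <- character()

  draw_sizes <- function(k) {
    sample(seq(config$term_size_range[1], config$term_size_range[2]), k,
      replace = TRUE
    )
  }

  for (d in domains) {
    ids <- sprintf("GO:%s%04d", d, seq_len(config$n_terms_per_domain))
    term_rows[[d]] <- tibble(
      term_id = ids,
      name = sprintf("simulated %s term %d", d, seq_along(ids)),
      domain = d, obsolete = FALSE
    )
    # random DAG: each non-root term gets one is_a parent among earlier
    # terms, occasionally an extra part_of parent
    if (length(ids) > 1L) {
      parent <- vapply(
        seq(2L, length(ids)),
        function(i) ids[sample.int(i - 1L, 1L)], character(1)
      )
      edge_rows[[paste0(d, "_isa")]] <- tibble(
        child = ids[-1], parent = parent, relation = "is_a"
      )
      extra <- which(stats::runif(length(ids) - 1L) < 0.2 & seq(2L, length(ids)) > 2L)
      if (length(extra)) {
        po_parent <- vapply(extra + 1L, function(i) {
          cand <- setdiff(ids[seq_len(i - 1L)], parent[i - 1L])
          cand[sample.int(length(cand), 1L)]
        }, character(1))
        edge_rows[[paste0(d, "_po")]] <- tibble(
          child = ids[extra + 1L], parent = po_parent, relation = "part_of"
        )
      }
    }
    planted_ids <- sample(ids, config$n_planted_terms)
    planted[[d]] <- sort(planted_ids)
    sizes <- setNames(draw_sizes(length(ids)), ids)
    for (t in planted_ids) {
      membership[[t]] <- sample(genes, min(sizes[[t]], length(genes)))
      planted_gene_pool <- union(planted_gene_pool, membership[[t]])
    }
  }
  free_genes <- setdiff(genes, planted_gene_pool)
  for (d in domains) {
    ids <- setdiff(term_rows[[d]]$term_id, planted[[d]])
    sizes <- draw_sizes(length(ids))
    for (i in seq_along(ids)) {
      size <- min(sizes[i], length(free_genes))
      if (size < 1L) abort("gene pool exhausted; increase n_genes")
      membership[[ids[i]]] <- sample(free_genes, size)
    }
  }

  ontology <- structure(
    list(terms = bind_rows(term_rows), edges = bind_rows(edge_rows)),
    class = "go_ontology"
  )

  domain_of <- setNames(ontology$terms$domain, ontology$terms$term_id)
  gaf <- bind_rows(lapply(names(membership), function(t) {
    tibble(
      gene_symbol = sort(membership[[t]]), go_id = t, qualifier = "",
      negated = FALSE, evidence_code = "EXP",
      aspect = unname(aspects[domain_of[[t]]]), date = "20260101"
    )
  }))
  gaf <- arrange(gaf, .data$gene_symbol, .data$go_id)

  planted_genes <- sort(unique(unlist(membership[unlist(planted)])))
  planted_probesets <- sort(
    annotation$probeset_id[annotation$gene_symbol %in% planted_genes]
  )

  n <- config$n_cases + config$n_controls
  p <- nrow(annotation)
  labels <- c(rep(1, config$n_cases), rep(-1, config$n_controls))
  values <- matrix(
    rnorm(p * n, mean = config$baseline, sd = config$noise_sd),
    nrow = p,
    dimnames = list(
      annotation$probeset_id,
      sprintf("SAMPLE%03d", seq_len(n))
    )
  )
  shift_rows <- rownames(values) %in% planted_probesets
  if (any(shift_rows) && config$effect_size > 0) {
    values[shift_rows, labels == 1] <- values[shift_rows, labels == 1] +
      config$effect_size * config$noise_sd
  }
  dataset <- expr_dataset(values, labels)

  structure(
    list(
      dataset = dataset, ontology = ontology, gaf = gaf,
      annotation = annotation,
      truth = list(
        terms = planted, genes = planted_genes,
        probesets = planted_probesets
      ),
      config = config
    ),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study> %d probesets x %d samples; %d terms/domain, %d planted/domain (delta = %g)\n",
    nrow(x$dataset$values), ncol(x$dataset$values),
    x$config$n_terms_per_domain, x$config$n_planted_terms,
    x$config$effect_size
  ))
  invisible(x)
}

#' Write a simulated study as plain-text fixtures
#'
#' Emits the expression TSV + labels TSV, an OBO file, a 17-column GAF, the
#' platform-annotation CSV and the ground-truth lists, in the exact dialects
#' the package's own parsers read, so the study round-trips through
#' [read_expression()], [parse_obo()], [parse_gaf()] and
#' [read_platform_annotation()].
#'
#' @param study A [simulate_study()] result.
#' @param outdir Output directory (created if missing).
#' @return Named character vector of the paths written.
#' @export
write_fixture <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(outdir, "expression.tsv"),
    labels = file.path(outdir, "labels.tsv"),
    obo = file.path(outdir, "ontology.obo"),
    gaf = file.path(outdir, "associations.gaf"),
    annotation = file.path(outdir, "platform.csv"),
    truth_terms = file.path(outdir, "truth_terms.tsv"),
    truth_genes = file.path(outdir, "truth_genes.txt")
  )
  write_expression(study$dataset, paths[["expression"]], paths[["labels"]])

  obo <- c("format-version: 1.2", "")
  ns_long <- c(
    BP = "biological_process", MF = "molecular_function",
    CC = "cellular_component"
  )
  for (i in seq_len(nrow(study$ontology$terms))) {
    t <- study$ontology$terms[i, ]
    parents <- filter(study$ontology$edges, .data$child == t$term_id)
    obo <- c(
      obo, "[Term]",
      paste0("id: ", t$term_id),
      paste0("name: ", t$name),
      paste0("namespace: ", ns_long[[t$domain]]),
      if (nrow(parents)) {
        unlist(lapply(seq_len(nrow(parents)), function(j) {
          if (parents$relation[j] == "is_a") {
            paste0("is_a: ", parents$parent[j])
          } else {
            paste0("relationship: part_of ", parents$parent[j])
          }
        }))
      },
      if (t$obsolete) "is_obsolete: true",
      ""
    )
  }
  writeLines(obo, paths[["obo"]])

  gaf_lines <- c(
    "!gaf-version: 2.1",
    vapply(seq_len(nrow(study$gaf)), function(i) {
      r <- study$gaf[i, ]
      fields <- rep("", 17)
      fields[1] <- "SIMDB"
      fields[2] <- r$gene_symbol
      fields[3] <- r$gene_symbol
      fields[4] <- r$qualifier
      fields[5] <- r$go_id
      fields[6] <- "SIM:0001"
      fields[7] <- r$evidence_code
      fields[9] <- r$aspect
      fields[12] <- "protein"
      fields[13] <- "taxon:0000"
      fields[14] <- r$date
      fields[15] <- "SIM"
      paste(fields, collapse = "\t")
    }, character(1))
  )
  writeLines(gaf_lines, paths[["gaf"]])

  readr::write_csv(
    tibble(
      probeset_id = study$annotation$probeset_id,
      gene_symbol = study$annotation$gene_symbol
    ),
    paths[["annotation"]], progress = FALSE
  )

  truth_terms <- bind_rows(lapply(names(study$truth$terms), function(d) {
    if (!length(study$truth$terms[[d]])) {
      return(NULL)
    }
    tibble(term_id = study$truth$terms[[d]], domain = d)
  }))
  if (is.null(truth_terms) || !nrow(truth_terms)) {
    writeLines("term_id\tdomain", paths[["truth_terms"]])
  } else {
    readr::write_tsv(truth_terms, paths[["truth_terms"]], progress = FALSE)
  }
  writeLines(study$truth$genes, paths[["truth_genes"]])
  paths
}
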