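#' Parse an OBO ontology file
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 file, keeping the identifier,
#' name, namespace (BP/MF/CC), `is_a` parents and `relationship: part_of`
#' parents. Obsolete terms are recorded but excluded from the edge set, and
#' terms in an unrecognized namespace are skipped with a warning. Parent
#' links are checked to form a DAG.
#'
#' @param path Path to the OBO file.
#' @return An object of class `go_ontology`: a list with `terms` (tibble:
#'   `term_id`, `name`, `domain`, `obsolete`) and `edges` (tibble: `child`,
#'   `parent`, `relation`).
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  boundaries <- c(
    grep("^\\[", lines),
    length(lines) + 1L
  )
  ns_map <- c(
    biological_process = "BP", molecular_function = "MF",
    cellular_component = "CC"
  )
  terms <- list()
  edges <- list()
  skipped <- 0L
  for (s in starts) {
    e <- min(boundaries[boundaries > s]) - 1L
    block <- lines[(s + 1L):e]
    field <- function(key) {
      hits <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", hits))
    }
    id <- field("id")[1]
    if (is.na(id)) next
    ns <- field("namespace")[1]
    if (is.na(ns) || !ns %in% names(ns_map)) {
      skipped <- skipped + 1L
      next
    }
    obsolete <- identical(field("is_obsolete")[1], "true")
    is_a <- sub("\\s*!.*$", "", field("is_a"))
    rels <- field("relationship")
    part_of <- sub("\\s*!.*$", "", sub("^part_of\\s+", "", rels[startsWith(rels, "part_of")]))
    terms[[id]] <- tibble(
      term_id = id, name = field("name")[1] %|NA|% id,
      domain = unname(ns_map[ns]), obsolete = obsolete
    )
    if (!obsolete) {
      if (length(is_a)) {
        edges[[paste0(id, ":isa")]] <-
          tibble(child = id, parent = trimws(is_a), relation = "is_a")
      }
      if (length(part_of)) {
        edges[[paste0(id, ":po")]] <-
          tibble(child = id, parent = trimws(part_of), relation = "part_of")
      }
    }
  }
  if (skipped > 0L) {
    warn(sprintf("%d term(s) skipped: unknown namespace", skipped))
  }
  terms <- bind_rows(terms)
  edges <- bind_rows(edges)
  if (nrow(edges)) {
    edges <- filter(edges, .data$parent %in% terms$term_id)
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
      vertices = terms$term_id
    )
    if (!igraph::is_dag(g)) abort("ontology parent links contain a cycle")
  }
  structure(list(terms = terms, edges = edges), class = "go_ontology")
}

`%|NA|%` <- function(x, y) if (is.null(x) || is.na(x)) y else x

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf(
    "<go_ontology> %d terms (%d obsolete), %d edges\n",
    nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges)
  ))
  invisible(x)
}

#' Parse a GAF 2.x gene-association file
#'
#' Tab-separated, 17 columns, `!`-prefixed comment lines. The gene symbol is
#' read from column 3, qualifier from column 4, GO id from column 5,
#' evidence code from column 7, aspect from column 9 and date (YYYYMMDD)
#' from column 14.
#'
#' @param path Path to the GAF file.
#' @return A tibble with columns `gene_symbol`, `go_id`, `qualifier`,
#'   `negated`, `evidence_code`, `aspect`, `date`.
#' @export
parse_gaf <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(tibble(
      gene_symbol = character(), go_id = character(),
      qualifier = character(), negated = logical(),
      evidence_code = character(), aspect = character(), date = character()
    ))
  }
  # sentinel keeps trailing empty fields from being dropped by strsplit
  rows <- strsplit(paste0(lines[idx], "\tEOL"), "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 18L)
  if (length(bad)) {
    abort(sprintf(
      "%s line %d: GAF 2.x needs 17 columns, found %d",
      path, idx[bad[1]], lengths(rows)[bad[1]] - 1L
    ))
  }
  col <- function(i) vapply(rows, `[[`, character(1), i)
  out <- tibble(
    gene_symbol = col(3), go_id = col(5), qualifier = col(4),
    negated = grepl("(^|\\|)NOT($|\\|)", col(4)),
    evidence_code = col(7), aspect = col(9), date = col(14)
  )
  if (any(!nzchar(out$evidence_code))) {
    abort(sprintf(
      "%s line %d: empty evidence code", path,
      idx[which(!nzchar(out$evidence_code))[1]]
    ))
  }
  bad_date <- !grepl("^\\d{8}$", out$date)
  if (any(bad_date)) {
    abort(sprintf(
      "%s line %d: date not YYYYMMDD", path, idx[which(bad_date)[1]]
    ))
  }
  out
}

aspect_to_domain <- c(P = "BP", F = "MF", C = "CC")

term_ancestors <- function(ontology) {
  # term_id -> character vector of all ancestors via is_a / part_of
  if (!nrow(ontology$edges)) {
    return(setNames(
      vector("list", nrow(ontology$terms)),
      ontology$terms$term_id
    ))
  }
  g <- igraph::graph_from_data_frame(ontology$edges[, c("child", "parent")],
    vertices = ontology$terms$term_id
  )
  ids <- ontology$terms$term_id
  anc <- lapply(ids, function(t) {
    r <- names(igraph::subcomponent(g, t, mode = "out"))
    setdiff(r, t)
  })
  setNames(anc, ids)
}

#' Build the bidirectional probeset/term map
#'
#' Joins gene-to-term associations to probesets through the platform
#' annotation, yielding for every ontology term the set of probesets whose
#' gene is annotated to it (and the inverse map). Negated (`NOT`)
#' associations and obsolete terms are excluded. With `propagate = TRUE`
#' every association is copied to all `is_a`/`part_of` ancestors (true-path
#' rule).
#'
#' @param ontology A [parse_obo()] result.
#' @param gaf_records A [parse_gaf()] tibble.
#' @param annotation A [platform_annotation()].
#' @param propagate Apply the true-path rule (default `TRUE`).
#' @return An object of class `knowledge_map`: list with `map` (tibble
#'   `term_id`, `domain`, `probeset_id`) plus a `terms` summary tibble.
#' @export
build_knowledge_map <- function(ontology, gaf_records, annotation,
                                propagate = TRUE) {
  recs <- filter(gaf_records, !.data$negated)
  live <- filter(ontology$terms, !.data$obsolete)
  recs <- filter(recs, .data$go_id %in% live$term_id)
  unmapped <- setdiff(unique(recs$gene_symbol), annotation$gene_symbol)
  if (length(unmapped)) {
    message(sprintf(
      "%d annotated gene(s) absent from the platform annotation",
      length(unmapped)
    ))
  }
  gene_term <- distinct(recs[, c("gene_symbol", "go_id")])
  if (propagate && nrow(ontology$edges)) {
    anc <- term_ancestors(ontology)
    extra <- tidyr::unnest(
      mutate(gene_term, go_id = unname(anc[.data$go_id])),
      "go_id"
    )
    gene_term <- distinct(bind_rows(gene_term, extra))
  }
  map <- inner_join(gene_term, annotation, by = "gene_symbol",
    relationship = "many-to-many"
  )
  map <- distinct(tibble(
    term_id = map$go_id, probeset_id = map$probeset_id
  ))
  map <- inner_join(map, live[, c("term_id", "domain")], by = "term_id")
  map <- arrange(map, .data$term_id, .data$probeset_id)[
    , c("term_id", "domain", "probeset_id")
  ]
  terms <- summarise(group_by(map, .data$term_id, .data$domain),
    n_probesets = dplyr::n(), .groups = "drop"
  )
  structure(list(map = map, terms = terms), class = "knowledge_map")
}

#' @export
print.knowledge_map <- function(x, ...) {
  cat(sprintf(
    "<knowledge_map> %d terms, %d probesets, %d links\n",
    nrow(x$terms), length(unique(x$map$probeset_id)), nrow(x$map)
  ))
  invisible(x)
}

#' Query a knowledge map
#'
#' `term_probesets()` returns the probesets of one term; `probeset_terms()`
#' the terms of one probeset.
#'
#' @param km A [build_knowledge_map()] result.
#' @param term_id,probeset_id Single identifier.
#' @return Character vector.
#' @export
term_probesets <- function(km, term_id) {
  km$map$probeset_id[km$map$term_id == term_id]
}

#' @rdname term_probesets
#' @export
probeset_terms <- function(km, probeset_id) {
  unique(km$map$term_id[km$map$probeset_id == probeset_id])
}

#' Gene-level term membership derived from a knowledge map
#'
#' Collapses the probeset-level map back to gene symbols through the
#' platform annotation; used by the enrichment test, which operates on
#' genes.
#'
#' @inheritParams term_probesets
#' @param annotation A [platform_annotation()].
#' @return Tibble with columns `term_id`, `domain`, `gene_symbol`.
#' @export
term_genes <- function(km, annotation) {
  joined <- inner_join(km$map, annotation, by = "probeset_id",
    relationship = "many-to-many"
  )
  distinct(joined[, c("term_id", "domain", "gene_symbol")])
}
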