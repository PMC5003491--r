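# Shared fixtures, all built in code at test time.

toy_dataset <- function(p = 3, n = 4, seed = 42, labels = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(p * n, mean = 8), p, n,
    dimnames = list(sprintf("ps%02d", seq_len(p)), sprintf("s%02d", seq_len(n)))
  )
  if (is.null(labels)) labels <- rep(c(1, -1), length.out = n)
  expr_dataset(x, labels)
}

# two-class dataset with a known shifted block of features
shifted_dataset <- function(p = 20, n1 = 15, n2 = 15, shifted = 1:4,
                            delta = 2, seed = 7) {
  set.seed(seed)
  n <- n1 + n2
  x <- matrix(rnorm(p * n), p, n,
    dimnames = list(sprintf("f%02d", seq_len(p)), sprintf("s%02d", seq_len(n)))
  )
  labels <- c(rep(1, n1), rep(-1, n2))
  x[shifted, labels == 1] <- x[shifted, labels == 1] + delta
  expr_dataset(x, labels)
}

toy_obo_lines <- function() {
  c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: child a", "namespace: biological_process",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: child b", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: grandchild a", "namespace: biological_process",
    "is_a: GO:0000002", "relationship: part_of GO:0000003", "",
    "[Term]", "id: GO:0000005", "name: grandchild b", "namespace: biological_process",
    "is_a: GO:0000003", "",
    "[Term]", "id: GO:0000006", "name: gone", "namespace: biological_process",
    "is_a: GO:0000001", "is_obsolete: true", ""
  )
}

write_toy_obo <- function(path = tempfile(fileext = ".obo"), lines = toy_obo_lines()) {
  writeLines(lines, path)
  path
}

gaf_line <- function(symbol, go_id, evidence = "IDA", aspect = "P",
                     qualifier = "", date = "20240101") {
  fields <- rep("", 17)
  fields[1] <- "DB"
  fields[2] <- symbol
  fields[3] <- symbol
  fields[4] <- qualifier
  fields[5] <- go_id
  fields[6] <- "REF:1"
  fields[7] <- evidence
  fields[9] <- aspect
  fields[12] <- "protein"
  fields[13] <- "taxon:9606"
  fields[14] <- date
  fields[15] <- "DB"
  paste(fields, collapse = "\t")
}

write_toy_gaf <- function(lines, path = tempfile(fileext = ".gaf")) {
  writeLines(c("!gaf-version: 2.1", lines), path)
  path
}

toy_annotation <- function() {
  platform_annotation(
    probeset_id = c("psA1", "psA2", "psB1", "psC1"),
    gene_symbol = c("GA", "GA", "GB", "GC")
  )
}

small_sim_config <- function(seed = 1, ...) {
  sim_config(
    n_cases = 20, n_controls = 20, n_genes = 60,
    n_terms_per_domain = 6, term_size_range = c(4, 10),
    n_planted_terms = 1, seed = seed, ...
  )
}

fast_selector <- function() selector_enet(alpha = 0.5, n_tau = 6, decades = 2)
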