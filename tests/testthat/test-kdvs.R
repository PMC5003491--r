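make_map <- function(term_sizes, dataset, domains = NULL) {
  # knowledge map over the first probesets of the dataset, sizes as given
  ids <- rownames(dataset$values)
  rows <- list()
  start <- 1
  for (i in seq_along(term_sizes)) {
    take <- ids[seq(start, start + term_sizes[i] - 1)]
    rows[[i]] <- tibble::tibble(
      term_id = sprintf("GO:T%03d", i),
      domain = if (is.null(domains)) "BP" else domains[i],
      probeset_id = take
    )
    start <- start + term_sizes[i]
  }
  structure(
    list(
      map = dplyr::bind_rows(rows),
      terms = dplyr::count(dplyr::bind_rows(rows), term_id, domain,
        name = "n_probesets"
      )
    ),
    class = "knowledge_map"
  )
}

test_that("submatrices respect the minimum-size rule at its boundary", {
  d <- toy_dataset(p = 11, n = 10, seed = 1)
  km <- make_map(c(5, 6), d)
  subs <- build_submatrices(d, km, min_size = 6)
  expect_identical(
    subs$status[match(c("GO:T001", "GO:T002"), subs$term_id)],
    c("skipped_small", "processed")
  )
  expect_equal(subs$ps, c(5L, 6L))
})

test_that("submatrix overlap equals the terms' probeset overlap", {
  d <- toy_dataset(p = 12, n = 8, seed = 2)
  ids <- rownames(d$values)
  map <- dplyr::bind_rows(
    tibble::tibble(term_id = "GO:A", domain = "BP", probeset_id = ids[1:7]),
    tibble::tibble(term_id = "GO:B", domain = "BP", probeset_id = ids[5:12])
  )
  km <- structure(
    list(map = map, terms = dplyr::count(map, term_id, domain, name = "n_probesets")),
    class = "knowledge_map"
  )
  subs <- build_submatrices(d, km)
  pa <- subs$probesets[[which(subs$term_id == "GO:A")]]
  pb <- subs$probesets[[which(subs$term_id == "GO:B")]]
  expect_setequal(intersect(pa, pb), ids[5:7])
})

test_that("unknown probesets in the map are dropped with a warning", {
  d <- toy_dataset(p = 8, n = 8, seed = 3)
  km <- make_map(c(8), d)
  km$map <- dplyr::bind_rows(
    km$map,
    tibble::tibble(term_id = "GO:T001", domain = "BP", probeset_id = "ghost")
  )
  expect_warning(subs <- build_submatrices(d, km), "dropped")
  expect_equal(subs$ps, 8L)
})

test_that("threshold arithmetic and strict retention behave as stated", {
  expect_equal(compute_threshold(23.1, 8.6), 31.7)
  expect_equal(compute_threshold(0, 0), 0)
  expect_equal(compute_threshold(10, 5), 15)
  expect_error(compute_threshold(-1, 0), "non-negative")

  tr <- tibble::tibble(
    term_id = c("a", "b", "c", "d"), domain = "BP", ps = 10L,
    status = c("processed", "processed", "processed", "skipped_small"),
    error_mean = c(0.20, 0.317, 0.35, NA), error_sd = 0.05,
    selected = list("x", "y", "z", character()),
    selected_genes = list("gx", "gy", "gz", character())
  )
  # strictly below: a term AT the threshold is not retained
  expect_identical(postprocess(tr, 0.317)$term_id, "a")
  expect_setequal(postprocess(tr, 1.0)$term_id, c("a", "b", "c"))
  expect_equal(nrow(postprocess(tr, 0)), 0)
  # monotone in the threshold
  prev <- character()
  for (th in c(0, 0.1, 0.25, 0.33, 0.5, 1)) {
    cur <- postprocess(tr, th)$term_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("domain pooling deduplicates genes and rejects duplicate terms", {
  mk <- function(ids, domain, genes) {
    tibble::tibble(
      term_id = ids, domain = domain, ps = 6L, status = "processed",
      error_mean = 0.1, error_sd = 0.02,
      selected = replicate(length(ids), "ps1", simplify = FALSE),
      selected_genes = replicate(length(ids), genes, simplify = FALSE)
    )
  }
  pooled <- pool_domains(list(
    mk("t1", "BP", c("g1", "g2")), mk("t2", "MF", c("g2", "g3")), NULL
  ))
  expect_setequal(pooled$terms$term_id, c("t1", "t2"))
  expect_identical(pooled$genes, c("g1", "g2", "g3"))
  expect_error(
    pool_domains(list(mk("t1", "BP", "g1"), mk("t1", "MF", "g1"))),
    "more than one domain"
  )
  empty <- pool_domains(list())
  expect_equal(nrow(empty$terms), 0)
  expect_length(empty$genes, 0)
})

test_that("knowledge retrieval is deterministic and order-independent", {
  st <- simulate_study(small_sim_config(seed = 61))
  km <- build_knowledge_map(st$ontology, st$gaf, st$annotation, propagate = FALSE)
  subs <- build_submatrices(st$dataset, km)
  subs <- subs[subs$status == "processed", ][1:4, ]
  cfg <- cv_config(B = 5, frequency_cutoff = 3, seed = 17)
  r1 <- knowledge_retrieval(st$dataset, subs, cfg, annotation = st$annotation)
  r2 <- knowledge_retrieval(st$dataset, subs[rev(seq_len(nrow(subs))), ], cfg,
    annotation = st$annotation
  )
  r2 <- r2[match(r1$term_id, r2$term_id), ]
  expect_equal(r1$error_mean, r2$error_mean)
  expect_identical(r1$selected, r2$selected)
  # re-running the same term twice gives the identical result
  r3 <- knowledge_retrieval(st$dataset, subs[1, ], cfg, annotation = st$annotation)
  expect_equal(r3$error_mean, r1$error_mean[1])
  expect_identical(r3$selected[[1]], r1$selected[[1]])
})

test_that("planted terms classify well and noise terms sit at chance", {
  # planted-term error across replicates stays well below chance; a
  # pure-noise term's errors straddle chance
  n_seeds <- 8L
  planted_errs <- numeric(n_seeds)
  noise_errs <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    st <- simulate_study(small_sim_config(seed = 200 + s))
    km <- build_knowledge_map(st$ontology, st$gaf, st$annotation, propagate = FALSE)
    subs <- build_submatrices(st$dataset, km)
    planted_id <- st$truth$terms$BP
    noise_ids <- setdiff(subs$term_id[subs$status == "processed"], unlist(st$truth$terms))
    pick <- subs[subs$term_id %in% c(planted_id, noise_ids[1]), ]
    res <- knowledge_retrieval(st$dataset, pick, cv_config(B = 5, frequency_cutoff = 3, seed = s))
    planted_errs[s] <- res$error_mean[res$term_id == planted_id]
    noise_errs[s] <- res$error_mean[res$term_id == noise_ids[1]]
  }
  chance <- 0.5
  expect_lt(mean(planted_errs), chance - 0.15)
  expect_lt(abs(mean(noise_errs) - chance), 2 * sd(noise_errs) + 0.05)
})

test_that("run_kdvs pools retained terms across domains at a fixed threshold", {
  st <- simulate_study(small_sim_config(seed = 71))
  km <- build_knowledge_map(st$ontology, st$gaf, st$annotation, propagate = FALSE)
  res <- run_kdvs(st$dataset, km, st$annotation,
    cv_config(B = 5, frequency_cutoff = 3, seed = 7),
    threshold = compute_threshold(0.231, 0.086)
  )
  expect_s3_class(res, "kdvs_result")
  expect_equal(
    nrow(res$term_results),
    sum(res$term_results$status == "processed") +
      sum(res$term_results$status != "processed")
  )
  expect_true(all(res$retained$error_mean < res$threshold))
  expect_true(all(res$genes %in% st$annotation$gene_symbol))
  g <- glance(res)
  expect_equal(g$n_retained, nrow(res$retained))
  td <- tidy(res)
  expect_true(all(td$retained[td$term_id %in% res$retained$term_id]))
})
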