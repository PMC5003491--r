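test_that("benchmark construction filters by evidence code and keeps latest dates", {
  gaf <- parse_gaf(write_toy_gaf(c(
    gaf_line("GA", "GO:0000010", evidence = "IDA", aspect = "P", date = "20100101"),
    gaf_line("GA", "GO:0000010", evidence = "TAS", aspect = "P", date = "20090101"),
    gaf_line("GB", "GO:0000011", evidence = "IEA", aspect = "F", date = "20100101"),
    gaf_line("GC", "GO:0000012", evidence = "IMP", aspect = "C", date = "20100101"),
    gaf_line("GC", "GO:0000013", evidence = "TAS", aspect = "P", date = "20100101"),
    gaf_line("GD", "GO:0000014", evidence = "EXP", aspect = "P", date = "20100101")
  )))
  bench <- build_benchmark(list(c("GA", "GB", "GC")), gaf)
  # GB has only an IEA association -> excluded; GD not in the input lists
  expect_setequal(bench$genes, c("GA", "GC"))
  expect_setequal(bench$terms$BP, c("GO:0000010", "GO:0000013"))
  expect_length(bench$terms$MF, 0)
  expect_identical(bench$terms$CC, "GO:0000012")
  # duplicate gene-term pair: single association, most recent retained
  expect_equal(sum(unlist(bench$terms) == "GO:0000010"), 1)
  # when the most recent duplicate bears a rejected code, the pair drops
  gaf2 <- parse_gaf(write_toy_gaf(c(
    gaf_line("GA", "GO:0000010", evidence = "TAS", aspect = "P", date = "20090101"),
    gaf_line("GA", "GO:0000010", evidence = "IEA", aspect = "P", date = "20100101")
  )))
  bench2 <- build_benchmark(list("GA"), gaf2)
  expect_length(bench2$genes, 0)
  expect_warning(
    build_benchmark(list("GA"), gaf, accepted_codes = c("IDA", "XXX")),
    "XXX"
  )
})

test_that("benchmark summary adds per-domain counts into the total", {
  s <- benchmark_summary(list(
    BP = paste0("b", seq_len(12)), MF = paste0("m", seq_len(5)),
    CC = paste0("c", seq_len(3))
  ))
  expect_equal(s$n_terms[s$domain == "total"], 20L)
  expect_equal(sum(s$n_terms[s$domain != "total"]), s$n_terms[s$domain == "total"])
})

test_that("selection metrics match direct set counting", {
  uni <- paste0("u", 1:50)
  bench <- uni[1:20]
  sel <- uni[16:25] # overlap 5, |sel| = 10
  m <- score_selection(sel, bench, uni)
  expect_equal(m$tp, 5)
  expect_equal(m$fp, 5)
  expect_equal(m$fn, 15)
  expect_equal(m$tn, 25)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.25)
  expect_equal(m$f_measure, 1 / 3)
  # perfect and disjoint selections
  perfect <- score_selection(bench, bench, uni)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f_measure), c(1, 1, 1))
  disjoint <- score_selection(uni[21:30], bench, uni)
  expect_equal(c(disjoint$precision, disjoint$recall, disjoint$f_measure), c(0, 0, 0))
  expect_error(score_selection("a", "a", character()), "nonempty")
})

test_that("F-measure satisfies the harmonic-mean identity and its bounds", {
  set.seed(23)
  for (i in 1:50) {
    p <- runif(1)
    r <- runif(1)
    f <- f_measure(p, r)
    expect_equal(f, 2 * p * r / (p + r), tolerance = 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
    expect_gte(f, min(p, r) - 1e-12)
  }
  expect_equal(f_measure(0, 0), 0)
})

test_that("roc sweep is monotone, anchored at (0,0) and (1,1), with best-F point", {
  tr <- tibble::tibble(
    term_id = paste0("t", 1:4), domain = "BP", ps = 10L,
    status = "processed",
    error_mean = c(0.1, 0.2, 0.3, 0.4), error_sd = 0.01,
    selected = list("a", "b", "c", "d"),
    selected_genes = list("a", "b", "c", "d")
  )
  bench <- c("t1", "t2") # the two lowest-error terms
  roc <- roc_over_threshold(tr, bench)
  expect_equal(min(roc$sensitivity), 0)
  expect_equal(max(roc$sensitivity), 1)
  expect_equal(roc$one_minus_specificity[roc$threshold == 0], 0)
  expect_equal(roc$sensitivity[which.max(roc$threshold)], 1)
  expect_equal(roc$one_minus_specificity[which.max(roc$threshold)], 1)
  # monotone in the threshold
  expect_true(all(diff(roc$sensitivity[order(roc$threshold)]) >= 0))
  expect_true(all(diff(roc$one_minus_specificity[order(roc$threshold)]) >= 0))
  # benchmark terms separate perfectly: full sensitivity before any FP,
  # i.e. the staircase passes through (0, 1) and the best F is 1
  expect_true(any(roc$sensitivity == 1 & roc$one_minus_specificity == 0))
  expect_equal(max(roc$f_measure), 1)
  expect_equal(sum(roc$best), 1)
  # hand-computed AUC of the staircase is 1
  ord <- order(roc$one_minus_specificity, roc$sensitivity)
  x <- roc$one_minus_specificity[ord]
  y <- roc$sensitivity[ord]
  auc <- sum(diff(x) * y[-length(y)]) # step interpolation
  expect_equal(auc, 1)
})

test_that("pipeline comparison reports consistent metric rows and ratios", {
  bench <- list(
    genes = paste0("G", 1:10),
    terms = list(BP = paste0("tb", 1:5), MF = paste0("tm", 1:3), CC = character())
  )
  report <- evaluate_pipelines(
    kdvs_result = NULL,
    standard_terms = list(
      l1l2fs = c("tb1", "tb2", "zz1"),
      enet_lr = c("tb1", "tb2", "zz1")
    ),
    standard_genes = list(
      l1l2fs = c("G1", "g2", "nope"),
      enet_lr = c("G1", "g2", "nope")
    ),
    benchmark = bench,
    term_universe = c(paste0("tb", 1:5), paste0("tm", 1:3), "zz1", "zz2"),
    gene_universe = c(paste0("G", 1:10), "NOPE")
  )
  # identical outputs give identical metric rows
  r1 <- dplyr::filter(report, method == "l1l2fs")
  r2 <- dplyr::filter(report, method == "enet_lr")
  expect_equal(
    dplyr::select(r1, -method), dplyr::select(r2, -method)
  )
  # recomputing P/R/F from the report's own counts reproduces the columns
  for (i in seq_len(nrow(report))) {
    row <- report[i, ]
    p <- ifelse(row$tp + row$fp > 0, row$tp / (row$tp + row$fp), 0)
    r <- ifelse(row$tp + row$fn > 0, row$tp / (row$tp + row$fn), 0)
    expect_equal(row$precision, p)
    expect_equal(row$recall, r)
    expect_equal(row$f_measure, f_measure(p, r))
    expect_equal(row$f_measure_x1000, 1000 * row$f_measure)
  }
  # case-insensitive gene matching
  gene_row <- dplyr::filter(report, item == "genes", method == "l1l2fs")
  expect_equal(gene_row$tp, 2) # G1 and g2 both count
  # the ratio column is F / F(first standard method) on term rows
  term_rows <- dplyr::filter(report, item == "go_terms")
  expect_equal(
    term_rows$f_ratio_vs_standard,
    term_rows$f_measure / r1$f_measure[r1$item == "go_terms"]
  )
  expect_equal(f_ratio(197.4, 4.8), 197.4 / 4.8)
  expect_error(f_ratio(1, 0), "positive")
})
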