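#' Expression dataset container
#'
#' Bundles a p x n matrix of log-scale normalized intensities (rows =
#' probesets, columns = samples) with a binary phenotype vector coded
#' case = +1, control = -1. This is the `(X, Y)` pair that every pipeline in
#' the package consumes.
#'
#' @param values Numeric matrix, probesets in rows, samples in columns.
#'   Row and column names are used as probeset and sample identifiers if
#'   `probeset_ids` / `sample_ids` are not given.
#' @param labels Numeric vector of +1 (case) / -1 (control), one per sample.
#' @param probeset_ids,sample_ids Optional character identifiers overriding
#'   the matrix dimnames.
#'
#' @return An object of class `expr_dataset`: a list with elements `values`
#'   (named matrix) and `labels` (named +1/-1 vector).
#' @examples
#' x <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("ps", 1:3), c("s1", "s2")))
#' expr_dataset(x, c(1, -1))
#' @export
expr_dataset <- function(values, labels, probeset_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(probeset_ids)) rownames(values) <- probeset_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values))) {
    abort("expression matrix must have probeset identifiers (row names)")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  }
  labels <- normalize_labels(labels, ncol(values))
  names(labels) <- colnames(values)

  p <- nrow(values)
  n <- ncol(values)
  if (p < 1L) abort("dataset must contain at least one probeset")
  if (n < 2L) abort("dataset must contain at least two samples")
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    abort(sprintf("duplicate probeset id: '%s'", dup))
  }
  if (!all(is.finite(values))) abort("expression values must be finite")
  if (length(unique(labels)) < 2L) {
    abort("both classes (case and control) must be present")
  }
  structure(list(values = values, labels = labels), class = "expr_dataset")
}

normalize_labels <- function(labels, n) {
  if (is.character(labels) || is.factor(labels)) {
    lab <- tolower(as.character(labels))
    ok <- lab %in% c("case", "control", "1", "0", "-1", "+1")
    if (!all(ok)) {
      abort(sprintf("unrecognized label value '%s'", labels[!ok][1]))
    }
    labels <- ifelse(lab %in% c("case", "1", "+1"), 1, -1)
  }
  labels <- as.numeric(labels)
  if (length(labels) != n) {
    abort(sprintf("expected %d labels, got %d", n, length(labels)))
  }
  if (all(labels %in% c(0, 1))) labels[labels == 0] <- -1
  if (!all(labels %in% c(-1, 1))) {
    abort("labels must be coded case/control, 1/0 or +1/-1")
  }
  labels
}

#' @export
print.expr_dataset <- function(x, ...) {
  n_case <- sum(x$labels == 1)
  cat(sprintf(
    "<expr_dataset> %d probesets x %d samples (%d cases / %d controls)\n",
    nrow(x$values), ncol(x$values), n_case, length(x$labels) - n_case
  ))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Number of probesets / samples in a dataset
#' @param dataset An [expr_dataset()].
#' @return Integer count.
#' @export
n_probesets <- function(dataset) nrow(dataset$values)

#' @rdname n_probesets
#' @export
n_samples <- function(dataset) ncol(dataset$values)

#' Read an expression matrix (plus labels) from disk
#'
#' Reads a tab-delimited probeset x sample matrix whose first column holds
#' probeset identifiers and whose header row holds sample identifiers. The
#' `series-matrix` dialect additionally tolerates `!`-prefixed metadata lines
#' and a quoted `"ID_REF"` header cell, as found in GEO series-matrix files.
#'
#' @param path Path to the matrix file.
#' @param labels_path Path to a two-column tab-delimited file
#'   (`sample_id<TAB>label`); labels may be `case`/`control`, `1`/`0` or
#'   `+1`/`-1`.
#' @param dialect `"tsv"` (default) or `"series-matrix"`.
#' @return An [expr_dataset()].
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, labels_path, dialect = c("tsv", "series-matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (dialect == "series-matrix") {
    lines <- lines[!startsWith(lines, "!")]
    lines <- lines[nzchar(lines)]
  }
  if (length(lines) < 2L) abort(sprintf("%s: no data rows", path))
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", header)
  sample_ids <- header[-1]
  n <- length(sample_ids)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != n + 1L)
  if (length(bad)) {
    abort(sprintf(
      "%s line %d: expected %d fields, found %d",
      path, bad[1] + 1L, n + 1L, lengths(rows)[bad[1]]
    ))
  }
  ids <- gsub('^"|"$', "", vapply(rows, `[[`, character(1), 1L))
  if (anyDuplicated(ids)) {
    line <- which(duplicated(ids))[1] + 1L
    abort(sprintf("%s line %d: duplicate probeset id '%s'", path, line, ids[line - 1L]))
  }
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1]), numeric(n))
  )
  vals <- matrix(vals, nrow = n) # vapply returns n x rows when n > 1
  if (anyNA(vals)) {
    bad_row <- which(apply(matrix(is.na(vals), nrow = n), 2, any))[1]
    abort(sprintf("%s line %d: non-numeric expression value", path, bad_row + 1L))
  }
  values <- t(vals)
  dimnames(values) <- list(ids, sample_ids)

  lab_tbl <- readr::read_tsv(labels_path,
    col_names = c("sample_id", "label"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(sample_ids, lab_tbl$sample_id)
  if (length(missing)) {
    abort(sprintf("no label for sample '%s'", missing[1]))
  }
  labels <- lab_tbl$label[match(sample_ids, lab_tbl$sample_id)]
  expr_dataset(values, labels)
}

#' Write an expression dataset to disk
#'
#' Writes the matrix as a TSV (first column `probeset_id`, header of sample
#' ids) and the labels as `sample_id<TAB>label` with `case`/`control` coding.
#'
#' @param dataset An [expr_dataset()].
#' @param path,labels_path Output paths.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_expression <- function(dataset, path, labels_path) {
  header <- paste(c("probeset_id", colnames(dataset$values)), collapse = "\t")
  body <- vapply(seq_len(nrow(dataset$values)), function(i) {
    paste(c(
      rownames(dataset$values)[i],
      format(dataset$values[i, ], digits = 15, trim = TRUE, scientific = FALSE)
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  writeLines(
    paste(names(dataset$labels),
      ifelse(dataset$labels > 0, "case", "control"),
      sep = "\t"
    ),
    labels_path
  )
  invisible(c(path, labels_path))
}

#' Platform annotation table
#'
#' Maps probeset identifiers to gene symbols (many probesets may map to one
#' gene) and records which identifier prefixes denote control probesets.
#'
#' @param probeset_id,gene_symbol Character vectors of equal length.
#' @param control_prefixes Identifier prefixes marking control probesets
#'   (default `"AFFX"`, the Affymetrix convention).
#' @return A tibble of class `platform_annotation` with columns
#'   `probeset_id`, `gene_symbol` and a `control_prefixes` attribute.
#' @export
platform_annotation <- function(probeset_id, gene_symbol, control_prefixes = "AFFX") {
  probeset_id <- as.character(probeset_id)
  gene_symbol <- as.character(gene_symbol)
  if (length(probeset_id) != length(gene_symbol)) {
    abort("probeset_id and gene_symbol must have equal length")
  }
  if (any(is.na(gene_symbol) | !nzchar(gene_symbol))) {
    abort("every mapped probeset needs a nonempty gene symbol")
  }
  out <- distinct(tibble(probeset_id = probeset_id, gene_symbol = gene_symbol))
  attr(out, "control_prefixes") <- control_prefixes
  class(out) <- c("platform_annotation", class(out))
  out
}

#' Read a platform annotation table
#'
#' @param path CSV or TSV file with columns `probeset_id,gene_symbol`
#'   (delimiter sniffed from the header line).
#' @inheritParams platform_annotation
#' @return A [platform_annotation()] tibble.
#' @export
read_platform_annotation <- function(path, control_prefixes = "AFFX") {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tbl <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!all(c("probeset_id", "gene_symbol") %in% names(tbl))) {
    abort(sprintf("%s: need columns probeset_id, gene_symbol", path))
  }
  platform_annotation(tbl$probeset_id, tbl$gene_symbol, control_prefixes)
}

control_prefixes_of <- function(annotation) {
  pfx <- attr(annotation, "control_prefixes")
  if (is.null(pfx)) "AFFX" else pfx
}

is_control_probeset <- function(ids, prefixes) {
  if (!length(prefixes)) {
    return(rep(FALSE, length(ids)))
  }
  Reduce(`|`, lapply(prefixes, function(p) startsWith(ids, p)))
}

#' Merge expression datasets on their common probesets
#'
#' Restricts each input to the probesets present in every dataset, drops
#' control probesets (identifier prefix match), and concatenates samples and
#' labels. Probeset content of the result does not depend on input order.
#'
#' @param datasets List of [expr_dataset()] objects with disjoint sample ids.
#' @param annotation Optional [platform_annotation()]; only its
#'   `control_prefixes` attribute is consulted here.
#' @param control_prefixes Overrides the annotation's prefixes.
#' @return A merged [expr_dataset()].
#' @export
merge_datasets <- function(datasets, annotation = NULL, control_prefixes = NULL) {
  if (!length(datasets)) abort("need at least one dataset")
  if (is.null(control_prefixes)) {
    control_prefixes <- if (!is.null(annotation)) control_prefixes_of(annotation) else "AFFX"
  }
  common <- Reduce(intersect, lapply(datasets, function(d) rownames(d$values)))
  common <- common[!is_control_probeset(common, control_prefixes)]
  if (!length(common)) abort("no common non-control probesets across datasets")
  common <- sort(common)
  sample_ids <- unlist(lapply(datasets, function(d) colnames(d$values)))
  if (anyDuplicated(sample_ids)) {
    abort(sprintf(
      "sample ids must be disjoint across datasets (duplicate '%s')",
      sample_ids[duplicated(sample_ids)][1]
    ))
  }
  values <- do.call(cbind, lapply(datasets, function(d) d$values[common, , drop = FALSE]))
  labels <- unlist(lapply(datasets, function(d) unname(d$labels)))
  expr_dataset(values, labels, sample_ids = sample_ids)
}

#' Chance (majority-class) error of a label vector
#'
#' The misclassification rate of the constant majority-class predictor,
#' i.e. `min(class counts) / n` -- the floor any informative classifier must
#' beat. For the 56 case / 62 control design this is 0.4746, i.e. 47% when
#' rounded to integer percent.
#'
#' @param labels A +1/-1 vector (or an [expr_dataset()], whose labels are
#'   used).
#' @return A fraction in (0, 0.5].
#' @export
chance_error <- function(labels) {
  if (inherits(labels, "expr_dataset")) labels <- labels$labels
  labels <- normalize_labels(labels, length(labels))
  counts <- table(labels)
  if (length(counts) < 2L) abort("both classes must be present")
  min(counts) / length(labels)
}
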