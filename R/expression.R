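#' Expression matrix container
#'
#' A genes-by-samples numeric matrix together with per-sample metadata and a
#' record of which transform has been applied. The container tracks three
#' states: `"raw"` (TPM-like, non-negative), `"log2p1"` (after
#' `log2(x + 1)`), and `"zscore"` (each sample column standardised across
#' genes so downstream Euclidean distances are comparable between data
#' sources).
#'
#' Duplicate gene symbols are tolerated only in the `"raw"` state (as read
#' from annotation-mapped files); they must be collapsed with
#' [collapse_duplicate_symbols()] before transformation.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers). All values must be
#'   finite; missing cells are a hard error.
#' @param meta Optional data frame of per-sample metadata with columns
#'   `sample_id`, `source_class` (one of `"cell_line"`, `"tumor"`,
#'   `"normal"`), `tissue_type`, and optionally `subtype`. Rows are matched
#'   to matrix columns by `sample_id`.
#' @param transform Transform state of `values`; one of `"raw"`,
#'   `"log2p1"`, `"zscore"`.
#' @return An object of class `expr_matrix`.
#' @seealso [read_expression()], [transform_log2p1()], [zscore_samples()]
#' @export
expr_matrix <- function(values, meta = NULL,
                        transform = c("raw", "log2p1", "zscore")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix is empty", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyNA(values) || !all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  }
  if (transform != "raw" && anyDuplicated(rownames(values))) {
    stop("duplicate gene symbols must be collapsed before transformation",
         call. = FALSE)
  }
  meta <- normalize_sample_meta(meta, colnames(values))
  structure(list(values = values, meta = meta, transform = transform),
            class = "expr_matrix")
}

normalize_sample_meta <- function(meta, sample_ids) {
  if (is.null(meta)) {
    return(tibble::tibble(sample_id = sample_ids,
                          source_class = NA_character_,
                          tissue_type = NA_character_,
                          subtype = NA_character_))
  }
  meta <- tibble::as_tibble(meta)
  if (!"sample_id" %in% names(meta)) {
    stop("sample metadata must have a `sample_id` column", call. = FALSE)
  }
  missing <- setdiff(sample_ids, meta$sample_id)
  if (length(missing)) {
    stop(sprintf("metadata missing for %d sample(s), e.g. '%s'",
                 length(missing), missing[1L]), call. = FALSE)
  }
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  for (col in c("source_class", "tissue_type", "subtype")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  meta
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, transform = %s\n",
              nrow(x$values), ncol(x$values), x$transform))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' Read an expression matrix from TSV or GCT text
#'
#' Reads a genes-by-samples expression matrix. Two dialects are supported:
#' plain TSV (first column gene symbols, header row of sample identifiers)
#' and GCT 1.2 (a `#1.2` version line, a dimensions line, then a table whose
#' first two columns are `Name` and `Description`). Values are returned in
#' the `"raw"` transform state; duplicate symbols are *not* collapsed (see
#' [collapse_duplicate_symbols()]).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension/sniffing), `"tsv"`, or `"gct"`.
#' @param meta Optional per-sample metadata, see [expr_matrix()].
#' @return An [expr_matrix()] with `transform = "raw"`.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"),
                            meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("expression file not found: '%s'", path), call. = FALSE)
  }
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^#1\\.2", first) || grepl("\\.gct$", path)) "gct"
              else "tsv"
  }
  if (format == "gct") read_expression_gct(path, meta)
  else read_expression_tsv(path, meta)
}

read_expression_tsv <- function(path, meta = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 2L) {
    stop(sprintf("malformed expression TSV '%s': need a gene column plus at least one sample column",
                 path), call. = FALSE)
  }
  values <- parse_numeric_block(df[, -1L, drop = FALSE], df[[1L]], path)
  expr_matrix(values, meta = meta, transform = "raw")
}

read_expression_gct <- function(path, meta = NULL) {
  header <- readLines(path, n = 2L)
  if (length(header) < 2L || !grepl("^#1\\.2", header[1L])) {
    stop(sprintf("malformed GCT '%s': first line must be '#1.2'", path),
         call. = FALSE)
  }
  dims <- suppressWarnings(as.integer(strsplit(header[2L], "\t")[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2])) {
    stop(sprintf("malformed GCT '%s': second line must give dimensions", path),
         call. = FALSE)
  }
  df <- readr::read_tsv(path, skip = 2L,
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("Name", "Description"))) {
    stop(sprintf("malformed GCT '%s': expected Name/Description columns", path),
         call. = FALSE)
  }
  if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L]) {
    stop(sprintf("malformed GCT '%s': dimension line says %d x %d but table is %d x %d",
                 path, dims[1L], dims[2L], nrow(df), ncol(df) - 2L),
         call. = FALSE)
  }
  values <- parse_numeric_block(df[, -(1:2), drop = FALSE], df[[1L]], path)
  expr_matrix(values, meta = meta, transform = "raw")
}

parse_numeric_block <- function(df, gene_ids, path) {
  chr <- as.matrix(df)
  num <- suppressWarnings(matrix(as.numeric(chr), nrow = nrow(chr)))
  bad <- is.na(num)
  if (any(bad)) {
    loc <- which(bad, arr.ind = TRUE)[1L, ]
    val <- chr[loc[1L], loc[2L]]
    stop(sprintf("parse error in '%s': non-numeric value '%s' at gene '%s' (row %d), sample '%s'",
                 path, if (is.na(val)) "NA" else val, gene_ids[loc[1L]],
                 loc[1L], colnames(df)[loc[2L]]), call. = FALSE)
  }
  dimnames(num) <- list(gene_ids, colnames(df))
  num
}

#' Write an expression matrix as TSV or GCT text
#'
#' Values are written with full double precision so that a write/read
#' round trip reproduces the matrix exactly.
#'
#' @param x An [expr_matrix()].
#' @param path Output path.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (format == "tsv") {
    df <- tibble::as_tibble(v, rownames = "gene")
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    df <- tibble::as_tibble(v, rownames = "Name")
    df <- tibble::add_column(df, Description = df$Name, .after = "Name")
    writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  invisible(path)
}

#' Collapse duplicate gene symbols by row averaging
#'
#' When several annotation entries map to the same gene symbol, their raw
#' expression rows are replaced by a single row holding their arithmetic
#' mean. Gene order follows first occurrence. Must be applied before any
#' transform.
#'
#' @param x An [expr_matrix()] with `transform = "raw"`.
#' @return An [expr_matrix()] with unique gene symbols.
#' @export
collapse_duplicate_symbols <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$transform != "raw") {
    stop("duplicate symbols must be collapsed on raw values", call. = FALSE)
  }
  v <- x$values
  if (!anyDuplicated(rownames(v))) return(x)
  grp <- factor(rownames(v), levels = unique(rownames(v)))
  summed <- rowsum(v, grp, reorder = FALSE)
  counts <- as.integer(table(grp)[levels(grp)])
  collapsed <- summed / counts
  rownames(collapsed) <- levels(grp)
  expr_matrix(collapsed, meta = x$meta, transform = "raw")
}

#' Apply the log2(x + 1) transform
#'
#' @param x An [expr_matrix()] with `transform = "raw"` and non-negative
#'   values (TPM-like).
#' @return An [expr_matrix()] with `transform = "log2p1"`.
#' @export
transform_log2p1 <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$transform != "raw") {
    stop("log2(x + 1) expects raw expression values", call. = FALSE)
  }
  if (anyDuplicated(rownames(x$values))) {
    stop("collapse duplicate gene symbols before transforming", call. = FALSE)
  }
  if (any(x$values < 0)) {
    bad <- which(x$values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value at gene '%s', sample '%s': log2(x + 1) requires x >= 0",
                 rownames(x$values)[bad[1L]], colnames(x$values)[bad[2L]]),
         call. = FALSE)
  }
  expr_matrix(log2(x$values + 1), meta = x$meta, transform = "log2p1")
}

#' Standardise each sample column across genes (per-sample Z-scores)
#'
#' Centres and scales every sample column so that, across genes, it has
#' mean 0 and standard deviation 1. This puts samples from different data
#' sources (cell lines, tumours, normal tissue) on a common scale before
#' gene-set intersection and neighbour search. Z-scores are computed once,
#' over the full gene universe, and are deliberately *not* recomputed after
#' any later gene-set intersection.
#'
#' @param x An [expr_matrix()] with `transform = "log2p1"`.
#' @param denominator `"n-1"` (sample standard deviation, the default) or
#'   `"n"` (population form).
#' @return An [expr_matrix()] with `transform = "zscore"`.
#' @export
zscore_samples <- function(x, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(x, "expr_matrix"))
  if (x$transform != "log2p1") {
    stop("Z-scoring expects log2(x + 1)-transformed values", call. = FALSE)
  }
  v <- x$values
  g <- nrow(v)
  if (g < 2L) stop("Z-scoring needs at least two genes", call. = FALSE)
  mu <- colMeans(v)
  centred <- sweep(v, 2L, mu, "-")
  ss <- colSums(centred^2)
  denom <- if (denominator == "n-1") g - 1L else g
  sds <- sqrt(ss / denom)
  degenerate <- sds <= 0
  if (any(degenerate)) {
    stop(sprintf("degenerate sample(s) with constant expression: %s",
                 paste(colnames(v)[degenerate], collapse = ", ")),
         call. = FALSE)
  }
  z <- sweep(centred, 2L, sds, "/")
  expr_matrix(z, meta = x$meta, transform = "zscore")
}

#' Run the full expression preparation chain
#'
#' Convenience wrapper: collapse duplicate symbols, apply log2(x + 1), then
#' per-sample Z-scores.
#'
#' @inheritParams zscore_samples
#' @param x An [expr_matrix()] with `transform = "raw"`.
#' @return An [expr_matrix()] with `transform = "zscore"`.
#' @export
prepare_expression <- function(x, denominator = c("n-1", "n")) {
  x |>
    collapse_duplicate_symbols() |>
    transform_log2p1() |>
    zscore_samples(denominator = denominator)
}
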