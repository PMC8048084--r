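#' Read a drug-response table
#'
#' Expects a TSV with columns `drug_id`, `drug_name`, `cell_line_id`,
#' `ln_ic50`, `release` (and optionally `putative_target`). Responses are
#' natural-log IC50 values; release is `"GDSC1"` or `"GDSC2"`.
#'
#' @param path Path to the TSV file.
#' @return A tibble of per-(drug, cell line) responses.
#' @export
read_drug_response <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("drug-response file not found: '%s'", path), call. = FALSE)
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  as_drug_response(df)
}

#' Validate a drug-response table
#'
#' @param df A data frame with columns `drug_id`, `drug_name`,
#'   `cell_line_id`, `ln_ic50`, `release`.
#' @return A validated tibble.
#' @export
as_drug_response <- function(df) {
  df <- tibble::as_tibble(df)
  needed <- c("drug_id", "drug_name", "cell_line_id", "ln_ic50", "release")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop(sprintf("drug-response table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$ln_ic50 <- as.numeric(df$ln_ic50)
  if (anyNA(df$ln_ic50) || !all(is.finite(df$ln_ic50))) {
    stop("non-finite ln_ic50 value in drug-response table", call. = FALSE)
  }
  if (!all(df$release %in% c("GDSC1", "GDSC2"))) {
    stop("release must be 'GDSC1' or 'GDSC2'", call. = FALSE)
  }
  df
}

#' Merge two drug-response releases, preferring the second
#'
#' Takes the union of the two tables; where a (drug_id, cell_line_id) pair
#' occurs in both releases, only the GDSC2 record is kept, as advised by
#' GDSC. Compounds sharing a name but carrying distinct drug identifiers in
#' the two releases are deliberately kept as distinct drugs.
#'
#' @param t1 Response tibble tagged `GDSC1`.
#' @param t2 Response tibble tagged `GDSC2`.
#' @return A merged response tibble with at most one record per
#'   (drug_id, cell_line_id).
#' @export
merge_drug_releases <- function(t1, t2) {
  t1 <- as_drug_response(t1)
  t2 <- as_drug_response(t2)
  if (!all(t1$release == "GDSC1")) {
    stop("first table must be tagged GDSC1 throughout", call. = FALSE)
  }
  if (!all(t2$release == "GDSC2")) {
    stop("second table must be tagged GDSC2 throughout", call. = FALSE)
  }
  for (tab in list(GDSC1 = t1, GDSC2 = t2)) {
    dup <- duplicated(tab[, c("drug_id", "cell_line_id")])
    if (any(dup)) {
      stop(sprintf("duplicate (drug_id, cell_line_id) pair within release %s: drug %s, cell line %s",
                   tab$release[1L], tab$drug_id[which(dup)[1L]],
                   tab$cell_line_id[which(dup)[1L]]), call. = FALSE)
    }
  }
  keep1 <- dplyr::anti_join(t1, t2, by = c("drug_id", "cell_line_id"))
  dplyr::bind_rows(t2, keep1)
}

#' Per-drug modelling dataset
#'
#' Restricts a Z-scored expression matrix to the cell lines with a response
#' for one drug, aligning a ln(IC50) vector to the columns. Sample order is
#' lexicographic by identifier so all downstream randomness depends only on
#' seeds.
#'
#' @param expression An [expr_matrix()] with `transform = "zscore"` whose
#'   columns are cell lines.
#' @param responses A (merged) drug-response tibble.
#' @param drug Drug identifier to extract.
#' @return A `drug_dataset`: list with elements `drug_id`, `drug_name`,
#'   `X` (genes x cell lines Z-score matrix), `y` (aligned ln(IC50)),
#'   `sample_ids`, `gene_ids`, and optional `external`/`external_meta`.
#' @export
build_drug_dataset <- function(expression, responses, drug) {
  stopifnot(inherits(expression, "expr_matrix"))
  if (expression$transform != "zscore") {
    stop("expression must be Z-scored before building a drug dataset",
         call. = FALSE)
  }
  responses <- as_drug_response(responses)
  rec <- responses[responses$drug_id == as.character(drug), , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop(sprintf("no responses for drug '%s'", drug), call. = FALSE)
  }
  if (anyDuplicated(rec$cell_line_id)) {
    stop(sprintf("multiple responses per cell line for drug '%s'; merge releases first",
                 drug), call. = FALSE)
  }
  shared <- sort(intersect(colnames(expression$values), rec$cell_line_id))
  if (length(shared) == 0L) {
    stop(sprintf("no overlap between expression samples and response cell lines for drug '%s'",
                 drug), call. = FALSE)
  }
  X <- expression$values[, shared, drop = FALSE]
  y <- rec$ln_ic50[match(shared, rec$cell_line_id)]
  structure(list(drug_id = as.character(drug),
                 drug_name = rec$drug_name[1L],
                 X = X, y = y,
                 sample_ids = shared,
                 gene_ids = rownames(X),
                 external = NULL,
                 external_meta = NULL),
            class = "drug_dataset")
}

#' @export
print.drug_dataset <- function(x, ...) {
  cat(sprintf("<drug_dataset> drug %s (%s): %d genes x %d cell lines%s\n",
              x$drug_id, x$drug_name, length(x$gene_ids),
              length(x$sample_ids),
              if (is.null(x$external)) "" else
                sprintf(", %d external samples", ncol(x$external))))
  invisible(x)
}

#' Attach external (tumour / normal) samples to a drug dataset
#'
#' Reduces the gene universe of the cell-line matrix and the external matrix
#' to their common genes (kept in the dataset's gene order) and stores the
#' external columns for transfer prediction. Z-scores were computed over the
#' full transcriptome of each sample and are *not* recomputed after the
#' intersection.
#'
#' @param dataset A `drug_dataset` from [build_drug_dataset()].
#' @param external An [expr_matrix()] with `transform = "zscore"` holding
#'   tumour/normal samples with metadata.
#' @return The dataset with `X` restricted to common genes and
#'   `external`/`external_meta` populated.
#' @export
attach_external <- function(dataset, external) {
  stopifnot(inherits(dataset, "drug_dataset"),
            inherits(external, "expr_matrix"))
  if (external$transform != "zscore") {
    stop("external expression must be Z-scored", call. = FALSE)
  }
  common <- dataset$gene_ids[dataset$gene_ids %in% rownames(external$values)]
  if (length(common) == 0L) {
    stop("no common genes between drug dataset and external samples",
         call. = FALSE)
  }
  dataset$X <- dataset$X[common, , drop = FALSE]
  dataset$gene_ids <- common
  dataset$external <- external$values[common, , drop = FALSE]
  dataset$external_meta <- external$meta
  dataset
}
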