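#' Impute ln(IC50) for external tumour / normal samples
#'
#' Every external sample is treated as an additional "test" sample in each
#' Monte-Carlo run: run `r`'s best gene set defines the subspace, the run's
#' *training* cell lines form the neighbour pool, and the prediction is the
#' mean observed ln(IC50) of the k nearest training neighbours. The final
#' value per sample is the mean over all runs, so every external sample has
#' `runs_contributing` equal to the number of runs.
#'
#' @param model A `drug_model` from [fit_drug_model()].
#' @param dataset The `drug_dataset` the model was fitted on, with external
#'   samples attached via [attach_external()].
#' @return Tibble with columns `sample_id`, `source_class`, `tissue_type`,
#'   `subtype`, `predicted_ln_ic50`, `runs_contributing`.
#' @export
predict_external <- function(model, dataset) {
  stopifnot(inherits(model, "drug_model"), inherits(dataset, "drug_dataset"))
  if (is.null(dataset$external)) {
    stop("no external samples attached to this dataset; see attach_external()",
         call. = FALSE)
  }
  if (!identical(dataset$gene_ids, model$gene_ids)) {
    stop("dataset gene universe differs from the one the model was fitted on",
         call. = FALSE)
  }
  ext <- dataset$external
  m <- ncol(ext)
  X <- dataset$X
  y <- dataset$y
  k <- model$config$k
  acc <- numeric(m)
  for (r in seq_len(model$runs)) {
    tr <- model$plan$partitions[[r]]$train
    genes <- model$run_results[[r]]$best_genes
    acc <- acc + cpp_knn_predict(X[genes, tr, drop = FALSE], y[tr],
                                 ext[genes, , drop = FALSE], k,
                                 integer(m))
  }
  meta <- dataset$external_meta
  meta <- meta[match(colnames(ext), meta$sample_id), , drop = FALSE]
  tibble::tibble(sample_id = colnames(ext),
                 source_class = meta$source_class,
                 tissue_type = meta$tissue_type,
                 subtype = meta$subtype,
                 predicted_ln_ic50 = acc / model$runs,
                 runs_contributing = model$runs)
}

#' Tumour-type specificity by the median-of-medians rule
#'
#' Computes each tumour type's median predicted ln(IC50) and the median of
#' those medians; a type is flagged as specifically sensitive when its
#' median lies more than `threshold_log_units` below the median of medians
#' (one log unit corresponds to an approximately 2.7-fold lower IC50).
#'
#' @param predictions Prediction tibble from [predict_external()] (tumour
#'   rows are used; rows with `source_class == "normal"` are dropped).
#' @param threshold_log_units Flagging threshold, default 1.0.
#' @return Tibble with one row per tumour type: `tissue_type`, `n`,
#'   `median_pred`, `median_of_medians`, `delta` (median - median of
#'   medians) and `flagged`.
#' @export
tumor_type_specificity <- function(predictions, threshold_log_units = 1.0) {
  preds <- dplyr::filter(predictions,
                         is.na(.data$source_class) |
                           .data$source_class != "normal")
  if (dplyr::n_distinct(preds$tissue_type) < 2L) {
    stop("need at least two tumour types", call. = FALSE)
  }
  per_type <- preds |>
    dplyr::group_by(.data$tissue_type) |>
    dplyr::summarise(n = dplyr::n(),
                     median_pred = median(.data$predicted_ln_ic50),
                     .groups = "drop")
  mom <- median(per_type$median_pred)
  per_type |>
    dplyr::mutate(median_of_medians = mom,
                  delta = .data$median_pred - mom,
                  flagged = .data$median_pred < mom - threshold_log_units)
}

#' Tumour-versus-normal sensitivity comparison
#'
#' For every tissue type with more than `min_normals` normal samples,
#' compares the median predicted ln(IC50) of tumour samples with that of
#' normal samples from the same tissue; the type is flagged when the tumour
#' median lies more than `threshold_log_units` below the normal median.
#' Types with too few normal samples are reported as ineligible, not
#' flagged.
#'
#' @param predictions Prediction tibble from [predict_external()] containing
#'   both tumour and normal rows sharing `tissue_type` values.
#' @param min_normals Minimum normal-sample count; eligibility is strict
#'   (`> min_normals`), default 20.
#' @param threshold_log_units Flagging threshold, default 1.0.
#' @return Tibble per tissue type: counts, medians, `delta`
#'   (tumour - normal), `eligible`, `flagged`.
#' @export
tumor_to_normal <- function(predictions, min_normals = 20L,
                            threshold_log_units = 1.0) {
  by_type <- predictions |>
    dplyr::filter(.data$source_class %in% c("tumor", "normal")) |>
    dplyr::group_by(.data$tissue_type) |>
    dplyr::summarise(
      n_tumor = sum(.data$source_class == "tumor"),
      n_normal = sum(.data$source_class == "normal"),
      median_tumor = median(.data$predicted_ln_ic50[.data$source_class == "tumor"]),
      median_normal = median(.data$predicted_ln_ic50[.data$source_class == "normal"]),
      .groups = "drop")
  by_type |>
    dplyr::mutate(delta = .data$median_tumor - .data$median_normal,
                  eligible = .data$n_normal > min_normals & .data$n_tumor > 0L,
                  flagged = .data$eligible &
                    .data$median_tumor <
                      .data$median_normal - threshold_log_units)
}

#' Subtype-differential sensitivity
#'
#' For tumour samples carrying subtype labels, compares each subtype's
#' median predicted ln(IC50) against the median of the subtype medians and
#' flags subtypes whose median lies more than `threshold_log_units` below
#' it (0.5 log units corresponds to a 1.65-fold difference). The subtype
#' with the minimum median is marked.
#'
#' @param predictions Prediction tibble from [predict_external()]; rows
#'   without a subtype label are dropped.
#' @param threshold_log_units Flagging threshold, default 0.5.
#' @return Tibble per subtype: `subtype`, `n`, `median_pred`,
#'   `median_of_medians`, `delta`, `flagged`, `is_minimum`.
#' @export
subtype_differential <- function(predictions, threshold_log_units = 0.5) {
  preds <- dplyr::filter(predictions, !is.na(.data$subtype))
  if (dplyr::n_distinct(preds$subtype) < 2L) {
    stop("need at least two subtypes", call. = FALSE)
  }
  per_subtype <- preds |>
    dplyr::group_by(.data$subtype) |>
    dplyr::summarise(n = dplyr::n(),
                     median_pred = median(.data$predicted_ln_ic50),
                     .groups = "drop")
  mom <- median(per_subtype$median_pred)
  per_subtype |>
    dplyr::mutate(median_of_medians = mom,
                  delta = .data$median_pred - mom,
                  flagged = .data$median_pred < mom - threshold_log_units,
                  is_minimum = .data$median_pred == min(.data$median_pred))
}

#' Variant classes that count as a gene mutation
#'
#' A sample is considered mutated in a gene when any of these MAF variant
#' classes is recorded for that gene; all other classes (e.g. silent) are
#' ignored.
#'
#' @return Character vector of qualifying variant classes.
#' @export
qualifying_variant_classes <- function() {
  c("nonsense mutation", "missense mutation", "frame shift deletion",
    "frame shift insertion", "In frame deletion", "splice site mutation")
}

#' Collapse a long mutation table to per-(sample, gene) indicators
#'
#' @param mutations Long-format tibble with columns `sample_id`, `gene`,
#'   `variant_class` (MAF-derived). Classes are matched case-insensitively
#'   with underscores treated as spaces.
#' @return Tibble `sample_id`, `gene` with one row per mutated pair.
#' @export
mutation_indicators <- function(mutations) {
  mutations <- tibble::as_tibble(mutations)
  needed <- c("sample_id", "gene", "variant_class")
  if (!all(needed %in% names(mutations))) {
    stop("mutation table needs columns sample_id, gene, variant_class",
         call. = FALSE)
  }
  norm <- tolower(gsub("_", " ", mutations$variant_class))
  keep <- norm %in% tolower(qualifying_variant_classes())
  dplyr::distinct(mutations[keep, c("sample_id", "gene")])
}

#' Mutation-group association with predicted sensitivity
#'
#' Within each tumour type, splits samples into carriers and non-carriers of
#' a mutation in each gene and compares predicted ln(IC50) between the two
#' groups with a two-sided Wilcoxon rank-sum test. A (gene, tumour type)
#' pair is analysed only when at least `min_mutated` samples carry the
#' mutation; ineligible pairs are skipped. The exact null distribution is
#' used for small untied groups, otherwise the normal approximation with
#' tie correction.
#'
#' @param predictions Prediction tibble from [predict_external()] (tumour
#'   rows are used).
#' @param mutations Either a long MAF-style table (`sample_id`, `gene`,
#'   `variant_class`) or a pre-filtered indicator table (`sample_id`,
#'   `gene`).
#' @param min_mutated Minimum carrier count per (gene, type), default 5.
#' @param adjust Multiple-testing adjustment for the returned
#'   `p_adjusted` column; `"none"` (default) or `"BH"`.
#' @return Tibble per eligible (gene, tissue type): `gene`, `tissue_type`,
#'   `n_mutated`, `n_wildtype`, `p_value`, `p_adjusted`, `direction` (sign
#'   of mutated-minus-wildtype median difference).
#' @export
mutation_association <- function(predictions, mutations, min_mutated = 5L,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  mutations <- tibble::as_tibble(mutations)
  if ("variant_class" %in% names(mutations)) {
    mutations <- mutation_indicators(mutations)
  }
  preds <- dplyr::filter(predictions,
                         is.na(.data$source_class) |
                           .data$source_class != "normal")
  genes <- unique(mutations$gene)
  types <- unique(preds$tissue_type)
  rows <- list()
  for (g in genes) {
    carriers <- mutations$sample_id[mutations$gene == g]
    for (tt in types) {
      sub <- preds[preds$tissue_type == tt, , drop = FALSE]
      mut <- sub$predicted_ln_ic50[sub$sample_id %in% carriers]
      wt <- sub$predicted_ln_ic50[!sub$sample_id %in% carriers]
      if (length(mut) < min_mutated || length(wt) < 1L) next
      p <- ranksum_p(mut, wt)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = g, tissue_type = tt,
        n_mutated = length(mut), n_wildtype = length(wt),
        p_value = p,
        direction = sign(median(mut) - median(wt)))
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(gene = character(), tissue_type = character(),
                          n_mutated = integer(), n_wildtype = integer(),
                          p_value = numeric(), p_adjusted = numeric(),
                          direction = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- if (adjust == "BH") {
    stats::p.adjust(out$p_value, method = "BH")
  } else {
    out$p_value
  }
  out[, c("gene", "tissue_type", "n_mutated", "n_wildtype",
          "p_value", "p_adjusted", "direction")]
}

# Two-sided rank-sum p-value: exact for small untied groups, normal
# approximation with tie correction otherwise.
ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)  # fully tied: no evidence
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- !ties && min(length(x), length(y)) <= 8L
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact))
  min(res$p.value, 1)
}

#' Convert a log-unit difference in ln(IC50) to a fold change
#'
#' Differences in ln(IC50) are natural-log units, so a difference of
#' `delta` corresponds to an `exp(delta)`-fold change in IC50: one log unit
#' is about a 2.7-fold difference and 0.5 log units about 1.65-fold.
#'
#' @param delta Difference in natural-log units.
#' @return `exp(delta)`.
#' @export
fold_change_from_log_units <- function(delta) {
  stopifnot(all(is.finite(delta)))
  exp(delta)
}
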