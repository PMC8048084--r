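#' Monte-Carlo train/test partition plan
#'
#' Draws `runs` independent uniform partitions of `n_samples` indices into a
#' training set (by default 90%) and a testing set (10%). The test size is
#' `round(test_fraction * n_samples)` with a minimum of 1. Over the plan,
#' each sample is expected to land in about `runs * test_fraction` test sets.
#'
#' @param n_samples Number of samples (cell lines).
#' @param runs Number of repeats (R), default 100.
#' @param test_fraction Fraction held out per repeat, default 0.1.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `partition_plan` with elements `partitions`
#'   (list of `list(train=, test=)` integer index pairs), `runs`,
#'   `test_fraction`, `n`.
#' @export
make_partitions <- function(n_samples, runs = 100L, test_fraction = 0.1,
                            seed = NULL) {
  n_samples <- as.integer(n_samples)
  runs <- as.integer(runs)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  n_test <- max(1L, as.integer(round(test_fraction * n_samples)))
  if (n_test >= n_samples) {
    stop(sprintf("too few samples (%d) for a nonempty training set at test fraction %.2f",
                 n_samples, test_fraction), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  partitions <- lapply(seq_len(runs), function(r) {
    test <- sort(sample.int(n_samples, n_test))
    list(train = setdiff(seq_len(n_samples), test), test = test)
  })
  structure(list(partitions = partitions, runs = runs,
                 test_fraction = test_fraction, n = n_samples),
            class = "partition_plan")
}

#' Fit the GA/kNN model for one drug under Monte-Carlo cross-validation
#'
#' For each of `runs` random 90/10 partitions: the genetic algorithm is run
#' on the training cell lines to find the gene set minimising leave-one-out
#' kNN squared error; that set then predicts each test sample by averaging
#' the observed ln(IC50) of its k nearest training neighbours, and each
#' training sample by leave-one-out within the training set. Per-sample
#' predictions are averaged over the runs in which the sample appeared in
#' the corresponding set; the Pearson and Spearman correlations between
#' observed and aggregated test predictions determine predictability.
#'
#' Run `r` is seeded with `seed + r`, so the whole result is a deterministic
#' function of (dataset, config, runs, seed).
#'
#' @param dataset A `drug_dataset` from [build_drug_dataset()].
#' @param runs Number of Monte-Carlo repeats (R), default 100.
#' @param config A [ga_config()].
#' @param test_fraction Held-out fraction per repeat, default 0.1.
#' @param seed Integer base seed (default 1).
#' @param threshold Predictability threshold on both correlations,
#'   default 0.4.
#' @return An object of class `drug_model`; see [tidy()], [glance()],
#'   [augment()] and [predict_external()].
#' @export
fit_drug_model <- function(dataset, runs = 100L, config = ga_config(),
                           test_fraction = 0.1, seed = 1L,
                           threshold = 0.4) {
  stopifnot(inherits(dataset, "drug_dataset"))
  n <- length(dataset$sample_ids)
  G <- length(dataset$gene_ids)
  runs <- as.integer(runs)
  seed <- as.integer(seed)
  plan <- make_partitions(n, runs = runs, test_fraction = test_fraction,
                          seed = seed)
  X <- dataset$X
  y <- dataset$y
  k <- config$k
  test_sum <- numeric(n); test_cnt <- integer(n)
  train_sum <- numeric(n); train_cnt <- integer(n)
  sel_count <- integer(G)
  run_results <- vector("list", runs)
  for (r in seq_len(runs)) {
    part <- plan$partitions[[r]]
    tr <- part$train; te <- part$test
    ga <- evolve(X[, tr, drop = FALSE], y[tr], config = config,
                 seed = seed + r)
    genes <- ga$best_genes
    pool <- X[genes, tr, drop = FALSE]
    test_pred <- cpp_knn_predict(pool, y[tr],
                                 X[genes, te, drop = FALSE], k,
                                 integer(length(te)))
    train_pred <- cpp_loo_predict(pool, y[tr], k)
    test_sum[te] <- test_sum[te] + test_pred
    test_cnt[te] <- test_cnt[te] + 1L
    train_sum[tr] <- train_sum[tr] + train_pred
    train_cnt[tr] <- train_cnt[tr] + 1L
    sel_count[genes] <- sel_count[genes] + 1L
    run_results[[r]] <- ga
  }
  pred_test <- ifelse(test_cnt > 0L, test_sum / test_cnt, NA_real_)
  pred_train <- ifelse(train_cnt > 0L, train_sum / train_cnt, NA_real_)
  seen <- test_cnt > 0L
  rho <- tryCatch(correlations(y[seen], pred_test[seen]),
                  error = function(e)
                    tibble::tibble(rho_pearson = NA_real_,
                                   rho_spearman = NA_real_))
  predictable <- if (anyNA(rho)) NA else
    classify_predictable(rho$rho_pearson, rho$rho_spearman,
                         threshold = threshold)
  structure(list(drug_id = dataset$drug_id,
                 drug_name = dataset$drug_name,
                 sample_ids = dataset$sample_ids,
                 gene_ids = dataset$gene_ids,
                 observed = y,
                 pred_test = pred_test,
                 pred_train = pred_train,
                 n_test_runs = test_cnt,
                 n_train_runs = train_cnt,
                 rho_pearson_test = rho$rho_pearson,
                 rho_spearman_test = rho$rho_spearman,
                 predictable = predictable,
                 threshold = threshold,
                 selection_count = setNames(sel_count, dataset$gene_ids),
                 run_results = run_results,
                 plan = plan,
                 config = config,
                 runs = runs,
                 seed = seed),
            class = "drug_model")
}

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf("<drug_model> drug %s: %d runs, rho_P = %.3f, rho_S = %.3f, predictable = %s\n",
              x$drug_id, x$runs, x$rho_pearson_test, x$rho_spearman_test,
              x$predictable))
  invisible(x)
}

#' Average per-run predictions per sample
#'
#' Each run contributes predictions for a subset of samples; the aggregate
#' for a sample is the arithmetic mean over the runs in which it appeared.
#' Samples that appeared in no run are absent from the result rather than
#' imputed.
#'
#' @param per_run List (one element per run) of named numeric vectors of
#'   predictions, names identifying samples.
#' @return Tibble with columns `sample_id`, `predicted`,
#'   `runs_contributing`.
#' @export
aggregate_predictions <- function(per_run) {
  flat <- unlist(per_run, use.names = TRUE)
  if (is.null(names(flat)) || any(names(flat) == "")) {
    stop("per-run predictions must be named by sample", call. = FALSE)
  }
  ids <- names(flat)
  first <- unique(ids)
  means <- tapply(flat, factor(ids, levels = first), mean)
  counts <- tapply(flat, factor(ids, levels = first), length)
  tibble::tibble(sample_id = first,
                 predicted = as.numeric(means),
                 runs_contributing = as.integer(counts))
}

#' Pearson and Spearman correlations between observed and predicted values
#'
#' Spearman is the product-moment correlation of mid-ranks (average ranks
#' for ties).
#'
#' @param obs,pred Numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return A one-row tibble with `rho_pearson` and `rho_spearman`.
#' @export
correlations <- function(obs, pred) {
  if (length(obs) != length(pred)) {
    stop("`obs` and `pred` must have the same length", call. = FALSE)
  }
  if (length(obs) < 3L) {
    stop("need at least 3 paired values for a correlation", call. = FALSE)
  }
  if (sd(obs) == 0 || sd(pred) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  tibble::tibble(rho_pearson = cor(obs, pred, method = "pearson"),
                 rho_spearman = cor(obs, pred, method = "spearman"))
}

#' Classify a drug as predictable
#'
#' A drug is predictable when both the Pearson and the Spearman correlation
#' between observed and aggregated test-set predictions reach the threshold
#' (boundary inclusive).
#'
#' @param rho_pearson,rho_spearman Finite correlation coefficients.
#' @param threshold Threshold applied to both, default 0.4.
#' @return Logical scalar.
#' @export
classify_predictable <- function(rho_pearson, rho_spearman,
                                 threshold = 0.4) {
  stopifnot(is.finite(rho_pearson), is.finite(rho_spearman))
  rho_pearson >= threshold && rho_spearman >= threshold
}

#' Gene-importance by selection frequency
#'
#' Counts, for every gene, how many of the per-run best gene sets contain
#' it, and expresses the count relative to the chance expectation
#' `runs * d / G`.
#'
#' @param x A `drug_model`, or a list of `ga_run` objects (then `n_genes`
#'   and `gene_ids` may be given).
#' @param n_genes Gene-universe size G (taken from the model when `x` is a
#'   `drug_model`).
#' @param gene_ids Optional gene names.
#' @return Tibble with columns `gene`, `count`, `frequency` (count / runs)
#'   and `fold_over_chance`, sorted by decreasing count.
#' @export
selection_frequencies <- function(x, n_genes = NULL, gene_ids = NULL) {
  if (inherits(x, "drug_model")) {
    counts <- as.integer(x$selection_count)
    gene_ids <- names(x$selection_count)
    runs <- x$runs
    d <- x$config$d
    n_genes <- length(counts)
  } else {
    if (is.null(n_genes)) {
      stop("`n_genes` is required when passing a list of GA runs",
           call. = FALSE)
    }
    counts <- integer(n_genes)
    for (run in x) counts[run$best_genes] <- counts[run$best_genes] + 1L
    runs <- length(x)
    d <- length(x[[1L]]$best_genes)
    if (is.null(gene_ids)) gene_ids <- as.character(seq_len(n_genes))
  }
  chance <- chance_frequency(runs, d, n_genes)
  out <- tibble::tibble(gene = gene_ids, count = counts,
                        frequency = counts / runs,
                        fold_over_chance = counts / chance)
  dplyr::arrange(out, dplyr::desc(.data$count), .data$gene)
}

#' Chance selection frequency
#'
#' Expected number of times a single gene enters `runs` uniformly random
#' gene sets of size `d` drawn from `n_genes` genes: `runs * d / n_genes`.
#' With 100 runs of 30-gene sets over a 19,163-gene transcriptome this is
#' 0.155, so a gene selected more than 20 times is over 100-fold above
#' chance.
#'
#' @param runs Number of repeats R.
#' @param d Gene-set size.
#' @param n_genes Gene-universe size G.
#' @return The expected count, a scalar.
#' @export
chance_frequency <- function(runs, d, n_genes) {
  stopifnot(runs >= 1, d >= 1, n_genes >= d)
  runs * d / n_genes
}

#' Spearman correlation between one gene's expression and drug response
#'
#' The single-gene biomarker screen: rank correlation between a gene's
#' expression across cell lines and the observed ln(IC50), with a flag for
#' absolute correlations at or above a cutoff.
#'
#' @param expr_row Numeric vector of one gene's expression over cell lines.
#' @param y Numeric vector of observed ln(IC50), same length.
#' @param cutoff Flagging cutoff on `|rho_s|`, default 0.3.
#' @return A one-row tibble with `rho_spearman` and `flagged`.
#' @export
gene_drug_response_correlation <- function(expr_row, y, cutoff = 0.3) {
  if (length(expr_row) != length(y)) {
    stop("expression and response vectors must have the same length",
         call. = FALSE)
  }
  if (length(y) < 3L) {
    stop("need at least 3 cell lines", call. = FALSE)
  }
  if (sd(expr_row) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rho <- cor(expr_row, y, method = "spearman")
  tibble::tibble(rho_spearman = rho, flagged = abs(rho) >= cutoff)
}

#' Screen every gene against the drug response
#'
#' @param dataset A `drug_dataset`.
#' @param cutoff Flagging cutoff on `|rho_s|`, default 0.3.
#' @return Tibble with one row per gene: `gene`, `rho_spearman`, `flagged`.
#' @export
gene_response_correlations <- function(dataset, cutoff = 0.3) {
  stopifnot(inherits(dataset, "drug_dataset"))
  ry <- rank(dataset$y)
  rx <- t(apply(dataset$X, 1L, rank))
  rho <- as.numeric(cor(t(rx), ry))
  tibble::tibble(gene = dataset$gene_ids, rho_spearman = rho,
                 flagged = abs(rho) >= cutoff)
}
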