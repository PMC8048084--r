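#' Tidy a fitted drug model into per-gene selection frequencies
#'
#' @param x A `drug_model` from [fit_drug_model()].
#' @param ... Unused.
#' @return Tibble `gene`, `count`, `frequency`, `fold_over_chance`, sorted
#'   by decreasing count.
#' @method tidy drug_model
#' @export
tidy.drug_model <- function(x, ...) {
  selection_frequencies(x)
}

#' One-row summary of a fitted drug model
#'
#' @param x A `drug_model`.
#' @param ... Unused.
#' @return Tibble with the drug identifier, problem sizes, correlations and
#'   the predictability call.
#' @method glance drug_model
#' @export
glance.drug_model <- function(x, ...) {
  tibble::tibble(drug_id = x$drug_id,
                 drug_name = x$drug_name,
                 n_samples = length(x$sample_ids),
                 n_genes = length(x$gene_ids),
                 runs = x$runs,
                 k = x$config$k,
                 d = x$config$d,
                 rho_pearson_test = x$rho_pearson_test,
                 rho_spearman_test = x$rho_spearman_test,
                 predictable = x$predictable,
                 mean_best_loss = mean(vapply(x$run_results,
                                              function(r) r$best_loss,
                                              numeric(1L))))
}

#' Per-sample observed and aggregated predicted values
#'
#' @param x A `drug_model`.
#' @param ... Unused.
#' @return Tibble `sample_id`, `observed`, `predicted_test`,
#'   `n_test_runs`, `predicted_train`, `n_train_runs`. Samples that never
#'   entered a test (or training) set have `NA` there rather than an
#'   imputed value.
#' @method augment drug_model
#' @export
augment.drug_model <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_ids,
                 observed = x$observed,
                 predicted_test = x$pred_test,
                 n_test_runs = x$n_test_runs,
                 predicted_train = x$pred_train,
                 n_train_runs = x$n_train_runs)
}

#' Observed versus predicted scatter plot for a fitted drug model
#'
#' @param object A `drug_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot drug_model
#' @export
autoplot.drug_model <- function(object, ...) {
  df <- augment.drug_model(object)
  df <- df[!is.na(df$predicted_test), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed,
                                   y = .data$predicted_test)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "observed ln(IC50)", y = "predicted ln(IC50) (test-set average)",
      title = sprintf("Drug %s", object$drug_id),
      subtitle = sprintf("rho_P = %.3f, rho_S = %.3f%s",
                         object$rho_pearson_test, object$rho_spearman_test,
                         if (object$predictable) " (predictable)" else ""))
}

#' Bar plot of the most frequently selected genes
#'
#' @param model A `drug_model`.
#' @param top_n Number of genes to display, default 20.
#' @return A ggplot object with a dashed line at the chance expectation.
#' @export
plot_selection_frequencies <- function(model, top_n = 20L) {
  freq <- head(selection_frequencies(model), top_n)
  chance <- chance_frequency(model$runs, model$config$d,
                             length(model$gene_ids))
  freq$gene <- factor(freq$gene, levels = rev(freq$gene))
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$count, y = .data$gene)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = chance, linetype = "dashed") +
    ggplot2::labs(x = sprintf("selection count (of %d runs)", model$runs),
                  y = NULL,
                  title = sprintf("Gene selection frequency, drug %s",
                                  model$drug_id))
}

#' Violin plot of predicted sensitivity by sample group
#'
#' @param predictions Prediction tibble from [predict_external()].
#' @param group Grouping column, default `"tissue_type"`.
#' @return A ggplot object with a solid line at the median of group medians
#'   and a dashed line one log unit below it.
#' @export
plot_predicted_by_group <- function(predictions, group = "tissue_type") {
  stopifnot(group %in% names(predictions))
  med <- tapply(predictions$predicted_ln_ic50, predictions[[group]], median)
  mom <- median(med)
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data[[group]],
                               y = .data$predicted_ln_ic50)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::geom_hline(yintercept = mom) +
    ggplot2::geom_hline(yintercept = mom - 1, linetype = "dashed") +
    ggplot2::stat_summary(fun = median, geom = "point", colour = "red") +
    ggplot2::labs(x = NULL, y = "predicted ln(IC50)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
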