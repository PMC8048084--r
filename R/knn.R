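#' k-nearest-neighbour regression prediction
#'
#' Predicts a response for one query profile as the arithmetic mean of the
#' observed responses of its `k` nearest pool samples under Euclidean
#' distance in the space spanned by the matrix rows (a gene set). An
#' optional pool column may be excluded (the query itself, for leave-one-out
#' use). Distance ties are broken deterministically by the lower pool column
#' index; distances are compared on the squared scale, which preserves the
#' neighbour ordering.
#'
#' @param pool Numeric matrix, d features x n pool samples.
#' @param values Numeric vector of n observed responses (ln(IC50)).
#' @param query Numeric vector of length d.
#' @param k Number of neighbours to average (default 3).
#' @param exclude Optional single pool column index to make ineligible.
#' @return The predicted response, always within the range of the eligible
#'   pool values.
#' @export
knn_regress <- function(pool, values, query, k = 3L, exclude = NULL) {
  pool <- as.matrix(pool)
  if (length(values) != ncol(pool)) {
    stop("`values` must have one entry per pool column", call. = FALSE)
  }
  if (length(query) != nrow(pool)) {
    stop("`query` length must match the pool feature dimension",
         call. = FALSE)
  }
  ex <- if (is.null(exclude)) 0L else as.integer(exclude)
  if (length(ex) != 1L || is.na(ex) || ex < 0L || ex > ncol(pool)) {
    stop("`exclude` must be NULL or a single valid pool column index",
         call. = FALSE)
  }
  cpp_knn_predict(pool, as.numeric(values),
                  matrix(as.numeric(query), ncol = 1L),
                  as.integer(k), ex)[1L]
}

#' Leave-one-out kNN predictions for every sample
#'
#' Element `i` of the result is the kNN prediction for column `i` with
#' column `i` itself excluded from the neighbour pool.
#'
#' @param X Numeric matrix, d features x n samples.
#' @param y Numeric vector of n observed responses.
#' @param k Number of neighbours (requires `n >= k + 1`).
#' @return Numeric vector of n leave-one-out predictions.
#' @export
loo_predictions <- function(X, y, k = 3L) {
  X <- as.matrix(X)
  if (length(y) != ncol(X)) {
    stop("`y` must have one entry per sample column", call. = FALSE)
  }
  as.numeric(cpp_loo_predict(X, as.numeric(y), as.integer(k)))
}

#' Squared-error loss between observed and predicted responses
#'
#' The training objective minimised by the gene-set search: the sum of
#' squared deviations between observed and predicted values.
#'
#' @param obs,pred Numeric vectors of equal length.
#' @return Non-negative scalar; zero iff the vectors are identical.
#' @export
squared_error_loss <- function(obs, pred) {
  if (length(obs) != length(pred)) {
    stop("`obs` and `pred` must have the same length", call. = FALSE)
  }
  sum((obs - pred)^2)
}
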