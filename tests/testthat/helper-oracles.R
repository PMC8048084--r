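# Independent brute-force oracles used to validate the compiled kNN paths
# and the rank-sum test, plus small reusable fixtures.

# Full-sort kNN oracle: squared distances computed in R, ties broken by the
# lower pool column index via order()'s stable secondary key.
oracle_knn <- function(pool, values, query, k, exclude = NULL) {
  d2 <- colSums((pool - query)^2)
  eligible <- setdiff(seq_along(values), exclude)
  ord <- eligible[order(d2[eligible], eligible)]
  mean(values[ord[seq_len(k)]])
}

oracle_loo <- function(X, y, k) {
  vapply(seq_len(ncol(X)),
         function(i) oracle_knn(X, y, X[, i], k, exclude = i),
         numeric(1L))
}

# Exact two-sided rank-sum p-value by complete enumeration of all
# assignments of the pooled observations to the first group (no ties).
oracle_ranksum_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  stopifnot(anyDuplicated(pooled) == 0L)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  w_all <- apply(combs, 2L, function(idx) sum(r[idx]))
  lower <- mean(w_all <= w_obs)
  upper <- mean(w_all >= w_obs)
  min(1, 2 * min(lower, upper))
}

# Tiny deterministic expression fixture: 4 genes x 3 samples, raw scale.
tiny_expr <- function() {
  v <- matrix(c(0, 1, 3, 7,
                1, 3, 7, 15,
                3, 7, 15, 31), nrow = 4,
              dimnames = list(c("GA", "GB", "GC", "GD"),
                              c("S1", "S2", "S3")))
  expr_matrix(v, transform = "raw")
}

# Small synthetic configuration: same planted structure as the defaults but
# sized for fast unit tests. Named arguments override the reduced defaults.
small_config <- function(...) {
  defaults <- list(n_genes = 80L, n_cell_lines = 60L,
                   n_signal_genes = 2L, effect_sizes = c(1, 0.8),
                   noise_sd = 0.7,
                   n_tumor_types = 3L, samples_per_type = 20L,
                   tissue_shifts = c(-1.5, 0, 0),
                   n_mutation_genes = 1L)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

small_ga_config <- function(...) {
  defaults <- list(d = 10L, k = 3L, population_size = 24L,
                   max_generations = 25L, stall_generations = 8L)
  do.call(ga_config, utils::modifyList(defaults, list(...)))
}
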