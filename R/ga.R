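#' Genetic-algorithm configuration
#'
#' Settings for the evolutionary search over fixed-size gene sets. A
#' candidate solution ("chromosome") is a set of exactly `d` distinct gene
#' indices scored by the leave-one-out kNN squared-error loss on the
#' training samples. Defaults use the near-optimal `k = 3`, `d = 30` rule
#' and modest population settings sized so that 100 Monte-Carlo runs on a
#' few-hundred-sample drug complete on a single desktop CPU; all settings
#' are tunable.
#'
#' @param d Gene-set size (chromosome length), default 30.
#' @param k Neighbour count for the kNN fitness, default 3.
#' @param population_size Chromosomes per generation.
#' @param max_generations Hard cap on generations.
#' @param mutation_rate Per-gene replacement probability; default `1/d`.
#' @param tournament_size Contestants per tournament selection draw.
#' @param elite_count Best chromosomes copied unchanged each generation
#'   (guarantees a non-increasing best-loss trace).
#' @param stall_generations Early stop after this many generations without
#'   improvement of the best loss.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(d = 30L, k = 3L, population_size = 60L,
                      max_generations = 200L, mutation_rate = NULL,
                      tournament_size = 3L, elite_count = 2L,
                      stall_generations = 25L) {
  d <- as.integer(d); k <- as.integer(k)
  population_size <- as.integer(population_size)
  max_generations <- as.integer(max_generations)
  tournament_size <- as.integer(tournament_size)
  elite_count <- as.integer(elite_count)
  stall_generations <- as.integer(stall_generations)
  if (is.null(mutation_rate)) mutation_rate <- 1 / d
  if (d < 1L) stop("`d` must be at least 1", call. = FALSE)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  if (elite_count <= 0L || elite_count >= population_size) {
    stop("`elite_count` must satisfy 0 < elite_count < population_size",
         call. = FALSE)
  }
  if (mutation_rate <= 0 || mutation_rate >= 1) {
    stop("`mutation_rate` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (tournament_size < 1L || tournament_size > population_size) {
    stop("`tournament_size` must lie in [1, population_size]", call. = FALSE)
  }
  structure(list(d = d, k = k, population_size = population_size,
                 max_generations = max_generations,
                 mutation_rate = mutation_rate,
                 tournament_size = tournament_size,
                 elite_count = elite_count,
                 stall_generations = stall_generations),
            class = "ga_config")
}

#' Initialise a random population of gene sets
#'
#' Each chromosome is a uniformly random `d`-subset of the gene universe,
#' drawn without replacement.
#'
#' @param config A [ga_config()].
#' @param n_genes Size of the gene universe (G).
#' @return List of `population_size` integer vectors of length `d`.
#' @export
init_population <- function(config, n_genes) {
  stopifnot(inherits(config, "ga_config"))
  n_genes <- as.integer(n_genes)
  if (n_genes < config$d) {
    stop(sprintf("infeasible configuration: gene universe (%d) smaller than set size d = %d",
                 n_genes, config$d), call. = FALSE)
  }
  lapply(seq_len(config$population_size),
         function(i) sample.int(n_genes, config$d))
}

#' Score one gene set by leave-one-out kNN squared error
#'
#' Equals `squared_error_loss(y, loo_predictions(X[genes, ], y, k))`,
#' computed in one pass.
#'
#' @param genes Integer vector of gene (row) indices.
#' @param X Numeric training matrix, genes x samples.
#' @param y Numeric training responses.
#' @param k Neighbour count.
#' @return The squared-error loss of the leave-one-out kNN predictions made
#'   in the subspace spanned by `genes`.
#' @export
evaluate_chromosome <- function(genes, X, y, k = 3L) {
  genes <- as.integer(genes)
  if (anyNA(genes) || any(genes < 1L) || any(genes > nrow(X))) {
    stop("chromosome contains invalid gene indices", call. = FALSE)
  }
  cpp_loo_sse(X[genes, , drop = FALSE], as.numeric(y), as.integer(k))
}

ga_crossover <- function(a, b, d) {
  common <- intersect(a, b)
  need <- d - length(common)
  if (need == 0L) return(common)
  pool <- setdiff(union(a, b), common)
  c(common, pool[sample.int(length(pool), need)])
}

ga_mutate <- function(genes, n_genes, rate) {
  hit <- which(runif(length(genes)) < rate)
  if (length(hit) == 0L) return(genes)
  avail <- setdiff(seq_len(n_genes), genes)
  if (length(avail) < length(hit)) hit <- hit[seq_along(avail)]
  if (length(hit) == 0L) return(genes)
  genes[hit] <- avail[sample.int(length(avail), length(hit))]
  genes
}

#' Evolve a gene set minimising leave-one-out kNN loss
#'
#' Single-population genetic algorithm: tournament selection, uniform
#' set-exchange crossover with repair (the child keeps the parents' common
#' genes and fills the remainder uniformly from their symmetric
#' difference), per-gene mutation replacing a gene with a uniformly chosen
#' unused gene, and elitism. Stops at `max_generations` or when the best
#' loss has not improved for `stall_generations` generations.
#'
#' @param X Numeric training matrix, genes x samples (Z-scored).
#' @param y Numeric training responses (ln(IC50)).
#' @param config A [ga_config()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   the run is fully reproducible.
#' @return A list of class `ga_run`: `best_genes` (integer indices),
#'   `best_loss`, `loss_trace` (per-generation best loss, non-increasing),
#'   `generations`, `seed`.
#' @export
evolve <- function(X, y, config = ga_config(), seed = NULL) {
  stopifnot(inherits(config, "ga_config"))
  n_genes <- nrow(X)
  n <- ncol(X)
  if (n < config$k + 1L) {
    stop(sprintf("training set too small: %d samples but k = %d", n, config$k),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  y <- as.numeric(y)
  pop <- init_population(config, n_genes)
  score <- function(genes) evaluate_chromosome(genes, X, y, config$k)
  loss <- vapply(pop, score, numeric(1L))
  n_off <- config$population_size - config$elite_count
  trace <- numeric(config$max_generations + 1L)
  trace[1L] <- min(loss)
  best_so_far <- trace[1L]
  stall <- 0L
  gen <- 0L
  while (gen < config$max_generations) {
    gen <- gen + 1L
    ord <- order(loss)
    elites <- pop[ord[seq_len(config$elite_count)]]
    elite_loss <- loss[ord[seq_len(config$elite_count)]]
    offspring <- vector("list", n_off)
    for (i in seq_len(n_off)) {
      p1 <- pop[[tournament_pick(loss, config$tournament_size)]]
      p2 <- pop[[tournament_pick(loss, config$tournament_size)]]
      child <- ga_crossover(p1, p2, config$d)
      offspring[[i]] <- ga_mutate(child, n_genes, config$mutation_rate)
    }
    off_loss <- vapply(offspring, score, numeric(1L))
    pop <- c(elites, offspring)
    loss <- c(elite_loss, off_loss)
    gen_best <- min(loss)
    trace[gen + 1L] <- gen_best
    if (gen_best < best_so_far) {
      best_so_far <- gen_best
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= config$stall_generations) break
  }
  trace <- trace[seq_len(gen + 1L)]
  best_idx <- which.min(loss)
  structure(list(best_genes = sort(pop[[best_idx]]),
                 best_loss = loss[best_idx],
                 loss_trace = trace,
                 generations = gen,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "ga_run")
}

tournament_pick <- function(loss, size) {
  contestants <- sample.int(length(loss), size)
  contestants[which.min(loss[contestants])]
}

#' @export
print.ga_run <- function(x, ...) {
  cat(sprintf("<ga_run> best loss %.4g after %d generations (|genes| = %d)\n",
              x$best_loss, x$generations, length(x$best_genes)))
  invisible(x)
}
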