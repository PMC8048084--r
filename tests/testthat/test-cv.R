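test_that("partition plans have the right shape and expectations", {
  # N = 10 at 10% forces singleton test sets
  plan <- make_partitions(10, runs = 20, seed = 1)
  expect_true(all(vapply(plan$partitions,
                         function(p) length(p$test) == 1L, logical(1))))
  for (p in plan$partitions) {
    expect_length(intersect(p$train, p$test), 0)
    expect_setequal(c(p$train, p$test), 1:10)
  }

  # per-sample test membership averages runs * test_fraction exactly
  plan2 <- make_partitions(500, runs = 100, seed = 2)
  counts <- tabulate(unlist(lapply(plan2$partitions, `[[`, "test")), 500)
  expect_equal(mean(counts), 10)

  # reproducibility
  p1 <- make_partitions(50, runs = 5, seed = 9)
  p2 <- make_partitions(50, runs = 5, seed = 9)
  expect_identical(p1, p2)

  expect_error(make_partitions(1, runs = 5), "too few samples")
  expect_error(make_partitions(100, test_fraction = 0), "test_fraction")
})

test_that("per-run predictions aggregate by arithmetic mean per sample", {
  per_run <- list(c(S1 = 1.0, S2 = 5.0),
                  c(S1 = 2.0),
                  c(S1 = 1.5, S3 = 0.5))
  agg <- aggregate_predictions(per_run)
  expect_equal(agg$predicted[agg$sample_id == "S1"], 1.5)
  expect_equal(agg$runs_contributing[agg$sample_id == "S1"], 3L)
  # sample seen once keeps its value
  expect_equal(agg$predicted[agg$sample_id == "S2"], 5.0)
  # three-run mean
  expect_equal(aggregate_predictions(list(c(A = 0.5), c(A = 1.0),
                                          c(A = 1.5)))$predicted, 1.0)
  expect_error(aggregate_predictions(list(c(1, 2))), "named")
})

test_that("correlations and the predictability rule behave at the boundary", {
  obs <- c(1, 2, 3, 4)
  expect_equal(correlations(obs, obs),
               tibble::tibble(rho_pearson = 1, rho_spearman = 1))
  expect_equal(correlations(obs, -obs)$rho_spearman, -1)
  # classic rank example: one adjacent swap, Spearman = 1 - 6*2/(4*15) = 0.8
  expect_equal(correlations(obs, c(1, 3, 2, 4))$rho_spearman, 0.8)
  expect_error(correlations(obs, rep(1, 4)), "constant")
  expect_error(correlations(1:2, 2:1), "at least 3")

  expect_true(classify_predictable(0.40, 0.40))
  expect_false(classify_predictable(0.55, 0.39))
  expect_false(classify_predictable(-0.2, 0.9))
  expect_true(classify_predictable(0.2, 0.2, threshold = 0.1))
})

test_that("selection frequencies count gene membership and conserve mass", {
  runs <- list(structure(list(best_genes = c(1L, 2L, 3L)), class = "ga_run"),
               structure(list(best_genes = c(3L, 4L, 5L)), class = "ga_run"))
  freq <- selection_frequencies(runs, n_genes = 6)
  expect_equal(sum(freq$count), 2 * 3)
  expect_equal(freq$count[freq$gene == "3"], 2L)
  expect_equal(freq$count[freq$gene == "6"], 0L)
  # fold over chance: chance = R*d/G = 1, so counts equal folds
  expect_equal(freq$fold_over_chance, as.numeric(freq$count))
})

test_that("chance frequency matches the closed form", {
  # 100 x 30 / 19163 = 0.1566, conventionally quoted as ~0.155
  expect_equal(chance_frequency(100, 30, 19163), 3000 / 19163)
  expect_equal(chance_frequency(100, 30, 19163), 0.155, tolerance = 0.02)
  expect_equal(chance_frequency(100, 30, 3000), 1.0)
  expect_equal(chance_frequency(1, 12, 12), 1.0)
})

test_that("single-gene response correlations flag monotone biomarkers", {
  y <- c(0.5, 1.2, 2.0, 3.1, 4.9)
  up <- c(1, 2, 3, 4, 5)
  expect_equal(gene_drug_response_correlation(up, y)$rho_spearman, 1)
  down <- gene_drug_response_correlation(rev(up), y)
  expect_equal(down$rho_spearman, -1)
  expect_true(down$flagged)
  mid <- gene_drug_response_correlation(c(1, 3, 2, 4), c(1, 2, 3, 4))
  expect_equal(mid$rho_spearman, 0.8)
  expect_error(gene_drug_response_correlation(rep(1, 5), y), "constant")
})

test_that("the full per-drug fit is deterministic and internally consistent", {
  study <- simulate_drug_study(small_config(), seed = 313)
  expr_z <- prepare_expression(study$expression)
  ds <- build_drug_dataset(expr_z, study$responses, study$config$drug_id)
  cfg <- small_ga_config()
  fit <- fit_drug_model(ds, runs = 8, config = cfg, seed = 77)

  # conservation: total selection mass = runs * d
  expect_equal(sum(fit$selection_count), 8 * cfg$d)
  # every run's loss trace is non-increasing
  for (r in fit$run_results) expect_true(all(diff(r$loss_trace) <= 0))
  # aggregated training predictions stay within the observed range
  inr <- !is.na(fit$pred_train)
  expect_true(all(fit$pred_train[inr] >= min(fit$observed)))
  expect_true(all(fit$pred_train[inr] <= max(fit$observed)))
  inr <- !is.na(fit$pred_test)
  expect_true(all(fit$pred_test[inr] >= min(fit$observed)))
  expect_true(all(fit$pred_test[inr] <= max(fit$observed)))

  # end-to-end determinism
  fit2 <- fit_drug_model(ds, runs = 8, config = cfg, seed = 77)
  expect_identical(glance(fit), glance(fit2))
  expect_identical(fit$pred_test, fit2$pred_test)
  expect_identical(fit$selection_count, fit2$selection_count)

  # tidy/glance/augment surfaces
  g <- glance(fit)
  expect_identical(g$runs, 8L)
  expect_identical(g$d, cfg$d)
  td <- tidy(fit)
  expect_identical(names(td),
                   c("gene", "count", "frequency", "fold_over_chance"))
  au <- augment(fit)
  expect_identical(au$sample_id, ds$sample_ids)
  expect_equal(au$observed, ds$y)
  expect_true(all(au$n_test_runs + au$n_train_runs == 8L))
})

test_that("a single run with one test sample aggregates to that prediction", {
  study <- simulate_drug_study(small_config(n_cell_lines = 10L), seed = 5)
  expr_z <- prepare_expression(study$expression)
  ds <- build_drug_dataset(expr_z, study$responses, study$config$drug_id)
  cfg <- small_ga_config(population_size = 10L, max_generations = 5L)
  fit <- fit_drug_model(ds, runs = 1, config = cfg, seed = 3)
  te <- fit$plan$partitions[[1]]$test
  expect_length(te, 1)
  tr <- fit$plan$partitions[[1]]$train
  genes <- fit$run_results[[1]]$best_genes
  direct <- knn_regress(ds$X[genes, tr, drop = FALSE], ds$y[tr],
                        ds$X[genes, te], k = cfg$k)
  expect_equal(fit$pred_test[te], direct)
})
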