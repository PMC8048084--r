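# One fitted small study with external samples, shared across the blocks.
transfer_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      study <- simulate_drug_study(
        small_config(n_cell_lines = 120L, samples_per_type = 100L),
        seed = 424)
      expr_z <- prepare_expression(study$expression)
      ext_z <- prepare_expression(study$external)
      ds <- build_drug_dataset(expr_z, study$responses, study$config$drug_id)
      ds <- attach_external(ds, ext_z)
      fit <- fit_drug_model(ds, runs = 8, config = small_ga_config(d = 6L),
                            seed = 17)
      cache <<- list(study = study, ds = ds, fit = fit,
                     preds = predict_external(fit, ds))
    }
    cache
  }
})

test_that("external predictions are bounded, complete and flag the planted tissue", {
  fx <- transfer_fixture()
  preds <- fx$preds
  expect_equal(nrow(preds), ncol(fx$ds$external))
  expect_true(all(preds$runs_contributing == fx$fit$runs))
  # every external prediction lies within the observed cell-line range
  expect_true(all(preds$predicted_ln_ic50 >= min(fx$ds$y)))
  expect_true(all(preds$predicted_ln_ic50 <= max(fx$ds$y)))
  # the tissue planted 1.5 log units toward sensitivity has the lowest median
  med <- tapply(preds$predicted_ln_ic50[preds$tissue_type != "duplicate_control"],
                preds$tissue_type[preds$tissue_type != "duplicate_control"],
                median)
  expect_equal(names(which.min(med)), "tissue_01")
  spec <- tumor_type_specificity(preds)
  expect_true(spec$flagged[spec$tissue_type == "tissue_01"])
})

test_that("a duplicated cell-line profile predicts its own observed value at k = 1, R = 1", {
  study <- simulate_drug_study(small_config(), seed = 99)
  expr_z <- prepare_expression(study$expression)
  ext_z <- prepare_expression(study$external)
  ds <- build_drug_dataset(expr_z, study$responses, study$config$drug_id)
  ds <- attach_external(ds, ext_z)
  cfg <- small_ga_config(k = 1L)
  fit <- fit_drug_model(ds, runs = 1, config = cfg, seed = 31)
  dup_cl <- study$truth$duplicate_control$cell_line_id
  # only valid when the duplicated line was in the training set of the run
  if (dup_cl %in% ds$sample_ids[fit$plan$partitions[[1]]$train]) {
    preds <- predict_external(fit, ds)
    dup_pred <- preds$predicted_ln_ic50[preds$sample_id == "DUP_CONTROL_1"]
    dup_obs <- ds$y[ds$sample_ids == dup_cl]
    expect_equal(dup_pred, dup_obs, tolerance = 1e-12)
  } else {
    succeed("duplicated line not in training set for this partition")
  }
})

test_that("tumour-type specificity applies the median-of-medians rule", {
  preds <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:9),
    source_class = "tumor",
    tissue_type = rep(c("A", "B", "C"), each = 3),
    subtype = NA_character_,
    predicted_ln_ic50 = c(0, 0.1, -0.1, 0, 0.2, -0.2, -2, -2.1, -1.9),
    runs_contributing = 10L)
  spec <- tumor_type_specificity(preds)
  expect_equal(spec$median_of_medians[1], 0)
  expect_identical(spec$tissue_type[spec$flagged], "C")
  # all types identical: nothing flagged
  null_preds <- preds
  null_preds$predicted_ln_ic50 <- rep(c(1, 2, 3), times = 3)
  expect_false(any(tumor_type_specificity(null_preds)$flagged))
  expect_error(tumor_type_specificity(preds[1:3, ]), "two tumour types")
  # threshold semantics: 1 log unit is about 2.7-fold
  expect_equal(fold_change_from_log_units(1), exp(1))
})

test_that("tumour-to-normal comparison requires > 20 normals and > 1 log unit", {
  mk <- function(type, n_t, n_n, mt, mn) {
    tibble::tibble(
      sample_id = paste0(type, seq_len(n_t + n_n)),
      source_class = rep(c("tumor", "normal"), c(n_t, n_n)),
      tissue_type = type, subtype = NA_character_,
      predicted_ln_ic50 = c(rnorm(n_t, mt, 0.01), rnorm(n_n, mn, 0.01)),
      runs_contributing = 10L)
  }
  set.seed(1)
  preds <- dplyr::bind_rows(
    mk("FLAG", 30, 25, -1.5, 0),     # difference 1.5 > 1, eligible
    mk("SMALL", 30, 20, -3, 0),      # exactly 20 normals: ineligible
    mk("CLOSE", 30, 25, -0.5, 0))    # difference 0.5 < 1
  out <- tumor_to_normal(preds)
  expect_true(out$flagged[out$tissue_type == "FLAG"])
  expect_false(out$eligible[out$tissue_type == "SMALL"])
  expect_false(out$flagged[out$tissue_type == "SMALL"])
  expect_false(out$flagged[out$tissue_type == "CLOSE"])
  # identical tumour and normal distributions never flag
  same <- mk("SAME", 30, 30, 0, 0)
  expect_false(any(tumor_to_normal(same)$flagged))
})

test_that("subtype differential uses a 0.5 log-unit gap and marks the minimum", {
  mk_sub <- function(medians) {
    tibble::tibble(
      sample_id = sprintf("B%02d", seq_along(rep(medians, each = 3))),
      source_class = "tumor", tissue_type = "breast",
      subtype = rep(names(medians), each = 3),
      predicted_ln_ic50 = rep(unname(medians), each = 3),
      runs_contributing = 10L)
  }
  # pattern from a sensitive-basal-like drug: minimum at subtype a
  m <- c(a = -3.6, b = -3.4, c = -2.8, d = -3.0, e = -3.0)
  out <- subtype_differential(mk_sub(m))
  expect_identical(out$subtype[out$is_minimum], "a")
  expect_true(out$flagged[out$subtype == "a"])  # -3.6 < -3.0 - 0.5
  # all equal: nothing flagged
  expect_false(any(subtype_differential(
    mk_sub(c(a = 1, b = 1, c = 1)))$flagged))
  # a 0.6 log-unit drop beats the default 0.5 threshold
  out2 <- subtype_differential(mk_sub(c(a = 0, b = 0, c = 0, d = 0,
                                        e = -0.6)))
  expect_true(out2$flagged[out2$subtype == "e"])
  expect_error(subtype_differential(mk_sub(c(a = 1))), "two subtypes")
})

test_that("rank-sum p-values match exact enumeration for small untied groups", {
  set.seed(71)
  for (n in 2:6) {
    for (m in 2:6) {
      x <- rnorm(n)
      y <- rnorm(m)
      expect_equal(gaknn:::ranksum_p(x, y), oracle_ranksum_p(x, y),
                   tolerance = 1e-12,
                   label = sprintf("ranksum n=%d m=%d", n, m))
    }
  }
  # complete separation at n = m = 5: p = 2/252
  expect_equal(gaknn:::ranksum_p(1:5, 6:10), 2 / 252, tolerance = 1e-12)
  # identical groups: p = 1 under the tie-corrected approximation
  expect_equal(gaknn:::ranksum_p(rep(1, 6), rep(1, 6)), 1)
})

test_that("mutation associations respect the carrier minimum and variant filter", {
  preds <- tibble::tibble(
    sample_id = sprintf("T%02d", 1:20),
    source_class = "tumor",
    tissue_type = "colon", subtype = NA_character_,
    predicted_ln_ic50 = c(1:5, 6:20),  # carriers T01-T05 most sensitive
    runs_contributing = 10L)
  mut <- tibble::tibble(
    sample_id = c(sprintf("T%02d", 1:5), sprintf("T%02d", 1:4), "T06"),
    gene = c(rep("KRAS", 5), rep("RARE", 4), "SILENTED"),
    variant_class = c(rep("missense mutation", 5),
                      rep("nonsense mutation", 4),
                      "Silent"))
  out <- mutation_association(preds, mut, min_mutated = 5)
  # KRAS: complete separation of 5 vs 15
  expect_identical(out$gene, "KRAS")
  expect_equal(out$n_mutated, 5L)
  expect_lt(out$p_value, 0.01)
  expect_equal(out$direction, -1)
  # RARE has only 4 carriers -> skipped; Silent never counts
  expect_false("RARE" %in% out$gene)
  expect_false("SILENTED" %in% out$gene)
  # BH adjustment option returns a column
  out_bh <- mutation_association(preds, mut, adjust = "BH")
  expect_true(all(out_bh$p_adjusted >= out_bh$p_value - 1e-15))
})

test_that("variant-class filtering keeps the six qualifying classes only", {
  mut <- tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S4"),
    gene = "G",
    variant_class = c("Missense_Mutation", "Silent",
                      "splice site mutation", "3'UTR"))
  ind <- mutation_indicators(mut)
  expect_setequal(ind$sample_id, c("S1", "S3"))
})

test_that("log-unit fold changes match the stated identities", {
  expect_equal(fold_change_from_log_units(0), 1)
  expect_equal(round(fold_change_from_log_units(1), 1), 2.7)
  expect_equal(round(fold_change_from_log_units(0.5), 2), 1.65)
})
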