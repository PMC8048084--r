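test_that("generation is seed-deterministic down to exported text", {
  cfg <- small_config()
  a <- simulate_drug_study(cfg, seed = 5)
  b <- simulate_drug_study(cfg, seed = 5)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$responses, b$responses)
  expect_identical(a$external$values, b$external$values)
  expect_identical(a$mutations, b$mutations)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(a, d1)
  write_study(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  c_ <- simulate_drug_study(cfg, seed = 6)
  expect_false(identical(a$responses$ln_ic50, c_$responses$ln_ic50))
})

test_that("raw expression is nonnegative and the pipeline accepts it", {
  study <- simulate_drug_study(small_config(), seed = 2)
  expect_true(all(study$expression$values >= 0))
  expect_true(all(study$external$values >= 0))
  z <- prepare_expression(study$expression)
  expect_true(all(abs(colMeans(z$values)) < 1e-8))
})

test_that("planted signal explains the configured share of response variance", {
  # defaults target ~75% explained variance; check expectation over seeds
  r2 <- vapply(1:8, function(s) {
    signal_r_squared(simulate_drug_study(seed = s))
  }, numeric(1))
  expect_gt(mean(r2), 0.70)
  expect_lt(mean(r2), 0.80)
  # noiseless limit: a single signal gene correlates perfectly
  cfg0 <- synthetic_config(n_genes = 60, n_cell_lines = 50,
                           n_signal_genes = 1, effect_sizes = 1,
                           noise_sd = 1e-9, n_tumor_types = 2,
                           samples_per_type = 4,
                           tissue_shifts = c(0, 0),
                           n_mutation_genes = 1,
                           include_duplicate_control = FALSE)
  study0 <- simulate_drug_study(cfg0, seed = 3)
  expect_gt(signal_r_squared(study0), 1 - 1e-6)
})

test_that("truth record reproduces the planted linear relationship", {
  study <- simulate_drug_study(small_config(), seed = 11)
  tr <- study$truth
  z <- prepare_expression(study$expression)$values
  rebuilt <- colSums((z[tr$signal_genes, , drop = FALSE] -
                        tr$zscore_centers) * tr$zscore_slopes)
  expect_equal(unname(rebuilt), tr$linear_signal, tolerance = 1e-10)
  resid <- study$responses$ln_ic50 - rebuilt
  expect_lt(abs(sd(resid) - tr$noise_sd), 0.25)
})

test_that("planted tissue shift is realised on the response scale", {
  shifts <- vapply(1:6, function(s) {
    study <- simulate_drug_study(small_config(samples_per_type = 50L),
                                 seed = 40 + s)
    tr <- study$truth
    ext_z <- prepare_expression(study$external)
    meta <- ext_z$meta
    imp <- colSums((ext_z$values[tr$signal_genes, , drop = FALSE] -
                      tr$zscore_centers) * tr$zscore_slopes)
    shifted <- meta$tissue_type == "tissue_01" & meta$source_class == "tumor"
    other <- meta$tissue_type %in% c("tissue_02", "tissue_03") &
      meta$source_class == "tumor"
    mean(imp[shifted]) - mean(imp[other])
  }, numeric(1))
  expect_lt(abs(mean(shifts) - (-1.5)), 0.4)
})

test_that("mutation carriers shift toward sensitivity; silent decoys do not count", {
  cfg <- small_config(samples_per_type = 60L, mutation_frequency = 0.4)
  study <- simulate_drug_study(cfg, seed = 8)
  expect_true(all(unique(study$mutations$gene) %in%
                    c(study$truth$mutation_genes)))
  ind <- mutation_indicators(study$mutations)
  expect_false(any(!ind$sample_id %in% study$external$meta$sample_id))
  # silent records exist and are filtered out
  expect_true(any(study$mutations$variant_class == "Silent"))
  expect_false(any(paste(ind$sample_id, ind$gene) %in%
                     paste(study$mutations$sample_id[study$mutations$variant_class == "Silent"],
                           study$mutations$gene[study$mutations$variant_class == "Silent"])))
  # carriers have a lower implied response than non-carrier tumours
  tr <- study$truth
  ext_z <- prepare_expression(study$external)
  imp <- colSums((ext_z$values[tr$signal_genes, , drop = FALSE] -
                    tr$zscore_centers) * tr$zscore_slopes)
  meta <- ext_z$meta
  tum <- meta$source_class == "tumor" & meta$tissue_type != "tissue_01" &
    meta$tissue_type != "duplicate_control"
  carrier <- meta$sample_id %in% ind$sample_id
  expect_lt(mean(imp[tum & carrier]), mean(imp[tum & !carrier]))
})

test_that("null studies break the expression-response link and zero all shifts", {
  cfg <- small_config()
  null <- simulate_null_study(cfg, seed = 14)
  expect_true(null$truth$null)
  expect_true(all(null$truth$tissue_shifts == 0))
  # same response marginal as the matching signal study, different pairing
  study <- simulate_drug_study(cfg, seed = 14)
  # gene-response correlations centre at zero over seeds
  rho <- vapply(1:10, function(s) {
    ns <- simulate_null_study(cfg, seed = 100 + s)
    z <- prepare_expression(ns$expression)$values
    cor(z[ns$truth$signal_index[1], ], ns$responses$ln_ic50)
  }, numeric(1))
  expect_lt(abs(mean(rho)), 0.15)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(synthetic_config(n_signal_genes = 5, effect_sizes = c(1, 2)),
               "one entry per signal gene")
  expect_error(synthetic_config(noise_sd = 0), "positive")
  expect_error(synthetic_config(n_tumor_types = 2, tissue_shifts = c(0)),
               "per tumour type")
  expect_error(synthetic_config(n_genes = 3, n_signal_genes = 5),
               "more signal genes")
})
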