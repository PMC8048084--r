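#' Configuration for the synthetic drug-sensitivity study generator
#'
#' Describes a simulated study with the structure the pipeline assumes: a
#' cohort of cell lines whose ln(IC50) for one synthetic drug is a noisy
#' linear function of a small planted set of signal genes (acting on the
#' per-sample Z-score scale that the preparation chain produces), plus
#' external tumour/normal samples drawn from the same expression model with
#' tissue-specific mean shifts along the signal axis, plus a mutation table
#' whose carriers receive an additional shift.
#'
#' Defaults plant 3 signal genes among 500 whose combined effect explains
#' roughly 75% of the response variance in a 200-cell-line cohort - strong
#' enough that a sound pipeline classifies the drug predictable, without
#' being degenerate - and one external tissue type shifted 1.5 log units
#' toward sensitivity as a positive control.
#'
#' @param n_genes Gene-universe size G.
#' @param n_cell_lines Cell-line cohort size.
#' @param n_signal_genes Number of planted signal genes.
#' @param effect_sizes Contribution of each signal gene's Z-score to
#'   ln(IC50); length `n_signal_genes`.
#' @param signal_dispersion Log2-scale dispersion of the signal genes.
#'   Background genes draw dispersions from U(0.3, 1.2); signal genes get
#'   this larger value, emulating the high-variance, near-bimodal expression
#'   of real sensitivity biomarkers, whose dynamic range is what lets them
#'   dominate the Euclidean neighbour distances.
#' @param noise_sd Standard deviation of the Gaussian response noise.
#' @param n_tumor_types Number of external tissue types.
#' @param samples_per_type External samples per tissue type.
#' @param tissue_shifts Per-type mean shift of tumour samples on the
#'   predicted ln(IC50) scale (log units); length `n_tumor_types`.
#' @param normal_fraction Fraction of each type's external samples labelled
#'   normal (normals carry no shift).
#' @param subtype_count Number of subtype labels assigned within the first
#'   tissue type's tumours (0 = none).
#' @param subtype_shifts Per-subtype shift in log units; length
#'   `subtype_count`.
#' @param n_mutation_genes Number of genes appearing in the mutation table.
#' @param mutation_effect Shift (log units) applied to carriers' predicted
#'   scale; negative values make carriers more sensitive.
#' @param mutation_frequency Per-(gene, tumour sample) carrier probability.
#' @param include_duplicate_control Append one external sample whose profile
#'   equals the first cell line's, to pin the zero-distance prediction
#'   contract (tissue type `"duplicate_control"`).
#' @param drug_id,drug_name Identifier and label of the synthetic drug.
#' @param seed Default seed used by [simulate_drug_study()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500L, n_cell_lines = 200L,
                             n_signal_genes = 3L,
                             effect_sizes = c(1, 0.9, 0.8),
                             signal_dispersion = 4,
                             noise_sd = 0.9,
                             n_tumor_types = 4L, samples_per_type = 50L,
                             tissue_shifts = c(-1.5, 0, 0, 0),
                             normal_fraction = 0.5,
                             subtype_count = 0L, subtype_shifts = NULL,
                             n_mutation_genes = 2L, mutation_effect = -1,
                             mutation_frequency = 0.25,
                             include_duplicate_control = TRUE,
                             drug_id = "1001",
                             drug_name = "synthetic-agent-1",
                             seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_cell_lines <- as.integer(n_cell_lines)
  n_signal_genes <- as.integer(n_signal_genes)
  n_tumor_types <- as.integer(n_tumor_types)
  samples_per_type <- as.integer(samples_per_type)
  subtype_count <- as.integer(subtype_count)
  n_mutation_genes <- as.integer(n_mutation_genes)
  if (n_signal_genes > n_genes) {
    stop("more signal genes than genes", call. = FALSE)
  }
  if (length(effect_sizes) != n_signal_genes) {
    stop("`effect_sizes` must have one entry per signal gene", call. = FALSE)
  }
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (length(tissue_shifts) != n_tumor_types) {
    stop("`tissue_shifts` must have one entry per tumour type", call. = FALSE)
  }
  if (subtype_count > 0L && length(subtype_shifts) != subtype_count) {
    stop("`subtype_shifts` must have one entry per subtype", call. = FALSE)
  }
  if (min(n_genes, n_cell_lines, n_tumor_types, samples_per_type) < 1L) {
    stop("all counts must be at least 1", call. = FALSE)
  }
  structure(list(n_genes = n_genes, n_cell_lines = n_cell_lines,
                 n_signal_genes = n_signal_genes,
                 effect_sizes = as.numeric(effect_sizes),
                 signal_dispersion = signal_dispersion,
                 noise_sd = noise_sd,
                 n_tumor_types = n_tumor_types,
                 samples_per_type = samples_per_type,
                 tissue_shifts = as.numeric(tissue_shifts),
                 normal_fraction = normal_fraction,
                 subtype_count = subtype_count,
                 subtype_shifts = as.numeric(subtype_shifts),
                 n_mutation_genes = n_mutation_genes,
                 mutation_effect = mutation_effect,
                 mutation_frequency = mutation_frequency,
                 include_duplicate_control = include_duplicate_control,
                 drug_id = as.character(drug_id),
                 drug_name = drug_name,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic drug-sensitivity study
#'
#' Raw expression is drawn as an exponentiated Gaussian (TPM-like,
#' heavy-tailed, non-negative): per-gene log2 means and dispersions are
#' drawn once, and every sample's log2 profile is Gaussian around them. The
#' cell-line response is built on the *pipeline* scale: the generator runs
#' log2(x + 1) and per-sample Z-scoring on its own raw matrix and sets
#' `ln(IC50) = sum_j effect_j * z_j + N(0, noise_sd)` over the planted
#' signal genes. Tissue, subtype and mutation shifts are applied to the
#' signal genes in log2 space, scaled so that the induced shift on the
#' Z-score (and hence predicted) scale approximates the requested log-unit
#' shift. Everything is a deterministic function of the seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `synthetic_study`: `expression` (raw
#'   [expr_matrix()] of cell lines), `responses` (drug-response tibble),
#'   `external` (raw [expr_matrix()] with tumour/normal metadata),
#'   `mutations` (long tibble `sample_id`, `gene`, `variant_class`), and
#'   `truth` (planted signal genes, effects, shifts - sufficient to
#'   recompute every planted quantity).
#' @export
simulate_drug_study <- function(config = synthetic_config(),
                                seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(seed))
  G <- config$n_genes
  n <- config$n_cell_lines
  gene_ids <- sprintf("G%05d", seq_len(G))
  mu <- runif(G, 1, 8)
  sigma <- runif(G, 0.3, 1.2)
  signal_idx <- sort(sample.int(G, config$n_signal_genes))
  # Signal genes are abundant, high-dynamic-range biomarkers: a silent gene
  # cannot act as a continuous predictor (its low tail saturates at zero
  # TPM), so their baseline means sit at the top of the background range.
  mu[signal_idx] <- runif(config$n_signal_genes, 6, 8)
  sigma[signal_idx] <- config$signal_dispersion
  eff <- config$effect_sizes
  eff_scale <- sum(abs(eff))

  cl_ids <- sprintf("CL_%04d", seq_len(n))
  L <- mu + sigma * matrix(rnorm(G * n), nrow = G)
  raw <- pmax(2^L - 1, 0)
  dimnames(raw) <- list(gene_ids, cl_ids)
  z <- pipeline_zscores(raw)
  # Standardise each signal gene's Z-score across the cohort before applying
  # its effect, so the explained variance is governed by effect_sizes and
  # noise_sd alone; the response stays exactly linear in the pipeline
  # Z-scores (realised slopes recorded in the truth record).
  zs <- z[signal_idx, , drop = FALSE]
  z_mu <- rowMeans(zs)
  z_sd <- apply(zs, 1L, sd)
  linear_signal <- as.numeric(crossprod((zs - z_mu) / z_sd, eff))
  y <- linear_signal + rnorm(n, 0, config$noise_sd)

  meta_cl <- tibble::tibble(sample_id = cl_ids,
                            source_class = "cell_line",
                            tissue_type = "cell_line",
                            subtype = NA_character_)
  responses <- tibble::tibble(drug_id = config$drug_id,
                              drug_name = config$drug_name,
                              cell_line_id = cl_ids,
                              ln_ic50 = y,
                              release = "GDSC2")

  # External tumour / normal samples
  n_types <- config$n_tumor_types
  spt <- config$samples_per_type
  n_ext <- n_types * spt
  type_labels <- sprintf("tissue_%02d", seq_len(n_types))
  tissue <- rep(type_labels, each = spt)
  n_norm <- round(config$normal_fraction * spt)
  source_class <- rep(c(rep("normal", n_norm), rep("tumor", spt - n_norm)),
                      times = n_types)
  ext_ids <- sprintf("EXT_%02d_%03d", rep(seq_len(n_types), each = spt),
                     rep(seq_len(spt), times = n_types))
  L_ext <- mu + sigma * matrix(rnorm(G * n_ext), nrow = G)
  s_ext <- apply(L_ext, 2L, sd)
  shift_pred <- numeric(n_ext)
  for (t in seq_len(n_types)) {
    idx <- which(tissue == type_labels[t] & source_class == "tumor")
    shift_pred[idx] <- shift_pred[idx] + config$tissue_shifts[t]
  }

  subtype <- rep(NA_character_, n_ext)
  if (config$subtype_count > 0L) {
    sub_labels <- sprintf("subtype_%s", letters[seq_len(config$subtype_count)])
    idx <- which(tissue == type_labels[1L] & source_class == "tumor")
    assigned <- sample(rep_len(sub_labels, length(idx)))
    subtype[idx] <- assigned
    shift_pred[idx] <- shift_pred[idx] +
      config$subtype_shifts[match(assigned, sub_labels)]
  }

  # Mutation carriers among tumour samples, with decoy silent records
  mut_genes <- sample(setdiff(gene_ids, gene_ids[signal_idx]),
                      config$n_mutation_genes)
  tumor_idx <- which(source_class == "tumor")
  mut_rows <- list()
  for (g in mut_genes) {
    carrier <- tumor_idx[runif(length(tumor_idx)) < config$mutation_frequency]
    shift_pred[carrier] <- shift_pred[carrier] + config$mutation_effect
    if (length(carrier)) {
      mut_rows[[length(mut_rows) + 1L]] <- tibble::tibble(
        sample_id = ext_ids[carrier], gene = g,
        variant_class = sample(qualifying_variant_classes(),
                               length(carrier), replace = TRUE))
    }
    decoy <- setdiff(tumor_idx, carrier)
    decoy <- decoy[runif(length(decoy)) < 0.1]
    if (length(decoy)) {
      mut_rows[[length(mut_rows) + 1L]] <- tibble::tibble(
        sample_id = ext_ids[decoy], gene = g,
        variant_class = "Silent")
    }
  }
  mutations <- if (length(mut_rows)) dplyr::bind_rows(mut_rows) else
    tibble::tibble(sample_id = character(), gene = character(),
                   variant_class = character())

  # Apply shifts on the log2 scale so the induced shift on the response
  # scale (through the realised slopes eff_j / z_sd_j on the Z-scores)
  # matches the requested log-unit shift. Because the raw-scale floor and
  # the per-sample re-standardisation are nonlinear, the initial shift is
  # corrected once against the realised response-scale displacement.
  implied_y <- function(raw_m) {
    zz <- pipeline_zscores(raw_m)
    as.numeric(crossprod((zz[signal_idx, , drop = FALSE] - z_mu) / z_sd,
                         eff))
  }
  base_y <- implied_y(pmax(2^L_ext - 1, 0))
  gain <- rep(1, n_ext)
  shifted <- abs(shift_pred) > 1e-8
  apply_gain <- function(gain) {
    L_shifted <- L_ext
    for (j in seq_along(signal_idx)) {
      delta_z <- gain * shift_pred * z_sd[j] * sign(eff[j]) / eff_scale
      L_shifted[signal_idx[j], ] <- L_shifted[signal_idx[j], ] +
        delta_z * s_ext
    }
    L_shifted
  }
  L_shifted <- L_ext
  if (any(shifted)) {
    # per-sample passes: match each sample's realised displacement
    for (pass in 1:4) {
      L_shifted <- apply_gain(gain)
      realised <- implied_y(pmax(2^L_shifted - 1, 0)) - base_y
      ratio <- ifelse(shifted & abs(realised) > 1e-8,
                      shift_pred / realised, 1)
      gain <- gain * pmin(pmax(ratio, 0.25), 4)
    }
    # group passes: the generator's contract is that each shifted group's
    # *median* displacement equals its target, which per-sample matching
    # alone misses when the zero-TPM floor truncates the low tail
    groups <- split(seq_len(n_ext)[shifted],
                    paste(tissue[shifted], source_class[shifted]))
    for (pass in 1:2) {
      L_shifted <- apply_gain(gain)
      realised <- implied_y(pmax(2^L_shifted - 1, 0)) - base_y
      for (idx in groups) {
        target <- median(shift_pred[idx])
        got <- median(realised[idx])
        if (abs(got) > 1e-8) {
          gain[idx] <- gain[idx] * min(max(target / got, 0.5), 2)
        }
      }
    }
    L_shifted <- apply_gain(gain)
  }
  raw_ext <- pmax(2^L_shifted - 1, 0)
  dimnames(raw_ext) <- list(gene_ids, ext_ids)

  if (config$include_duplicate_control) {
    dup <- raw[, 1L, drop = FALSE]
    colnames(dup) <- "DUP_CONTROL_1"
    raw_ext <- cbind(raw_ext, dup)
    ext_ids <- c(ext_ids, "DUP_CONTROL_1")
    tissue <- c(tissue, "duplicate_control")
    source_class <- c(source_class, "tumor")
    subtype <- c(subtype, NA_character_)
  }
  meta_ext <- tibble::tibble(sample_id = ext_ids,
                             source_class = source_class,
                             tissue_type = tissue,
                             subtype = subtype)

  truth <- list(signal_genes = gene_ids[signal_idx],
                signal_index = signal_idx,
                effect_sizes = eff,
                zscore_slopes = eff / z_sd,
                zscore_centers = z_mu,
                noise_sd = config$noise_sd,
                linear_signal = linear_signal,
                tissue_shifts = setNames(config$tissue_shifts, type_labels),
                subtype_shifts = if (config$subtype_count > 0L)
                  setNames(config$subtype_shifts,
                           sprintf("subtype_%s",
                                   letters[seq_len(config$subtype_count)]))
                  else NULL,
                mutation_genes = mut_genes,
                mutation_effect = config$mutation_effect,
                duplicate_control = if (config$include_duplicate_control)
                  list(external_id = "DUP_CONTROL_1",
                       cell_line_id = cl_ids[1L]) else NULL,
                seed = as.integer(seed),
                null = FALSE)

  structure(list(expression = expr_matrix(raw, meta = meta_cl,
                                          transform = "raw"),
                 responses = responses,
                 external = expr_matrix(raw_ext, meta = meta_ext,
                                        transform = "raw"),
                 mutations = mutations,
                 truth = truth,
                 config = config),
            class = "synthetic_study")
}

#' Generate a null study (response independent of expression)
#'
#' Identical marginals to [simulate_drug_study()] but the ln(IC50) values
#' are randomly permuted against the expression profiles, all tissue,
#' subtype and mutation shifts are zeroed, and external tissue labels are
#' therefore exchangeable. Used to calibrate false-positive rates of the
#' predictability call and the specificity rules.
#'
#' @inheritParams simulate_drug_study
#' @return A `synthetic_study` with `truth$null = TRUE`.
#' @export
simulate_null_study <- function(config = synthetic_config(),
                                seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  null_cfg <- config
  null_cfg$tissue_shifts <- rep(0, config$n_tumor_types)
  if (config$subtype_count > 0L) {
    null_cfg$subtype_shifts <- rep(0, config$subtype_count)
  }
  null_cfg$mutation_effect <- 0
  study <- simulate_drug_study(null_cfg, seed = seed)
  study$responses$ln_ic50 <- sample(study$responses$ln_ic50)
  study$truth$null <- TRUE
  study$config <- null_cfg
  study
}

# Reproduce the preparation-chain Z-scores on a raw matrix (no metadata).
pipeline_zscores <- function(raw) {
  xl <- log2(raw + 1)
  mu <- colMeans(xl)
  centred <- sweep(xl, 2L, mu, "-")
  sds <- sqrt(colSums(centred^2) / (nrow(xl) - 1L))
  sweep(centred, 2L, sds, "/")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d genes, %d cell lines, %d external samples%s\n",
              nrow(x$expression$values), ncol(x$expression$values),
              ncol(x$external$values),
              if (isTRUE(x$truth$null)) " (null)" else ""))
  invisible(x)
}

#' Squared correlation between the planted signal and the response
#'
#' Generator self-check: the fraction of response variance explained by the
#' planted linear signal, computed from the truth record.
#'
#' @param study A `synthetic_study`.
#' @return Scalar squared Pearson correlation.
#' @export
signal_r_squared <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  cor(study$truth$linear_signal, study$responses$ln_ic50)^2
}

#' Write a synthetic study to plain-text files
#'
#' Writes `expression.tsv`, `external.tsv`, `responses.tsv`,
#' `metadata.tsv`, `mutations.tsv` and `truth.json` under `dir`.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(study$expression, file.path(dir, "expression.tsv"), "tsv")
  write_expression(study$external, file.path(dir, "external.tsv"), "tsv")
  readr::write_tsv(study$responses, file.path(dir, "responses.tsv"),
                   progress = FALSE)
  meta <- dplyr::bind_rows(study$expression$meta, study$external$meta)
  readr::write_tsv(meta, file.path(dir, "metadata.tsv"), progress = FALSE)
  readr::write_tsv(study$mutations, file.path(dir, "mutations.tsv"),
                   progress = FALSE)
  truth <- study$truth
  truth$linear_signal <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
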