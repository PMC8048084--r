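#' Write per-drug results with a provenance manifest
#'
#' Writes `predictions.tsv` (per-sample observed and aggregated predicted
#' values), `frequencies.tsv` (gene selection counts), `summary.tsv` (the
#' one-row model summary) and, when external predictions are supplied,
#' `external_predictions.tsv`, plus a `manifest.json` recording the seed,
#' configuration, package version, timestamps and MD5 hashes of every file
#' written - enough to re-run the model bit-identically.
#'
#' @param model A `drug_model`.
#' @param dir Output directory (created if needed).
#' @param external_predictions Optional tibble from [predict_external()].
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(model, dir, external_predictions = NULL) {
  stopifnot(inherits(model, "drug_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  files <- c(predictions = "predictions.tsv",
             frequencies = "frequencies.tsv",
             summary = "summary.tsv")
  readr::write_tsv(augment.drug_model(model),
                   file.path(dir, files[["predictions"]]), progress = FALSE)
  readr::write_tsv(selection_frequencies(model),
                   file.path(dir, files[["frequencies"]]), progress = FALSE)
  readr::write_tsv(glance.drug_model(model),
                   file.path(dir, files[["summary"]]), progress = FALSE)
  if (!is.null(external_predictions)) {
    files <- c(files, external = "external_predictions.tsv")
    readr::write_tsv(external_predictions,
                     file.path(dir, files[["external"]]), progress = FALSE)
  }
  hashes <- as.list(tools::md5sum(file.path(dir, unname(files))))
  names(hashes) <- unname(files)
  manifest <- list(
    drug_id = model$drug_id,
    package_version = as.character(utils::packageVersion("gaknn")),
    seed = model$seed,
    runs = model$runs,
    run_seeds = model$seed + seq_len(model$runs),
    config = unclass(model$config),
    threshold = model$threshold,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = hashes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full pipeline on a synthetic or user-supplied study
#'
#' Convenience orchestration: prepares the cell-line and external expression
#' (collapse duplicates, log2(x + 1), per-sample Z-scores), builds the
#' per-drug dataset, fits the Monte-Carlo GA/kNN model, and - when external
#' samples are present - imputes their sensitivity.
#'
#' @param expression Raw [expr_matrix()] of cell lines.
#' @param responses Drug-response tibble (already release-merged).
#' @param drug Drug identifier.
#' @param external Optional raw [expr_matrix()] of tumour/normal samples.
#' @param runs,config,seed,test_fraction Passed to [fit_drug_model()].
#' @return List with elements `dataset`, `model` and (optionally)
#'   `external_predictions`.
#' @export
run_drug_pipeline <- function(expression, responses, drug, external = NULL,
                              runs = 100L, config = ga_config(),
                              seed = 1L, test_fraction = 0.1) {
  expr_z <- prepare_expression(expression)
  dataset <- build_drug_dataset(expr_z, responses, drug)
  if (!is.null(external)) {
    ext_z <- prepare_expression(external)
    dataset <- attach_external(dataset, ext_z)
  }
  model <- fit_drug_model(dataset, runs = runs, config = config,
                          seed = seed, test_fraction = test_fraction)
  out <- list(dataset = dataset, model = model)
  if (!is.null(external)) {
    out$external_predictions <- predict_external(model, dataset)
  }
  out
}
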