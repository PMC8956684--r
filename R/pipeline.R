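#' Simulate a cohort and write it to disk
#'
#' Generates a synthetic cohort from the configuration and writes the matrix
#' TSV, label TSV, and a JSON echo of the configuration into `out_dir`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  paths <- c(matrix = file.path(out_dir, "cohort_matrix.tsv"),
             labels = file.path(out_dir, "cohort_labels.tsv"),
             config = file.path(out_dir, "cohort_config.json"))
  write_cohort(cohort, paths[["matrix"]], paths[["labels"]])
  jsonlite::write_json(unclass(config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the full analysis pipeline on a labeled cohort
#'
#' Orchestrates the complete analysis: stratified train/test split, sparse
#' wrapper search on the training data, optional post-selection by dimension,
#' per-model test metrics and AUCs, lasso baseline with bootstrap confidence
#' intervals, ROC region, events-per-variable per dimension, effect table,
#' synonym detection, co-occurrence network, and frozen models for external
#' validation. A single global seed deterministically derives all per-stage
#' seeds, so a rerun with the same inputs is reproducible file-for-file.
#' When `out_dir` is given, the model set (JSON + TSV), metrics, effect table,
#' network exports, frozen models, and a run manifest are written there.
#'
#' @param cohort a [labeled_cohort()].
#' @param test_size samples held out for testing (default 25).
#' @param swag a [swag_config()]; its seed is overridden by the derived
#'   per-stage seed.
#' @param dims dimensions to keep after the search (default: all).
#' @param min_occurrence occurrence filter for the antagonistic call.
#' @param n_boot bootstrap resamples for the lasso baseline.
#' @param synonym_tolerance AUC tolerance for synonym detection.
#' @param seed global seed.
#' @param out_dir optional output directory.
#' @return list (invisibly when writing) with elements `split`, `model_set`,
#'   `selected`, `metrics`, `aucs`, `lasso`, `roc_region`, `epv`, `effects`,
#'   `synonyms`, `network`, `frozen`, `manifest`.
#' @export
run_pipeline <- function(cohort, test_size = 25L, swag = swag_config(),
                         dims = NULL, min_occurrence = 0.10,
                         n_boot = 2000L, synonym_tolerance = 0,
                         seed = 1L, out_dir = NULL) {
  stopifnot(inherits(cohort, "labeled_cohort"), inherits(swag, "swag_config"))
  seeds <- list(split = derive_seed(seed, 1L), swag = derive_seed(seed, 2L),
                lasso = derive_seed(seed, 3L))
  split <- split_cohort(cohort, test_size = test_size, seed = seeds$split)
  swag$seed <- seeds$swag
  message(sprintf("search: %d features, alpha = %g, p_max = %d",
                  length(cohort$feature_ids), swag$alpha, swag$p_max))
  ms <- run_swag(split$train, swag)
  tab <- table(ms$models$dimension)
  message("retained models per dimension: ",
          paste(sprintf("%s:%d", names(tab), tab), collapse = " "))
  n_sep <- sum(vapply(model_features(ms), function(f) {
    pr <- fit_and_predict(f, split$train, split$train)
    attr(pr, "model")$separated
  }, logical(1)))
  if (n_sep)
    message(sprintf("%d model fit(s) showed complete separation (stabilized)", n_sep))
  selected <- select_model_set(ms, dims = dims)
  selected <- add_test_errors(selected, split$train, split$test)

  metrics <- do.call(rbind, lapply(model_features(selected), function(f) {
    pr <- fit_and_predict(f, split$train, split$test)
    m <- confusion_metrics(split$test$labels, pr)
    data.frame(model = join_features(f), dimension = length(f),
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, ppv = m$ppv, npv = m$npv,
               auc = auc(split$test$labels, pr), stringsAsFactors = FALSE)
  }))
  aucs <- metrics$auc
  lasso <- lasso_baseline(split$train, split$test, n_boot = n_boot,
                          seed = seeds$lasso)
  region <- roc_region(selected, split$train, split$test)
  n_events <- min(table(split$train$labels))
  epv_tab <- data.frame(dimension = sort(unique(selected$models$dimension)))
  epv_tab$epv <- epv(n_events, epv_tab$dimension)
  effects <- effect_table(selected, cohort, min_occurrence = min_occurrence)
  synonyms <- find_synonyms(selected, aucs, tolerance = synonym_tolerance)
  net <- build_network(selected, effects, cohort)
  frozen <- freeze_models(selected, split$train)
  manifest <- list(seed = seed, seeds = seeds, test_size = test_size,
                   swag = unclass(swag), dims = dims,
                   min_occurrence = min_occurrence, n_boot = n_boot,
                   synonym_tolerance = synonym_tolerance,
                   n_samples = length(cohort$labels),
                   n_features = length(cohort$feature_ids),
                   package_version = as.character(utils::packageVersion("sparsewrap")))
  out <- list(split = split, model_set = ms, selected = selected,
              metrics = metrics, aucs = aucs, lasso = lasso,
              roc_region = region, epv = epv_tab, effects = effects,
              synonyms = synonyms, network = net, frozen = frozen,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_model_set(selected, file.path(out_dir, "model_set.json"))
    write_model_set_tsv(selected, file.path(out_dir, "model_set.tsv"))
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(effects, file.path(out_dir, "effects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(synonyms, file.path(out_dir, "synonyms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_network_graphml(net, file.path(out_dir, "network.graphml"))
    write_network_edgelist(net, file.path(out_dir, "network_edges.tsv"))
    write_frozen_models(frozen, file.path(out_dir, "frozen_models.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(out))
  }
  out
}

#' Validate frozen models against a new cohort
#'
#' Runs both validation modes of [apply_frozen_models()]: prediction-mode
#' metrics with the original coefficients, and refit-mode sign concordance of
#' the single and associative coefficients.
#'
#' @param frozen a `frozen_models` object or a path to a frozen-models JSON.
#' @param cohort a [labeled_cohort()] containing every model feature.
#' @param min_occurrence occurrence filter for the refit classification.
#' @return list with `prediction` (metrics per model) and `refit`
#'   (concordance table and refitted effect table).
#' @export
validate_frozen <- function(frozen, cohort, min_occurrence = 0.10) {
  if (is.character(frozen)) frozen <- read_frozen_models(frozen)
  list(prediction = apply_frozen_models(frozen, cohort, mode = "predict"),
       refit = apply_frozen_models(frozen, cohort, mode = "refit",
                                   min_occurrence = min_occurrence))
}
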