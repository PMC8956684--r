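#' Serialize a model set to JSON and back
#'
#' The JSON form stores the retained models (feature-id arrays, dimensions,
#' cross-validation errors, optional test errors), the screening result, the
#' per-dimension retention thresholds, and an echo of the search configuration
#' including the seed, so a run can be audited and reloaded.
#'
#' @param model_set a `swag_model_set`.
#' @param path file path.
#' @return `write_model_set` returns `path` invisibly; `read_model_set`
#'   returns a `swag_model_set`.
#' @export
write_model_set <- function(model_set, path) {
  stopifnot(inherits(model_set, "swag_model_set"))
  payload <- list(
    models = lapply(seq_len(nrow(model_set$models)), function(i) {
      row <- model_set$models[i, ]
      out <- list(features = split_features(row$features)[[1L]],
                  dimension = row$dimension, cv_error = row$cv_error)
      if (!is.null(row$test_error)) out$test_error <- row$test_error
      out
    }),
    screening = if (!is.null(model_set$screening)) list(
      features = model_set$screening$features,
      errors = as.list(model_set$screening$errors),
      threshold = model_set$screening$threshold
    ),
    thresholds = as.list(model_set$thresholds),
    config = unclass(model_set$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_set
#' @export
read_model_set <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- do.call(rbind, lapply(payload$models, function(m) {
    df <- data.frame(dimension = as.integer(m$dimension),
                     features = join_features(unlist(m$features)),
                     cv_error = as.numeric(m$cv_error),
                     stringsAsFactors = FALSE)
    if (!is.null(m$test_error)) df$test_error <- as.numeric(m$test_error)
    df
  }))
  screening <- NULL
  if (!is.null(payload$screening)) {
    errors <- unlist(payload$screening$errors)
    screening <- structure(
      list(features = unlist(payload$screening$features),
           errors = errors,
           threshold = as.numeric(payload$screening$threshold)),
      class = "swag_screening")
  }
  cfg <- payload$config
  config <- if (!is.null(cfg))
    swag_config(p_max = cfg$p_max, alpha = cfg$alpha,
                m_models = if (is.character(cfg$m_models)) Inf else cfg$m_models,
                k_folds = cfg$k_folds, n_repeats = cfg$n_repeats,
                seed = cfg$seed, ridge = cfg$ridge)
  thresholds <- unlist(payload$thresholds)
  new_model_set(models, screening, config, thresholds)
}

#' Write / read a model set as a flat TSV
#'
#' One model per row: pipe-joined feature ids, dimension, cross-validation
#' error, and the test error when present — the layout used for supplementary
#' model listings. `read_model_list` also accepts minimal files with just a
#' `features` column (e.g. a published model list), returning a model set
#' usable for occurrence, co-occurrence, and network reconstruction.
#'
#' @param model_set a `swag_model_set`.
#' @param path file path.
#' @return `write_model_set_tsv` returns `path` invisibly; `read_model_list`
#'   returns a `swag_model_set` (without screening/config when the file does
#'   not carry them).
#' @export
write_model_set_tsv <- function(model_set, path) {
  stopifnot(inherits(model_set, "swag_model_set"))
  utils::write.table(model_set$models, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_model_set_tsv
#' @export
read_model_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"features" %in% names(df))
    stop("model list must have a 'features' column of pipe-joined ids")
  if (nrow(df) == 0L) stop("empty model list")
  feats <- split_features(df$features)
  if (any(lengths(feats) == 0L)) stop("model list contains an empty model")
  if (is.null(df$dimension)) df$dimension <- lengths(feats)
  if (is.null(df$cv_error)) df$cv_error <- NA_real_
  df$dimension <- as.integer(df$dimension)
  if (!all(df$dimension == lengths(feats)))
    stop("dimension column disagrees with the number of features")
  keep <- c("dimension", "features", "cv_error",
            intersect("test_error", names(df)))
  new_model_set(df[, keep, drop = FALSE], screening = NULL, config = NULL,
                thresholds = NULL)
}

#' Build a model set directly from feature lists
#'
#' Wraps a list of feature-id vectors (e.g. a published model list, or models
#' chosen by hand) as a `swag_model_set` so the occurrence, co-occurrence,
#' effect, and network machinery can be applied to it.
#'
#' @param feature_sets list of character vectors, one per model.
#' @param cv_error optional cross-validation errors (recycled).
#' @return a `swag_model_set` without screening/config provenance.
#' @export
as_model_set <- function(feature_sets, cv_error = NA_real_) {
  stopifnot(is.list(feature_sets), length(feature_sets) >= 1L,
            all(lengths(feature_sets) >= 1L))
  df <- data.frame(
    dimension = lengths(feature_sets),
    features = vapply(feature_sets, join_features, character(1)),
    cv_error = rep_len(as.numeric(cv_error), length(feature_sets)),
    stringsAsFactors = FALSE)
  new_model_set(df, screening = NULL, config = NULL, thresholds = NULL)
}
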