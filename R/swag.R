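#' Configuration for the sparse wrapper model search
#'
#' Parameters of the greedy wrapper: a screening step fits every one-feature
#' model and keeps the best `alpha` proportion; each growing step extends the
#' retained models of the previous dimension with one screened feature at a
#' time, scores the candidates by repeated stratified k-fold cross-validation,
#' and again keeps the best `alpha` proportion, up to dimension `p_max`.
#'
#' The two roles that a single symbol often plays in wrapper descriptions are
#' deliberately separated here: `n_repeats` is the number of cross-validation
#' repetitions and `m_models` the number of candidate models built per
#' dimension.
#'
#' @param p_max maximum model dimension (number of features per model).
#' @param alpha retention proportion in (0, 1); typical values 0.01-0.1, kept
#'   deliberately small so only the strongest models survive each step.
#' @param m_models candidate models built per dimension; `Inf` requests
#'   exhaustive candidate generation.
#' @param k_folds cross-validation folds (default 10).
#' @param n_repeats cross-validation repetitions (default 10).
#' @param seed integer seed controlling fold assignment and candidate sampling.
#' @param ridge stabilization penalty forwarded to [fit_logit()].
#' @return object of class `swag_config`.
#' @export
swag_config <- function(p_max = 5L, alpha = 0.05, m_models = 100L,
                        k_folds = 10L, n_repeats = 10L, seed = 1L,
                        ridge = 1e-6) {
  stopifnot(is_count(p_max),
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            (is.numeric(m_models) && length(m_models) == 1L &&
               (is.infinite(m_models) || m_models >= 1)),
            is_count(k_folds), k_folds >= 2,
            is_count(n_repeats),
            is.numeric(seed), length(seed) == 1L)
  structure(list(p_max = as.integer(p_max), alpha = alpha,
                 m_models = m_models, k_folds = as.integer(k_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 ridge = ridge),
            class = "swag_config")
}

# Stratified fold assignment: within each repeat, class indices are shuffled
# and dealt cyclically across folds, the second class continuing the cycle
# where the first stopped so fold sizes differ by at most one (this also makes
# k = n exact leave-one-out). If any training complement would contain a
# single class, the stratification is redrawn with a perturbed seed.
make_cv_folds <- function(y, k, n_repeats, seed) {
  n <- length(y)
  stopifnot(k >= 2L, k <= n)
  idx0 <- which(y == 0L)
  idx1 <- which(y == 1L)
  folds <- vector("list", 0L)
  for (r in seq_len(n_repeats)) {
    ok <- FALSE
    for (attempt in 1:25) {
      fr <- with_seed(derive_seed(seed, r * 1000L + attempt), {
        f <- integer(n)
        f[sample(idx0)] <- ((seq_along(idx0) - 1L) %% k) + 1L
        start1 <- length(idx0) %% k
        f[sample(idx1)] <- ((seq_along(idx1) - 1L + start1) %% k) + 1L
        f
      })
      ok <- all(vapply(seq_len(k), function(j) {
        sum(fr == j) > 0L && length(unique(y[fr != j])) == 2L
      }, logical(1)))
      if (ok) break
      message(sprintf("fold stratification redrawn (repeat %d, attempt %d): a training fold had one class",
                      r, attempt))
    }
    if (!ok) stop("could not stratify folds with both classes in every training set")
    folds <- c(folds, lapply(seq_len(k), function(j) which(fr == j)))
  }
  folds
}

#' Repeated cross-validated misclassification error of a feature subset
#'
#' Mean held-out misclassification proportion at the 0.5 probability cutoff
#' over `k_folds` x `n_repeats` class-stratified folds. Standardization
#' parameters (column means/sds) are computed on the training folds only.
#' Deterministic given the config seed; all models scored against the same
#' config share the same folds, which makes their errors directly comparable.
#'
#' @param features character vector of feature ids.
#' @param cohort a [labeled_cohort()] with both classes present.
#' @param config a [swag_config()].
#' @param folds optional precomputed fold list (internal reuse).
#' @return misclassification proportion in \[0, 1\].
#' @export
cv_error <- function(features, cohort, config, folds = NULL) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  unknown <- setdiff(features, cohort$feature_ids)
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  y <- cohort$labels
  if (length(unique(y)) < 2L) stop("cohort must contain both classes")
  if (is.null(folds))
    folds <- make_cv_folds(y, config$k_folds, config$n_repeats, config$seed)
  x <- cohort$matrix[, features, drop = FALSE]
  n <- length(y)
  errs <- vapply(folds, function(hold) {
    tr <- seq_len(n)[-hold]
    xtr <- x[tr, , drop = FALSE]
    ctr <- colMeans(xtr)
    sds <- sqrt(colSums(sweep(xtr, 2L, ctr)^2) / max(1L, length(tr) - 1L))
    sds[sds < 1e-12] <- 1
    xtr <- sweep(sweep(xtr, 2L, ctr), 2L, sds, "/")
    fit <- fit_logit(xtr, y[tr], ridge = config$ridge)
    xte <- sweep(sweep(x[hold, , drop = FALSE], 2L, ctr), 2L, sds, "/")
    pr <- predict(fit, xte)
    mean((pr >= 0.5) != (y[hold] == 1L))
  }, numeric(1))
  mean(errs)
}

# Inclusive empirical alpha-quantile retention: the threshold is the
# ceiling(alpha * n)-th smallest error and everything <= it (all ties) is kept.
retention_threshold <- function(errors, alpha) {
  stopifnot(length(errors) >= 1L)
  unname(sort(errors)[max(1L, ceiling(alpha * length(errors)))])
}

#' Screening step: evaluate and filter all one-feature models
#'
#' Fits all p one-feature models, scores each by [cv_error()], and retains the
#' features whose error is at or below the empirical alpha-quantile of the p
#' errors (ties at the threshold are all retained). Only these survivors are
#' eligible for higher-dimensional models.
#'
#' @inheritParams cv_error
#' @return object of class `swag_screening`: `features` (retained ids),
#'   `errors` (named, all p), `threshold`.
#' @export
screen_features <- function(cohort, config, folds = NULL) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  p <- length(cohort$feature_ids)
  if (p == 0L) stop("cohort has no features to screen")
  if (is.null(folds))
    folds <- make_cv_folds(cohort$labels, config$k_folds, config$n_repeats,
                           config$seed)
  errors <- vapply(cohort$feature_ids, function(f)
    cv_error(f, cohort, config, folds), numeric(1))
  thr <- retention_threshold(errors, config$alpha)
  structure(list(features = cohort$feature_ids[errors <= thr],
                 errors = errors, threshold = thr),
            class = "swag_screening")
}

#' Grow candidate models of the next dimension
#'
#' Builds up to `m_models` candidate feature sets of dimension `d`, each the
#' union of a model sampled uniformly (with replacement) from the retained
#' models of dimension `d - 1` and one screened feature not already in it.
#' Duplicate feature sets are removed after formation. When the number of
#' distinct achievable combinations does not exceed `m_models` the exact
#' exhaustive set is returned instead of sampling.
#'
#' @param prev_retained list of character vectors (retained models, dim d-1).
#' @param screened character vector of screening survivors.
#' @param d target dimension (>= 2).
#' @param config a [swag_config()].
#' @param seed sampling seed (defaults to a value derived from the config).
#' @return list of character feature vectors, each of length `d`.
#' @export
grow_dimension <- function(prev_retained, screened, d, config,
                           seed = derive_seed(config$seed, d)) {
  stopifnot(d >= 2L, length(prev_retained) >= 1L)
  if (!all(lengths(prev_retained) == d - 1L))
    stop("all previous-dimension models must have exactly d - 1 features")
  # enumerate the distinct achievable combinations
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  exhaustive <- list()
  for (m in prev_retained) {
    for (f in setdiff(screened, m)) {
      cand <- c(m, f)
      key <- feature_key(cand)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        exhaustive[[length(exhaustive) + 1L]] <- cand
      }
    }
  }
  n_distinct <- length(exhaustive)
  if (n_distinct == 0L) {
    warning("no screened feature can extend any model; returning empty candidate set")
    return(list())
  }
  if (is.infinite(config$m_models) || n_distinct <= config$m_models) {
    ord <- order(vapply(exhaustive, feature_key, character(1)))
    return(exhaustive[ord])
  }
  m_target <- as.integer(config$m_models)
  with_seed(seed, {
    out <- vector("list", m_target)
    keys <- new.env(parent = emptyenv(), hash = TRUE)
    got <- 0L
    draws <- 0L
    max_draws <- 50L * m_target
    while (got < m_target && draws < max_draws) {
      draws <- draws + 1L
      base <- prev_retained[[sample.int(length(prev_retained), 1L)]]
      pool <- setdiff(screened, base)
      if (!length(pool)) next
      cand <- c(base, pool[sample.int(length(pool), 1L)])
      key <- feature_key(cand)
      if (!exists(key, envir = keys, inherits = FALSE)) {
        assign(key, TRUE, envir = keys)
        got <- got + 1L
        out[[got]] <- cand
      }
    }
    if (got < m_target)
      message(sprintf("candidate generation stopped at %d of %d distinct sets after %d draws",
                      got, m_target, draws))
    out[seq_len(got)]
  })
}

new_model_set <- function(models, screening, config, thresholds) {
  stopifnot(is.data.frame(models),
            all(c("dimension", "features", "cv_error") %in% names(models)))
  structure(list(models = models, screening = screening, config = config,
                 thresholds = thresholds),
            class = "swag_model_set")
}

#' Run the full sparse wrapper search
#'
#' Screening, then for each dimension d = 2..p_max: grow candidates from the
#' previous dimension's retained models, score each by repeated
#' cross-validation, and retain the models whose error is at or below the
#' empirical alpha-quantile of that dimension's candidate errors. Fully
#' reproducible given the config seed. The result is the set of near-equivalent
#' sparse models that all downstream analysis (effects, networks) reads.
#'
#' @inheritParams cv_error
#' @return object of class `swag_model_set` with elements `models` (data frame:
#'   `dimension`, `features` as pipe-joined ids, `cv_error`), `screening`,
#'   `config`, `thresholds` (per-dimension retention thresholds).
#' @examples
#' cfg <- cohort_config(150, 6, effects = c(`1` = 2, `2` = -2), seed = 3)
#' cohort <- generate_cohort(cfg)
#' ms <- run_swag(cohort, swag_config(p_max = 2, alpha = 0.3, n_repeats = 2))
#' ms$models
#' @export
run_swag <- function(cohort, config = swag_config()) {
  stopifnot(inherits(cohort, "labeled_cohort"), inherits(config, "swag_config"))
  folds <- make_cv_folds(cohort$labels, config$k_folds, config$n_repeats,
                         config$seed)
  scr <- screen_features(cohort, config, folds)
  models <- data.frame(dimension = 1L, features = scr$features,
                       cv_error = unname(scr$errors[scr$features]),
                       stringsAsFactors = FALSE)
  thresholds <- c(`1` = scr$threshold)
  prev <- as.list(scr$features)
  d <- 2L
  while (d <= config$p_max && length(prev)) {
    cands <- grow_dimension(prev, scr$features, d, config,
                            seed = derive_seed(config$seed, d))
    if (!length(cands)) break
    errs <- vapply(cands, cv_error, numeric(1), cohort = cohort,
                   config = config, folds = folds)
    thr <- retention_threshold(errs, config$alpha)
    keep <- errs <= thr
    prev <- cands[keep]
    models <- rbind(models, data.frame(
      dimension = d,
      features = vapply(cands[keep], join_features, character(1)),
      cv_error = errs[keep], stringsAsFactors = FALSE))
    thresholds[as.character(d)] <- thr
    d <- d + 1L
  }
  rownames(models) <- NULL
  new_model_set(models, scr, config, thresholds)
}

#' @exportS3Method base::print
print.swag_model_set <- function(x, ...) {
  tab <- table(x$models$dimension)
  cat(sprintf("<swag_model_set> %d models (%s); %d screened features\n",
              nrow(x$models),
              paste(sprintf("dim %s: %d", names(tab), tab), collapse = ", "),
              length(x$screening$features %||% character())))
  invisible(x)
}

# List of character feature vectors, one per retained model.
model_features <- function(model_set) {
  split_features(model_set$models$features)
}

#' Post-process a model set by dimension and test error
#'
#' Returns the retained models of the requested dimensions, optionally filtered
#' by a test-error ceiling (requires a `test_error` column, see
#' [add_test_errors()]), ordered by cross-validation error.
#'
#' @param model_set a `swag_model_set`.
#' @param dims integer vector of dimensions to keep (default: all).
#' @param max_test_error optional ceiling on held-out test error.
#' @return a `swag_model_set` containing the selected rows.
#' @export
select_model_set <- function(model_set, dims = NULL, max_test_error = NULL) {
  stopifnot(inherits(model_set, "swag_model_set"))
  df <- model_set$models
  if (!is.null(dims)) {
    stopifnot(all(dims >= 1L))
    df <- df[df$dimension %in% as.integer(dims), , drop = FALSE]
  }
  if (!is.null(max_test_error)) {
    if (is.null(df$test_error))
      stop("model set has no test errors; call add_test_errors() first")
    df <- df[df$test_error <= max_test_error, , drop = FALSE]
  }
  df <- df[order(df$cv_error), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) == 0L) warning("selection returned no models")
  new_model_set(df, model_set$screening, model_set$config,
                model_set$thresholds)
}

#' Attach held-out test errors to a model set
#'
#' Fits every retained model on the training cohort (train-only
#' standardization) and records its misclassification proportion on the test
#' cohort at the 0.5 cutoff, in a `test_error` column.
#'
#' @param model_set a `swag_model_set`.
#' @param train,test [labeled_cohort()] objects.
#' @return the model set with a `test_error` column.
#' @export
add_test_errors <- function(model_set, train, test) {
  stopifnot(inherits(model_set, "swag_model_set"))
  feats <- model_features(model_set)
  model_set$models$test_error <- vapply(feats, function(f) {
    pr <- fit_and_predict(f, train, test)
    mean((pr >= 0.5) != (test$labels == 1L))
  }, numeric(1))
  model_set
}

# Internal invariant checker used by the property tests: screened-feature
# closure, per-dimension threshold compliance, and no duplicate feature sets.
validate_model_set <- function(model_set) {
  df <- model_set$models
  feats <- split_features(df$features)
  scr <- model_set$screening$features
  multi <- df$dimension >= 2L
  stopifnot(all(unlist(feats[multi]) %in% scr))
  stopifnot(all(lengths(feats) == df$dimension))
  for (d in unique(df$dimension)) {
    sel <- df$dimension == d
    keys <- vapply(feats[sel], feature_key, character(1))
    stopifnot(!anyDuplicated(keys))
    thr <- model_set$thresholds[[as.character(d)]]
    stopifnot(all(df$cv_error[sel] <= thr + 1e-12))
  }
  stopifnot(all(df$cv_error >= 0), all(df$cv_error <= 1))
  invisible(TRUE)
}
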