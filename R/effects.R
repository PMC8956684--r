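#' Standardize the design matrix of a cohort
#'
#' Centers and rescales every column to mean 0 and sd 1 so that coefficients
#' are comparable across models and features. The transformation parameters
#' are stored in the returned cohort (`$standardization`) and the operation is
#' idempotent: a cohort already carrying them is returned unchanged.
#'
#' @param cohort a [labeled_cohort()].
#' @return the cohort with standardized columns and a `standardization`
#'   element (`center`, `scale`).
#' @export
standardize_design <- function(cohort) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  if (!is.null(cohort$standardization)) return(cohort)
  x <- cohort$matrix
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  bad <- which(scale < 1e-12)
  if (length(bad))
    stop("constant column(s): ", paste(cohort$feature_ids[bad], collapse = ", "))
  x <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  out <- labeled_cohort(x, cohort$labels, cohort$feature_ids, cohort$sample_ids)
  out$standardization <- list(center = center, scale = scale)
  out
}

#' Undo the standardization of a cohort
#'
#' @param cohort a cohort produced by [standardize_design()].
#' @return the cohort on its original scale.
#' @export
unstandardize_design <- function(cohort) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  st <- cohort$standardization
  if (is.null(st)) return(cohort)
  x <- sweep(sweep(cohort$matrix, 2L, st$scale, "*"), 2L, st$center, "+")
  labeled_cohort(x, cohort$labels, cohort$feature_ids, cohort$sample_ids)
}

#' Single (marginal) logistic coefficient of one feature
#'
#' The slope of the one-feature logistic fit (with intercept) on the
#' standardized design — the feature's effect when considered in isolation.
#'
#' @param feature a feature id.
#' @param cohort a [labeled_cohort()]; standardized internally if needed.
#' @return the estimated slope.
#' @export
single_beta <- function(feature, cohort) {
  stopifnot(length(feature) == 1L)
  cohort <- standardize_design(cohort)
  if (!feature %in% cohort$feature_ids) stop("unknown feature: ", feature)
  fit <- fit_logit(cohort$matrix[, feature, drop = FALSE], cohort$labels)
  unname(fit$coefficients[2L])
}

#' Associative coefficients of a feature across a model set
#'
#' Refits every retained model containing the feature on the standardized
#' design and collects the feature's coefficient in each — the distribution of
#' its effect across the contexts (feature combinations) in which the wrapper
#' retained it. Summarized by the median and the (min, max) range.
#'
#' @param feature a feature id.
#' @param model_set a `swag_model_set`.
#' @param cohort a [labeled_cohort()]; standardized internally if needed.
#' @return list with `values` (named by model), `median`, `range` (length-2).
#' @export
associative_betas <- function(feature, model_set, cohort) {
  stopifnot(inherits(model_set, "swag_model_set"), length(feature) == 1L)
  cohort <- standardize_design(cohort)
  feats <- model_features(model_set)
  containing <- which(vapply(feats, function(f) feature %in% f, logical(1)))
  if (!length(containing))
    stop("feature ", feature, " occurs in no retained model")
  values <- vapply(containing, function(i) {
    f <- feats[[i]]
    fit <- fit_logit(cohort$matrix[, f, drop = FALSE], cohort$labels)
    unname(fit$coefficients[match(feature, f) + 1L])
  }, numeric(1))
  names(values) <- model_set$models$features[containing]
  list(values = values, median = stats::median(values),
       range = c(min(values), max(values)))
}

#' Proportion of retained models containing a feature
#'
#' @param feature a feature id.
#' @param model_set a `swag_model_set`.
#' @return proportion in \[0, 1\].
#' @export
occurrence_rate <- function(feature, model_set) {
  stopifnot(inherits(model_set, "swag_model_set"))
  feats <- model_features(model_set)
  if (!length(feats)) stop("empty model set")
  mean(vapply(feats, function(f) feature %in% f, logical(1)))
}

#' Classify a feature's effect from its single and associative coefficients
#'
#' A feature is *oncogenic* when both its single and median associative
#' coefficients are positive, *protective* when both are negative, and
#' *antagonistic* when the two signs disagree and the feature occurs in at
#' least `min_occurrence` of the retained models — the operational marker of a
#' context-dependent (Yule–Simpson-type) effect. Discordant features below the
#' occurrence filter, and exact-zero coefficients, are *unstable*.
#'
#' @param beta_single single coefficient (or an `effect_profile` object, in
#'   which case the remaining arguments are taken from it).
#' @param median_associative median associative coefficient.
#' @param occurrence proportion of retained models containing the feature.
#' @param min_occurrence occurrence filter for the antagonistic call
#'   (default 0.10).
#' @return one of `"oncogenic"`, `"protective"`, `"antagonistic"`,
#'   `"unstable"`.
#' @examples
#' classify_effect(-0.736, 0.939, occurrence = 0.25) # "antagonistic"
#' classify_effect(1.427, 2.120, occurrence = 0.75)  # "oncogenic"
#' @export
classify_effect <- function(beta_single, median_associative = NULL,
                            occurrence = NULL, min_occurrence = 0.10) {
  if (inherits(beta_single, "effect_profile")) {
    p <- beta_single
    return(classify_effect(p$beta_single, p$median_associative,
                           p$occurrence_rate, min_occurrence))
  }
  stopifnot(is.numeric(beta_single), is.numeric(median_associative),
            is.numeric(occurrence))
  if (beta_single == 0 || median_associative == 0) {
    warning("exact-zero coefficient: no sign, classified unstable")
    return("unstable")
  }
  s1 <- sign(beta_single)
  s2 <- sign(median_associative)
  if (s1 == s2) return(if (s1 > 0) "oncogenic" else "protective")
  if (occurrence >= min_occurrence) "antagonistic" else "unstable"
}

#' Full effect profile of a feature
#'
#' Combines the single coefficient, the associative coefficients across the
#' model set (median and range), the occurrence rate, and the resulting effect
#' class.
#'
#' @param feature a feature id.
#' @param model_set a `swag_model_set`.
#' @param cohort a [labeled_cohort()].
#' @param min_occurrence occurrence filter for [classify_effect()].
#' @return object of class `effect_profile`.
#' @export
effect_profile <- function(feature, model_set, cohort, min_occurrence = 0.10) {
  cohort <- standardize_design(cohort)
  assoc <- associative_betas(feature, model_set, cohort)
  bs <- single_beta(feature, cohort)
  occ <- occurrence_rate(feature, model_set)
  structure(list(feature_id = feature, beta_single = bs,
                 betas_associative = assoc$values,
                 median_associative = assoc$median,
                 range_associative = assoc$range,
                 occurrence_rate = occ,
                 effect_class = classify_effect(bs, assoc$median, occ,
                                                min_occurrence)),
            class = "effect_profile")
}

#' @exportS3Method base::print
print.effect_profile <- function(x, ...) {
  cat(sprintf(paste0("<effect_profile> %s [%s]\n",
                     "  single beta %.3f | median associative %.3f ",
                     "(range %.3f..%.3f) | occurrence %.1f%%\n"),
              x$feature_id, x$effect_class, x$beta_single,
              x$median_associative, x$range_associative[1L],
              x$range_associative[2L], 100 * x$occurrence_rate))
  invisible(x)
}

#' Effect table for all (or selected) features of a model set
#'
#' One row per feature: single coefficient, median associative coefficient,
#' associative range, occurrence percentage, and effect class — the tabular
#' summary of the single-versus-associative analysis.
#'
#' @param model_set a `swag_model_set`.
#' @param cohort a [labeled_cohort()].
#' @param features feature ids (default: every feature in the model set).
#' @param min_occurrence occurrence filter for the antagonistic call.
#' @return data frame with columns `feature`, `single_beta`,
#'   `median_associative`, `assoc_min`, `assoc_max`, `occurrence_pct`,
#'   `effect_class`, ordered by decreasing occurrence.
#' @export
effect_table <- function(model_set, cohort, features = NULL,
                         min_occurrence = 0.10) {
  cohort <- standardize_design(cohort)
  features <- features %||% sort(unique(unlist(model_features(model_set))))
  rows <- lapply(features, function(f) {
    p <- effect_profile(f, model_set, cohort, min_occurrence)
    data.frame(feature = f, single_beta = p$beta_single,
               median_associative = p$median_associative,
               assoc_min = p$range_associative[1L],
               assoc_max = p$range_associative[2L],
               occurrence_pct = 100 * p$occurrence_rate,
               effect_class = p$effect_class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$occurrence_pct, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect interchangeable feature pairs (synonyms) in a model set
#'
#' Two features are synonyms when two retained models exist whose feature sets
#' differ exactly by swapping one for the other and whose test AUCs differ by
#' at most `tolerance` — substitution without loss of predictive power. The
#' shared context (the features common to both models) is reported with each
#' pair.
#'
#' @param model_set a `swag_model_set`.
#' @param aucs numeric vector of test AUCs aligned with the model-set rows
#'   (see [model_aucs()]).
#' @param tolerance maximum AUC difference (default 0, an exact tie).
#' @return data frame with columns `feature_a`, `feature_b`, `context`,
#'   `auc_a`, `auc_b` (zero rows when no pair qualifies).
#' @export
find_synonyms <- function(model_set, aucs, tolerance = 0) {
  stopifnot(inherits(model_set, "swag_model_set"),
            length(aucs) == nrow(model_set$models))
  feats <- model_features(model_set)
  out <- list()
  nm <- length(feats)
  for (i in seq_len(max(0L, nm - 1L))) {
    for (j in seq.int(i + 1L, nm)) {
      if (length(feats[[i]]) != length(feats[[j]])) next
      d1 <- setdiff(feats[[i]], feats[[j]])
      d2 <- setdiff(feats[[j]], feats[[i]])
      if (length(d1) != 1L || length(d2) != 1L) next
      if (abs(aucs[i] - aucs[j]) > tolerance + 1e-12) next
      pair <- sort(c(d1, d2))
      out[[length(out) + 1L]] <- data.frame(
        feature_a = pair[1L], feature_b = pair[2L],
        context = join_features(sort(intersect(feats[[i]], feats[[j]]))),
        auc_a = aucs[i], auc_b = aucs[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(feature_a = character(), feature_b = character(),
                      context = character(), auc_a = numeric(),
                      auc_b = numeric(), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, out))
  rownames(out) <- NULL
  out
}

#' Test AUC of every model in a set
#'
#' @param model_set a `swag_model_set`.
#' @param train,test [labeled_cohort()] objects.
#' @return numeric vector of AUCs aligned with the model-set rows.
#' @export
model_aucs <- function(model_set, train, test) {
  vapply(model_features(model_set), function(f) {
    auc(test$labels, fit_and_predict(f, train, test))
  }, numeric(1))
}

#' Freeze the fitted models of a model set
#'
#' Fits every retained model on the training cohort (train-only
#' standardization) and records intercepts, slopes, and standardization
#' parameters, plus the single coefficients of every involved feature, so the
#' models can be applied unchanged to an external validation cohort.
#'
#' @param model_set a `swag_model_set`.
#' @param train a [labeled_cohort()].
#' @return object of class `frozen_models`.
#' @export
freeze_models <- function(model_set, train) {
  stopifnot(inherits(model_set, "swag_model_set"))
  feats <- model_features(model_set)
  models <- lapply(feats, function(f) {
    pr <- fit_and_predict(f, train, train)
    attr(pr, "model")
  })
  all_feats <- sort(unique(unlist(feats)))
  singles <- vapply(all_feats, single_beta, numeric(1), cohort = train)
  structure(list(models = models,
                 single_betas = stats::setNames(singles, all_feats)),
            class = "frozen_models")
}

#' Write / read frozen models as JSON
#'
#' @param frozen a [freeze_models()] result.
#' @param path file path.
#' @return `write_frozen_models` returns `path` invisibly; `read_frozen_models`
#'   returns a `frozen_models` object.
#' @export
write_frozen_models <- function(frozen, path) {
  stopifnot(inherits(frozen, "frozen_models"))
  jsonlite::write_json(
    list(models = lapply(frozen$models, function(m) {
      list(features = m$features, intercept = m$intercept,
           slopes = as.list(m$slopes), center = as.list(m$center),
           scale = as.list(m$scale))
    }),
    single_betas = as.list(frozen$single_betas)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frozen_models
#' @export
read_frozen_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(payload$models)) stop("empty model file")
  models <- lapply(payload$models, function(m) {
    list(features = unlist(m$features), intercept = as.numeric(m$intercept),
         slopes = unlist(m$slopes), center = unlist(m$center),
         scale = unlist(m$scale), separated = FALSE)
  })
  structure(list(models = models, single_betas = unlist(payload$single_betas)),
            class = "frozen_models")
}

#' Apply frozen models to a new cohort
#'
#' Two validation modes. In `"predict"` mode the frozen coefficients (with the
#' original training standardization) are evaluated on the new cohort,
#' returning one metrics row per model. In `"refit"` mode the same models are
#' re-estimated on the new cohort and the sign concordance of the single and
#' associative coefficients with the originals is reported per feature —
#' checking whether each feature's direction of effect replicates.
#'
#' @param frozen a `frozen_models` object.
#' @param new_cohort a [labeled_cohort()] containing every model feature.
#' @param mode `"predict"` or `"refit"`.
#' @param min_occurrence occurrence filter forwarded to the refit effect
#'   classification.
#' @return In predict mode: list with `metrics` (data frame, one row per
#'   model) and `probabilities`. In refit mode: list with `concordance` (data
#'   frame per feature: original and refitted single/median-associative
#'   coefficients, sign agreement) and `effects` (refitted effect table).
#' @export
apply_frozen_models <- function(frozen, new_cohort,
                                mode = c("predict", "refit"),
                                min_occurrence = 0.10) {
  stopifnot(inherits(frozen, "frozen_models"),
            inherits(new_cohort, "labeled_cohort"))
  mode <- match.arg(mode)
  needed <- sort(unique(unlist(lapply(frozen$models, `[[`, "features"))))
  missing <- setdiff(needed, new_cohort$feature_ids)
  if (length(missing))
    stop("new cohort is missing feature(s): ", paste(missing, collapse = ", "))
  if (mode == "predict") {
    probs <- lapply(frozen$models, function(m) {
      x <- sweep(sweep(new_cohort$matrix[, m$features, drop = FALSE],
                       2L, m$center), 2L, m$scale, "/")
      drop(plogis(m$intercept + x %*% m$slopes))
    })
    metrics <- do.call(rbind, lapply(seq_along(probs), function(i) {
      m <- confusion_metrics(new_cohort$labels, probs[[i]])
      data.frame(model = join_features(frozen$models[[i]]$features),
                 accuracy = m$accuracy, sensitivity = m$sensitivity,
                 specificity = m$specificity, ppv = m$ppv, npv = m$npv,
                 stringsAsFactors = FALSE)
    }))
    return(list(metrics = metrics, probabilities = probs))
  }
  # refit mode: rebuild a model set from the frozen feature lists
  ms <- new_model_set(
    data.frame(dimension = lengths(lapply(frozen$models, `[[`, "features")),
               features = vapply(frozen$models, function(m)
                 join_features(m$features), character(1)),
               cv_error = NA_real_, stringsAsFactors = FALSE),
    screening = NULL, config = NULL, thresholds = NULL)
  std <- standardize_design(new_cohort)
  eff <- effect_table(ms, std, min_occurrence = min_occurrence)
  orig_assoc <- lapply(stats::setNames(needed, needed), function(f) {
    vals <- unlist(lapply(frozen$models, function(m)
      if (f %in% m$features) unname(m$slopes[f])))
    stats::median(vals)
  })
  conc <- do.call(rbind, lapply(needed, function(f) {
    new_single <- eff$single_beta[eff$feature == f]
    new_assoc <- eff$median_associative[eff$feature == f]
    os <- unname(frozen$single_betas[f])
    oa <- orig_assoc[[f]]
    data.frame(feature = f,
               single_orig = os, single_new = new_single,
               assoc_orig = oa, assoc_new = new_assoc,
               single_concordant = sign(os) == sign(new_single),
               assoc_concordant = sign(oa) == sign(new_assoc),
               stringsAsFactors = FALSE)
  }))
  list(concordance = conc, effects = eff)
}
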