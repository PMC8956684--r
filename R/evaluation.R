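#' Stratified train/test split of a labeled cohort
#'
#' Splits a cohort into disjoint, exhaustive train and test parts. With
#' stratification (the default) the per-class test counts follow
#' largest-remainder rounding of `test_size * class_n / n`, so class
#' proportions of both parts differ from the cohort's by at most one sample
#' per class; a 70/55 cohort split with `test_size = 25` gives exactly a 56/44
#' training and a 14/11 test composition. Reproducible given the seed.
#'
#' @param cohort a [labeled_cohort()].
#' @param test_size number of test samples (or use `test_fraction`).
#' @param test_fraction fraction of samples for the test set.
#' @param stratified stratify by class (default TRUE).
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both [labeled_cohort()]s.
#' @export
split_cohort <- function(cohort, test_size = NULL, test_fraction = NULL,
                         stratified = TRUE, seed = 1L) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  n <- length(cohort$labels)
  if (is.null(test_size)) {
    stopifnot(is.numeric(test_fraction), test_fraction > 0, test_fraction < 1)
    test_size <- round(n * test_fraction)
  }
  test_size <- as.integer(test_size)
  if (test_size < 2L || test_size >= n)
    stop("test size must be between 2 and n - 1")
  if (stratified) {
    counts <- c(sum(cohort$labels == 0L), sum(cohort$labels == 1L))
    quota <- test_size * counts / n
    base <- floor(quota)
    rem <- test_size - sum(base)
    if (rem > 0) {
      ord <- order(quota - base, decreasing = TRUE)
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    test_idx <- with_seed(seed, c(
      sample(which(cohort$labels == 0L), base[1L]),
      sample(which(cohort$labels == 1L), base[2L])
    ))
  } else {
    test_idx <- with_seed(seed, sample.int(n, test_size))
  }
  test_idx <- sort(test_idx)
  train <- subset_cohort(cohort, setdiff(seq_len(n), test_idx))
  test <- subset_cohort(cohort, test_idx)
  if (length(unique(train$labels)) < 2L || length(unique(test$labels)) < 2L)
    stop("a class is absent from the train or test part; use stratification or a larger split")
  list(train = train, test = test)
}

#' Fit a model on the training cohort and predict the test cohort
#'
#' Standardizes the selected columns with training means/sds only, fits the
#' ridge-stabilized logistic regression, and returns predicted probabilities
#' for the test samples. The fitted model (intercept, slopes, standardization
#' parameters, separation flag) is attached as attribute `"model"` so it can be
#' frozen and reapplied to external cohorts.
#'
#' @param features character vector of feature ids; `character(0)` fits the
#'   intercept-only model (constant probability = training prevalence).
#' @param train,test [labeled_cohort()] objects containing the features.
#' @return numeric vector of test probabilities with attribute `"model"`.
#' @export
fit_and_predict <- function(features, train, test) {
  stopifnot(inherits(train, "labeled_cohort"), inherits(test, "labeled_cohort"))
  missing_tr <- setdiff(features, train$feature_ids)
  missing_te <- setdiff(features, test$feature_ids)
  if (length(missing_tr) || length(missing_te))
    stop("feature(s) absent: ",
         paste(unique(c(missing_tr, missing_te)), collapse = ", "))
  xtr <- train$matrix[, features, drop = FALSE]
  center <- colMeans(xtr)
  scale <- apply(xtr, 2L, stats::sd)
  scale[scale < 1e-12] <- 1
  xtr <- sweep(sweep(xtr, 2L, center), 2L, scale, "/")
  fit <- fit_logit(xtr, train$labels)
  xte <- sweep(sweep(test$matrix[, features, drop = FALSE], 2L, center),
               2L, scale, "/")
  pr <- predict(fit, xte)
  b <- fit$coefficients
  model <- list(features = as.character(features), intercept = unname(b[1L]),
                slopes = stats::setNames(unname(b[-1L]), features),
                center = center, scale = scale, separated = fit$separated)
  attr(pr, "model") <- model
  pr
}

#' Confusion-matrix metrics at a probability cutoff
#'
#' Thresholds probabilities at `>= cutoff` (a prediction exactly at the cutoff
#' counts as positive) and reports accuracy, sensitivity, specificity,
#' positive and negative predictive values together with the TP/FP/TN/FN
#' counts. Ratios with a zero denominator (e.g. sensitivity when no positives
#' are present) are reported as `NA`, never silently as 0.
#'
#' @param labels binary 0/1 vector.
#' @param probabilities predicted probabilities, same length.
#' @param cutoff threshold in (0, 1), default 0.5.
#' @return object of class `metrics_report` (a named list).
#' @examples
#' confusion_metrics(c(0, 0, 1, 1), c(0.1, 0.6, 0.7, 0.9))
#' @export
confusion_metrics <- function(labels, probabilities, cutoff = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(0L, 1L)),
            cutoff > 0, cutoff < 1)
  pred <- probabilities >= cutoff
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  n <- length(labels)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(accuracy = (tp + tn) / n,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp),
                 npv = ratio(tn, tn + fn),
                 tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 cutoff = cutoff),
            class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> n = %d, cutoff = %.2f\n",
                     "  accuracy %.3f | sens %.3f | spec %.3f | ppv %.3f | npv %.3f\n",
                     "  TP %d FP %d TN %d FN %d\n"),
              x$n, x$cutoff, x$accuracy, x$sensitivity, x$specificity,
              x$ppv, x$npv, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' `roc_curve` returns the (FPR, TPR) points at every distinct score threshold
#' plus the endpoints (0,0) and (1,1). `auc` integrates it by the trapezoid
#' rule, which equals the probability that a random positive outranks a random
#' negative with ties half-credited.
#'
#' @param labels binary 0/1 vector with both classes present.
#' @param scores numeric scores (higher = more positive).
#' @return `roc_curve`: data frame with columns `fpr`, `tpr`; `auc`: a number
#'   in \[0, 1\].
#' @examples
#' auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)) # 0.75
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  pos <- sum(labels == 1L)
  neg <- sum(labels == 0L)
  if (pos == 0L || neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  keep <- !duplicated(s, fromLast = TRUE) # last index within each tied block
  data.frame(fpr = c(0, fp[keep] / neg), tpr = c(0, tp[keep] / pos))
}

#' @rdname roc_curve
#' @export
auc <- function(labels, scores) {
  rc <- roc_curve(labels, scores)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

# Staircase value of a ROC curve at a grid point: the highest TPR reached at
# or below the given FPR.
interp_roc <- function(curve, grid) {
  vapply(grid, function(g) max(curve$tpr[curve$fpr <= g + 1e-12]), numeric(1))
}

#' ROC region of a model set
#'
#' Fits every model on the training cohort, computes its ROC curve on the test
#' cohort, interpolates all curves onto a common FPR grid, and returns the
#' pointwise lower and upper envelopes — the region jointly enclosing all the
#' model-set ROC curves.
#'
#' @param models a `swag_model_set` or a list of character feature vectors.
#' @param train,test [labeled_cohort()] objects.
#' @param grid FPR grid in \[0, 1\].
#' @return object of class `roc_region`: `fpr` (grid), `curves` (models x grid
#'   TPR matrix), `lower`, `upper`.
#' @export
roc_region <- function(models, train, test, grid = seq(0, 1, by = 0.01)) {
  feats <- if (inherits(models, "swag_model_set")) model_features(models)
           else models
  stopifnot(length(feats) >= 1L, all(grid >= 0), all(grid <= 1))
  grid <- sort(unique(c(0, grid, 1)))
  curves <- t(vapply(feats, function(f) {
    pr <- fit_and_predict(f, train, test)
    interp_roc(roc_curve(test$labels, pr), grid)
  }, numeric(length(grid))))
  structure(list(fpr = grid, curves = curves,
                 lower = apply(curves, 2L, min),
                 upper = apply(curves, 2L, max)),
            class = "roc_region")
}

#' Events per variable
#'
#' The size of the smaller outcome category divided by the number of model
#' variables — a rough index of external validity for logistic models (values
#' around 10 are commonly considered safe, values below 4 problematic).
#'
#' @param n_events size of the smaller outcome class.
#' @param n_variables number of variables in the model.
#' @return `n_events / n_variables`.
#' @examples
#' epv(44, 5) # 8.8
#' epv(44, 4) # 11
#' @export
epv <- function(n_events, n_variables) {
  stopifnot(is.numeric(n_events), is.numeric(n_variables),
            n_events > 0)
  if (any(n_variables <= 0)) stop("n_variables must be positive")
  n_events / n_variables
}

#' Lasso baseline with bootstrap confidence intervals
#'
#' The reference single-model selector: an L1-penalized logistic regression on
#' the standardized training cohort with the penalty chosen by 10-fold
#' cross-validated misclassification, evaluated on the test cohort at the 0.5
#' cutoff. 95% percentile bootstrap confidence intervals for each metric are
#' obtained by resampling the test rows `n_boot` times.
#'
#' @param train,test [labeled_cohort()] objects.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed (penalty CV and bootstrap).
#' @return list with `selected` (nonzero-coefficient features), `coefficients`,
#'   `metrics` (a [confusion_metrics()] report), `ci` (2 x metrics matrix of
#'   percentile bounds), `probabilities`, `n_boot`.
#' @export
lasso_baseline <- function(train, test, n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(train, "labeled_cohort"), inherits(test, "labeled_cohort"))
  xtr <- train$matrix
  center <- colMeans(xtr)
  scale <- apply(xtr, 2L, stats::sd)
  scale[scale < 1e-12] <- 1
  xtr <- sweep(sweep(xtr, 2L, center), 2L, scale, "/")
  cvfit <- with_seed(derive_seed(seed, 1L),
    glmnet::cv.glmnet(xtr, train$labels, family = "binomial",
                      type.measure = "class", nfolds = 10L,
                      standardize = FALSE))
  co <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
  selected <- rownames(co)[-1L][co[-1L, 1L] != 0]
  if (!length(selected))
    warning("lasso selected no features; intercept-only baseline")
  xte <- sweep(sweep(test$matrix, 2L, center), 2L, scale, "/")
  pr <- drop(stats::predict(cvfit, xte, s = "lambda.min", type = "response"))
  metrics <- confusion_metrics(test$labels, pr)
  metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  boot <- with_seed(derive_seed(seed, 2L), {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(pr), replace = TRUE)
      if (length(unique(test$labels[idx])) < 2L)
        return(rep(NA_real_, length(metric_names)))
      m <- confusion_metrics(test$labels[idx], pr[idx])
      unlist(m[metric_names])
    }, numeric(length(metric_names))))
  })
  ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  colnames(ci) <- metric_names
  list(selected = selected,
       coefficients = stats::setNames(co[, 1L], rownames(co)),
       metrics = metrics, ci = ci, probabilities = pr, n_boot = n_boot)
}
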