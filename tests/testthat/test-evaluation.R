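test_that("stratified splitting reproduces the 70/55 -> 56/44 + 14/11 design", {
  set.seed(1)
  y <- sample(rep(c(0L, 1L), c(70, 55)))
  co <- labeled_cohort(matrix(rnorm(125 * 3), 125, 3), y)
  parts <- split_cohort(co, test_size = 25, seed = 8)
  expect_equal(as.vector(table(parts$train$labels)), c(56, 44))
  expect_equal(as.vector(table(parts$test$labels)), c(14, 11))
  # same seed: identical partition; parts disjoint and exhaustive
  parts2 <- split_cohort(co, test_size = 25, seed = 8)
  expect_identical(parts$test$sample_ids, parts2$test$sample_ids)
  expect_length(intersect(parts$train$sample_ids, parts$test$sample_ids), 0L)
  expect_setequal(c(parts$train$sample_ids, parts$test$sample_ids),
                  co$sample_ids)
})

test_that("degenerate split requests are rejected", {
  co <- noise_cohort(n = 30, seed = 2)
  expect_error(split_cohort(co, test_size = 1), "between 2")
  expect_error(split_cohort(co, test_size = 30), "between 2")
  lopsided <- labeled_cohort(matrix(rnorm(40), 20, 2),
                             c(1L, rep(0L, 19)))
  expect_error(split_cohort(lopsided, test_size = 4), "absent")
})

test_that("split class proportions stay within one sample per class", {
  for (s in 1:20) {
    n <- sample(40:200, 1)
    y <- rbinom(n, 1, runif(1, 0.25, 0.75))
    if (length(unique(y)) < 2) next
    co <- labeled_cohort(matrix(rnorm(n * 2), n, 2), y)
    ts <- sample(5:(n - 5), 1)
    parts <- tryCatch(split_cohort(co, test_size = ts, seed = s),
                      error = function(e) NULL)
    if (is.null(parts)) next
    for (part in parts) {
      n_part <- length(part$labels)
      expect_lte(abs(sum(part$labels) - n_part * mean(y)), 1 + 1e-9)
    }
  }
})

test_that("confusion metrics satisfy their identities on random tables", {
  set.seed(10)
  for (rep in 1:60) {
    counts <- as.vector(rmultinom(1, size = sample(5:60, 1), prob = runif(4)))
    labels <- rep(c(1L, 1L, 0L, 0L), counts)   # TP, FN, TN, FP
    probs <- rep(c(0.9, 0.1, 0.1, 0.9), counts)
    m <- confusion_metrics(labels, probs)
    expect_equal(m$tp + m$fp + m$tn + m$fn, m$n)
    expect_equal(m$accuracy, (m$tp + m$tn) / m$n)
    if (m$tp + m$fn > 0) expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
    else expect_true(is.na(m$sensitivity))
    if (m$tn + m$fp > 0) expect_equal(m$specificity, m$tn / (m$tn + m$fp))
    else expect_true(is.na(m$specificity))
    if (m$tp + m$fp > 0) expect_equal(m$ppv, m$tp / (m$tp + m$fp))
    else expect_true(is.na(m$ppv))
    if (m$tn + m$fn > 0) expect_equal(m$npv, m$tn / (m$tn + m$fn))
    else expect_true(is.na(m$npv))
  }
})

test_that("worked metric examples come out exactly", {
  # TP=10, FN=1, TN=13, FP=1
  labels <- rep(c(1L, 1L, 0L, 0L), c(10, 1, 13, 1))
  probs <- rep(c(0.8, 0.2, 0.2, 0.8), c(10, 1, 13, 1))
  m <- confusion_metrics(labels, probs)
  expect_equal(m$accuracy, 0.92)
  expect_equal(m$ppv, 10 / 11)
  expect_equal(m$npv, 13 / 14)
  # all-negative classifier on 14 normal / 11 carcinoma
  m2 <- confusion_metrics(rep(c(0L, 1L), c(14, 11)), rep(0.1, 25))
  expect_equal(m2$accuracy, 0.56)
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)
  expect_equal(m2$npv, 14 / 25)
  expect_true(is.na(m2$ppv)) # no positive predictions: PPV undefined
  # perfect classification
  m3 <- confusion_metrics(rep(c(0L, 1L), c(14, 11)),
                          rep(c(0.1, 0.9), c(14, 11)))
  expect_equal(unlist(m3[c("accuracy", "sensitivity", "specificity",
                           "ppv", "npv")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 ppv = 1, npv = 1))
})

test_that("a prediction exactly at the cutoff counts as positive", {
  m <- confusion_metrics(c(0L, 1L), c(0.5, 0.5))
  expect_equal(m$tp, 1L)
  expect_equal(m$fp, 1L)
})

test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  set.seed(20)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 1) # coarse grid forces ties
    expect_equal(auc(labels, scores), pair_count_auc(labels, scores))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (rep in 1:5) {
    labels <- rbinom(40, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(40), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(labels, scores), ref)
  }
})

test_that("ROC curves are monotone staircases with fixed endpoints", {
  set.seed(22)
  labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- c(0L, 1L)
  scores <- rnorm(30)
  rc <- roc_curve(labels, scores)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_error(roc_curve(rep(1L, 5), rnorm(5)), "both classes")
  # independent scores at large n sit near the diagonal
  set.seed(23)
  expect_lt(abs(auc(rbinom(4000, 1, 0.5), rnorm(4000)) - 0.5), 0.03)
})

test_that("the ROC region envelopes are exact pointwise extrema", {
  cfg <- cohort_config(120, 6, prevalence = 0.5,
                       effects = c(`1` = 1.5, `2` = -1), seed = 41)
  co <- generate_cohort(cfg)
  parts <- split_cohort(co, test_size = 40, seed = 2)
  models <- list("f001", c("f001", "f002"), c("f002", "f003"))
  region <- roc_region(models, parts$train, parts$test)
  expect_equal(region$lower, apply(region$curves, 2, min))
  expect_equal(region$upper, apply(region$curves, 2, max))
  expect_true(all(region$lower <= region$upper))
  for (i in seq_along(models)) {
    expect_true(all(region$curves[i, ] >= region$lower - 1e-12))
    expect_true(all(region$curves[i, ] <= region$upper + 1e-12))
    expect_true(all(diff(region$curves[i, ]) >= -1e-12))
  }
  # a single model degenerates to its own curve
  solo <- roc_region(models[1], parts$train, parts$test)
  expect_equal(solo$lower, solo$upper)
  # adding a model never shrinks the region
  expect_true(all(region$lower <= solo$lower + 1e-12))
  expect_true(all(region$upper >= solo$upper - 1e-12))
})

test_that("events-per-variable arithmetic is exact", {
  expect_equal(epv(44, 5), 8.8)
  expect_equal(epv(44, 4), 11)
  expect_equal(epv(37, 1), 37)
  expect_error(epv(44, 0), "positive")
})

test_that("fit_and_predict handles the degenerate model forms", {
  co <- separable_cohort(n = 30, n_noise = 1, seed = 51)
  # perfect separator scored on its own training data
  pr <- fit_and_predict("sep", co, co)
  expect_true(all((pr >= 0.5) == (co$labels == 1L)))
  # intercept-only model: constant probability equal to train prevalence
  pr0 <- fit_and_predict(character(0), co, co)
  expect_equal(unique(round(pr0, 10)), round(mean(co$labels), 10))
  expect_error(fit_and_predict("ghost", co, co), "ghost")
})

test_that("the lasso baseline selects a dominant feature and bounds its CIs", {
  cfg <- cohort_config(250, 8, prevalence = 0.5, effects = c(`1` = 3),
                       seed = 61)
  co <- generate_cohort(cfg)
  parts <- split_cohort(co, test_size = 60, seed = 3)
  res <- lasso_baseline(parts$train, parts$test, n_boot = 300, seed = 4)
  expect_true("f001" %in% res$selected)
  expect_gt(res$metrics$accuracy, 0.7)
  for (m in colnames(res$ci)) {
    lo <- res$ci[1, m]; hi <- res$ci[2, m]
    expect_true(lo <= hi)
    expect_gte(lo, 0); expect_lte(hi, 1)
    expect_true(res$metrics[[m]] >= lo - 1e-9 && res$metrics[[m]] <= hi + 1e-9)
  }
  # identical seed reproduces the baseline exactly
  res2 <- lasso_baseline(parts$train, parts$test, n_boot = 300, seed = 4)
  expect_identical(res$ci, res2$ci)
})
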