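test_that("standardization is exact, idempotent, and reversible", {
  co <- noise_cohort(n = 50, p = 4, seed = 3)
  co$matrix <- co$matrix * 3 + 7
  std <- standardize_design(co)
  expect_lt(max(abs(colMeans(std$matrix))), 1e-10)
  expect_lt(max(abs(apply(std$matrix, 2, sd) - 1)), 1e-10)
  expect_identical(standardize_design(std), std)
  back <- unstandardize_design(std)
  expect_equal(back$matrix, co$matrix, tolerance = 1e-10)
  # a simple hand case: column (1,2,3)
  tiny <- labeled_cohort(matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "v")),
                         c(0L, 1L, 1L))
  stiny <- standardize_design(tiny)
  expect_equal(as.vector(stiny$matrix), c(-1, 0, 1))
  # constant column: error names the feature
  cc <- labeled_cohort(cbind(ok = rnorm(10), flat = rep(2, 10)),
                       rep(c(0L, 1L), 5))
  expect_error(standardize_design(cc), "flat")
})

test_that("single coefficients recover the generative marginal effect", {
  # null feature: coefficient near zero
  co <- noise_cohort(n = 5000, p = 1, seed = 5)
  expect_lt(abs(single_beta("n1", co)), 0.1)
  # planted marginal slope 2 on a standardized single-feature design
  cfg <- cohort_config(20000, 1, prevalence = 0.5, effects = c(`1` = 2),
                       seed = 6)
  co2 <- generate_cohort(cfg)
  expect_lt(abs(single_beta("f001", co2) - 2), 0.1)
})

test_that("associative coefficients degenerate to the single fit for one-feature models", {
  co <- noise_cohort(n = 300, p = 3, seed = 7)
  ms <- manual_model_set(list("n1"))
  assoc <- associative_betas("n1", ms, co)
  expect_equal(unname(assoc$values), single_beta("n1", co), tolerance = 1e-9)
  expect_equal(assoc$median, assoc$range[1])
  expect_error(associative_betas("n2", ms, co), "no retained model")
})

test_that("independent covariates give associative values near the single value", {
  cfg <- cohort_config(20000, 3, prevalence = 0.5,
                       effects = c(`1` = 1, `2` = 0.8), seed = 8)
  co <- generate_cohort(cfg)
  ms <- manual_model_set(list(c("f001", "f002"), c("f001", "f003")))
  assoc <- associative_betas("f001", ms, co)
  bs <- single_beta("f001", co)
  # no confounding: the gap is attenuation only, small at these effect sizes
  expect_lt(max(abs(assoc$values - bs)), 0.25)
  expect_true(assoc$range[1] <= assoc$median && assoc$median <= assoc$range[2])
})

test_that("Simpson cohorts yield opposite-signed associative values across contexts", {
  cfg <- simpson_config(1, 3, -0.8, n_samples = 20000, seed = 9)
  co <- generate_cohort(cfg)
  ms <- manual_model_set(list("f001", c("f001", "f002")))
  assoc <- associative_betas("f001", ms, co)
  expect_lt(assoc$values[["f001"]], 0)           # confounded context
  expect_gt(assoc$values[["f001|f002"]], 0)      # deconfounded context
})

test_that("effect classification follows the sign/occurrence rule", {
  expect_equal(classify_effect(-0.736, 0.939, occurrence = 0.25),
               "antagonistic")
  expect_equal(classify_effect(1.427, 2.120, occurrence = 0.75), "oncogenic")
  expect_equal(classify_effect(-2.191, -0.979, occurrence = 0.446),
               "protective")
  expect_equal(classify_effect(-0.5, 0.5, occurrence = 0.05), "unstable")
  expect_equal(classify_effect(0.694, -0.753, occurrence = 0.10),
               "antagonistic") # boundary occurrence is inclusive
  expect_warning(cls <- classify_effect(0, 1, occurrence = 0.5), "zero")
  expect_equal(cls, "unstable")
})

test_that("occurrence rates are exact model-count fractions", {
  sets <- c(lapply(1:84, function(i) c("A", paste0("x", i))),
            lapply(1:28, function(i) c("B", paste0("y", i))))
  ms <- manual_model_set(sets)
  expect_equal(occurrence_rate("A", ms), 84 / 112)
  expect_equal(100 * occurrence_rate("A", ms), 75.0)
  expect_equal(occurrence_rate("x1", ms), 1 / 112)
  expect_equal(occurrence_rate("absent", ms), 0)
  ms_all <- manual_model_set(list(c("A", "B"), c("A", "C")))
  expect_equal(occurrence_rate("A", ms_all), 1)
})

test_that("effect profiles bracket their median and carry consistent fields", {
  cfg <- cohort_config(600, 6, prevalence = 0.5,
                       effects = c(`1` = 1.5, `2` = -1.5), seed = 10)
  co <- generate_cohort(cfg)
  ms <- manual_model_set(list(c("f001", "f002"), c("f001", "f003"),
                              c("f002", "f004")))
  for (f in c("f001", "f002")) {
    p <- effect_profile(f, ms, co)
    expect_true(p$range_associative[1] <= p$median_associative)
    expect_true(p$median_associative <= p$range_associative[2])
    expect_true(all(p$betas_associative >= p$range_associative[1]))
    expect_true(all(p$betas_associative <= p$range_associative[2]))
    expect_equal(p$occurrence_rate,
                 length(p$betas_associative) / nrow(ms$models))
    expect_equal(p$effect_class, classify_effect(p))
  }
  tab <- effect_table(ms, co)
  expect_setequal(tab$feature, c("f001", "f002", "f003", "f004"))
  expect_equal(tab$effect_class[tab$feature == "f001"], "oncogenic")
  expect_equal(tab$effect_class[tab$feature == "f002"], "protective")
})

test_that("synonym detection finds exactly the one-feature swaps within tolerance", {
  ms <- manual_model_set(list(c("a", "b", "c", "d", "e"),
                              c("a", "b", "c", "d", "f"),
                              c("a", "b", "c", "g", "h"),
                              c("a", "b", "c", "d", "e")))
  aucs <- c(1, 1, 1, 1)
  syn <- find_synonyms(ms, aucs)
  expect_true(any(syn$feature_a == "e" & syn$feature_b == "f"))
  expect_equal(syn$context[syn$feature_a == "e" & syn$feature_b == "f"],
               "a|b|c|d")
  # duplicates (rows 1 and 4) are not a swap; two-position differences are not
  expect_false(any(syn$feature_a == syn$feature_b))
  expect_false(any(syn$feature_a == "g" | syn$feature_b == "g"))
  # a performance gap beyond tolerance suppresses the pair
  syn2 <- find_synonyms(ms, c(1, 0.8, 1, 1), tolerance = 0.1)
  expect_false(any(syn2$feature_a == "e" & syn2$feature_b == "f"))
  syn3 <- find_synonyms(ms, c(1, 0.8, 1, 1), tolerance = 0.3)
  expect_true(any(syn3$feature_a == "e" & syn3$feature_b == "f"))
})

test_that("frozen models reproduce training metrics and validate structure", {
  cfg <- cohort_config(200, 5, prevalence = 0.5,
                       effects = c(`1` = 2, `2` = -1.5), seed = 11)
  co <- generate_cohort(cfg)
  ms <- manual_model_set(list(c("f001", "f002"), c("f001", "f003")))
  frozen <- freeze_models(ms, co)
  # prediction mode on the training cohort equals direct training metrics
  val <- apply_frozen_models(frozen, co, mode = "predict")
  for (i in 1:2) {
    pr <- fit_and_predict(strsplit(ms$models$features[i], "|", fixed = TRUE)[[1]],
                          co, co)
    m <- confusion_metrics(co$labels, pr)
    expect_equal(val$metrics$accuracy[i], m$accuracy)
    expect_equal(val$metrics$sensitivity[i], m$sensitivity)
  }
  # label permutation drops accuracy to the class prior
  set.seed(15)
  perm <- labeled_cohort(co$matrix, sample(co$labels))
  prior <- max(mean(perm$labels), 1 - mean(perm$labels))
  valp <- apply_frozen_models(frozen, perm, mode = "predict")
  expect_lt(mean(valp$metrics$accuracy), prior + 0.1)
  # missing feature is reported by id
  small <- labeled_cohort(co$matrix[, 1:2], co$labels)
  expect_error(apply_frozen_models(frozen, small), "f003")
})

test_that("refit mode reports sign concordance across cohorts of one config", {
  cfg1 <- cohort_config(1500, 4, prevalence = 0.5,
                        effects = c(`1` = 2, `2` = -1.5), seed = 12)
  cfg2 <- cfg1; cfg2$seed <- 13L
  co1 <- generate_cohort(cfg1)
  co2 <- generate_cohort(cfg2)
  ms <- manual_model_set(list(c("f001", "f002"), c("f001", "f003")))
  frozen <- freeze_models(ms, co1)
  val <- apply_frozen_models(frozen, co2, mode = "refit")
  planted <- val$concordance[val$concordance$feature %in% c("f001", "f002"), ]
  expect_true(all(planted$single_concordant))
  expect_true(all(planted$assoc_concordant))
  expect_setequal(val$effects$feature, c("f001", "f002", "f003"))
})

test_that("frozen-model JSON round trips", {
  co <- separable_cohort(n = 40, n_noise = 2, seed = 14)
  ms <- manual_model_set(list(c("sep", "noise1")))
  frozen <- freeze_models(ms, co)
  path <- withr::local_tempfile(fileext = ".json")
  write_frozen_models(frozen, path)
  back <- read_frozen_models(path)
  expect_equal(back$models[[1]]$slopes, frozen$models[[1]]$slopes)
  expect_equal(back$single_betas, frozen$single_betas)
  jsonlite::write_json(list(models = list()), path, auto_unbox = TRUE)
  expect_error(read_frozen_models(path), "empty")
})
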