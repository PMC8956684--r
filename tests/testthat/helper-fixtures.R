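# Fixture builders shared across the test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# A cohort whose first feature is a perfect separator (+1 for cases, -1 for
# controls) followed by `n_noise` standard-normal noise features.
separable_cohort <- function(n = 40L, n_noise = 3L, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- cbind(ifelse(y == 1L, 1, -1) + 0,
             matrix(rnorm(n * n_noise), n, n_noise))
  colnames(x) <- c("sep", sprintf("noise%d", seq_len(n_noise)))
  labeled_cohort(x, y)
}

# A pure-noise cohort: labels independent of all features.
noise_cohort <- function(n = 200L, p = 5L, prevalence = 0.5, seed = 1L) {
  set.seed(seed)
  labeled_cohort(matrix(rnorm(n * p), n, p,
                        dimnames = list(NULL, paste0("n", seq_len(p)))),
                 rbinom(n, 1L, prevalence))
}

# Build a minimal model set directly from a list of feature vectors, for
# occurrence / co-occurrence / network arithmetic tests.
manual_model_set <- function(feature_sets, cv_error = NA_real_) {
  as_model_set(feature_sets, cv_error)
}

# Brute-force AUC: fraction of positive-negative pairs where the positive
# outranks the negative, ties half-credited.
pair_count_auc <- function(labels, scores) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}
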