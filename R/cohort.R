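#' Configuration for a synthetic labeled cohort
#'
#' Describes the generative model used throughout the package's simulations: a
#' correlated Gaussian design (unit marginal variance within configured
#' correlation blocks, scaled by `noise_sd`) and a binary outcome drawn from a
#' logistic model whose intercept is solved numerically so that the marginal
#' prevalence matches `prevalence`. This emulates the statistical structure of
#' a case/control expression study — a few informative features with positive or
#' negative conditional log-odds effects, correlated blocks that can flip
#' marginal signs (Yule–Simpson reversals), and many pure-noise features — at
#' the default prevalence of a 55-carcinoma / 70-normal cohort.
#'
#' @param n_samples number of samples to draw.
#' @param n_features number of features (columns).
#' @param prevalence probability of the positive (carcinoma) class, in (0, 1).
#' @param effects named numeric vector mapping feature index (as name) to its
#'   conditional log-odds coefficient; unlisted features have effect 0.
#' @param correlation_blocks list of blocks, each `list(indices =, rho =)`,
#'   giving a set of feature indices and their common pairwise correlation.
#' @param noise_sd marginal standard deviation of every feature.
#' @param seed integer seed; generation is bit-reproducible given the config.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()], [simpson_config()]
#' @export
cohort_config <- function(n_samples, n_features, prevalence = 0.44,
                          effects = numeric(), correlation_blocks = list(),
                          noise_sd = 1, seed = 1L) {
  stopifnot(is_count(n_samples), is_count(n_features),
            is.numeric(prevalence), length(prevalence) == 1L,
            prevalence > 0, prevalence < 1,
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd > 0,
            is.numeric(seed), length(seed) == 1L)
  effects <- effects[effects != 0]
  if (length(effects)) {
    idx <- suppressWarnings(as.integer(names(effects)))
    if (anyNA(idx) || any(idx < 1L) || any(idx > n_features) || anyDuplicated(idx))
      stop("`effects` must be named by distinct feature indices in 1..n_features")
  }
  cfg <- structure(
    list(n_samples = as.integer(n_samples), n_features = as.integer(n_features),
         prevalence = prevalence, effects = effects,
         correlation_blocks = correlation_blocks, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
  build_sigma(cfg) # validates blocks (indices in range, positive definite)
  cfg
}

# Assemble the feature correlation matrix from the configured blocks,
# rejecting any block whose implied matrix is not positive definite.
build_sigma <- function(config) {
  p <- config$n_features
  sigma <- diag(p)
  for (b in seq_along(config$correlation_blocks)) {
    blk <- config$correlation_blocks[[b]]
    idx <- as.integer(blk$indices)
    rho <- blk$rho
    if (anyNA(idx) || any(idx < 1L) || any(idx > p) || anyDuplicated(idx) ||
        length(idx) < 2L)
      stop(sprintf("correlation block %d: indices must be >= 2 distinct features in 1..%d",
                   b, p))
    if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1)
      stop(sprintf("correlation block %d: rho must be in (-1, 1)", b))
    m <- length(idx)
    # equicorrelation matrix is positive definite iff rho > -1/(m-1)
    if (rho <= -1 / (m - 1))
      stop(sprintf("correlation block %d is not positive definite: rho = %g with %d features requires rho > %g",
                   b, rho, m, -1 / (m - 1)))
    sigma[idx, idx] <- rho
    sigma[cbind(idx, idx)] <- 1
  }
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stop("combined correlation blocks yield a non-positive-definite matrix (overlapping blocks?)")
  attr(sigma, "chol") <- ch
  sigma
}

# Solve the logistic intercept so that the population prevalence under the
# Gaussian design equals the target: E_Z[ plogis(b0 + s Z) ] = prevalence,
# with s the sd of the linear predictor. 1-D root finding, not sampling, so
# prevalence is decoupled from effect sizes.
solve_intercept <- function(prevalence, s) {
  if (s < 1e-12) return(qlogis(prevalence))
  f <- function(b0) {
    stats::integrate(function(z) plogis(b0 + s * z) * stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value - prevalence
  }
  half <- 10 + 5 * s
  stats::uniroot(f, interval = qlogis(prevalence) + c(-half, half),
                 tol = 1e-10)$root
}

# Expand the sparse effects map to a full coefficient vector.
effect_vector <- function(config) {
  beta <- numeric(config$n_features)
  if (length(config$effects))
    beta[as.integer(names(config$effects))] <- as.numeric(config$effects)
  beta
}

#' Construct a labeled cohort object
#'
#' The container every analysis stage consumes: an expression-like matrix
#' (samples x features, continuous log-intensity scale) and a binary outcome
#' per sample (1 = case / invasive carcinoma).
#'
#' @param matrix numeric matrix, samples in rows.
#' @param labels binary 0/1 vector, one per sample.
#' @param feature_ids,sample_ids unique identifiers; default to the matrix
#'   dimnames or generated ids.
#' @return object of class `labeled_cohort` with elements `matrix`, `labels`,
#'   `feature_ids`, `sample_ids`.
#' @export
labeled_cohort <- function(matrix, labels, feature_ids = NULL, sample_ids = NULL) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (nrow(matrix) == 0L) stop("empty cohort")
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(matrix), all(labels %in% c(0L, 1L)))
  if (anyNA(matrix)) stop("cohort matrix contains missing values")
  feature_ids <- feature_ids %||% colnames(matrix) %||%
    sprintf("f%03d", seq_len(ncol(matrix)))
  sample_ids <- sample_ids %||% rownames(matrix) %||%
    sprintf("s%03d", seq_len(nrow(matrix)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != ncol(matrix) || anyDuplicated(feature_ids))
    stop("feature_ids must be unique and match the number of columns")
  if (length(sample_ids) != nrow(matrix) || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match the number of rows")
  dimnames(matrix) <- list(sample_ids, feature_ids)
  structure(list(matrix = matrix, labels = labels, feature_ids = feature_ids,
                 sample_ids = sample_ids),
            class = "labeled_cohort")
}

#' @exportS3Method base::print
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("<labeled_cohort> %d samples x %d features; %d cases / %d controls\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$labels == 1L),
              sum(x$labels == 0L)))
  invisible(x)
}

subset_cohort <- function(cohort, idx) {
  labeled_cohort(cohort$matrix[idx, , drop = FALSE], cohort$labels[idx],
                 cohort$feature_ids, cohort$sample_ids[idx])
}

#' Generate a synthetic labeled cohort
#'
#' Draws features from a correlated Gaussian (block correlations from the
#' config, marginal sd `noise_sd`) and labels from the logistic model
#' `logit P(y = 1 | x) = b0 + sum_j effects[j] x_j`, with the intercept solved
#' so the marginal prevalence matches the configured value within binomial
#' error. Bit-reproducible under a fixed config seed.
#'
#' @param config a [cohort_config()].
#' @return a [labeled_cohort()].
#' @examples
#' cfg <- cohort_config(200, 10, effects = c(`1` = 2), seed = 7)
#' cohort <- generate_cohort(cfg)
#' table(cohort$labels)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sigma <- build_sigma(config)
  ch <- attr(sigma, "chol")
  beta <- effect_vector(config)
  s <- config$noise_sd * sqrt(drop(crossprod(beta, sigma %*% beta)))
  b0 <- solve_intercept(config$prevalence, s)
  n <- config$n_samples
  p <- config$n_features
  draw <- with_seed(config$seed, {
    z <- matrix(stats::rnorm(n * p), n, p)
    x <- (z %*% ch) * config$noise_sd
    pr <- plogis(b0 + drop(x %*% beta))
    list(x = x, y = stats::rbinom(n, 1L, pr))
  })
  labeled_cohort(draw$x, draw$y,
                 feature_ids = sprintf(paste0("f%0", max(3L, nchar(p)), "d"),
                                       seq_len(p)),
                 sample_ids = sprintf(paste0("s%0", max(3L, nchar(n)), "d"),
                                      seq_len(n)))
}

#' Two-feature configuration guaranteed to show a Yule-Simpson sign reversal
#'
#' Builds a cohort configuration with a focal feature and a correlated
#' confounder whose parameters satisfy the sign condition
#' `beta_focal * (beta_focal + beta_confounder * rho) < 0` — in the Gaussian
#' linear-probability approximation the marginal (single-feature) slope of the
#' focal feature is proportional to `beta_focal + beta_confounder * rho`, so
#' this condition guarantees opposite marginal and conditional signs. Used to
#' exercise the antagonistic-feature machinery on data where the reversal is
#' known to be present.
#'
#' @param beta_focal conditional log-odds effect of the focal feature (index 1).
#' @param beta_confounder conditional effect of the confounder (index 2).
#' @param rho correlation between the two features, |rho| < 1.
#' @param n_samples,prevalence,n_noise,seed forwarded to the config;
#'   `n_noise` extra pure-noise features are appended after the two
#'   informative ones.
#' @return a [cohort_config()] whose generated cohorts show the reversal.
#' @examples
#' cfg <- simpson_config(1, 3, -0.8)
#' @export
simpson_config <- function(beta_focal, beta_confounder, rho,
                           n_samples = 2000L, prevalence = 0.5,
                           n_noise = 0L, seed = 1L) {
  stopifnot(is.numeric(rho), length(rho) == 1L, abs(rho) < 1)
  marginal <- beta_focal + beta_confounder * rho
  if (!(beta_focal * marginal < 0))
    stop(sprintf(paste0("no sign reversal: beta_focal * (beta_focal + beta_confounder * rho) ",
                        "= %g * %g >= 0; the marginal and conditional signs of the focal ",
                        "feature would agree"), beta_focal, marginal))
  cohort_config(n_samples, 2L + as.integer(n_noise), prevalence = prevalence,
                effects = c(`1` = beta_focal, `2` = beta_confounder),
                correlation_blocks = list(list(indices = 1:2, rho = rho)),
                seed = seed)
}

#' Write / read a labeled cohort as TSV
#'
#' The matrix file is a TSV with a header row (`sample_id` then the feature
#' ids) and one row per sample; the label file is a two-column TSV
#' (`sample_id`, `label`). The round trip is lossless to the printed precision
#' (15 significant digits).
#'
#' @param cohort a [labeled_cohort()].
#' @param matrix_path,labels_path file paths.
#' @return `write_cohort` returns the paths invisibly; `read_cohort` returns a
#'   [labeled_cohort()].
#' @export
write_cohort <- function(cohort, matrix_path, labels_path) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  df <- data.frame(sample_id = cohort$sample_ids,
                   signif(cohort$matrix, 15), check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = cohort$sample_ids, label = cohort$labels),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = matrix_path, labels = labels_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(matrix_path, labels_path) {
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  if (nrow(mat_df) == 0L) stop("empty cohort")
  if (!identical(colnames(mat_df)[1L], "sample_id"))
    stop("matrix file must have 'sample_id' as its first column")
  lab_df <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(lab_df)))
    stop("label file must have columns 'sample_id' and 'label'")
  if (anyDuplicated(mat_df$sample_id))
    stop("duplicate sample ids in matrix file")
  if (anyDuplicated(lab_df$sample_id))
    stop("duplicate sample ids in label file")
  missing <- setdiff(mat_df$sample_id, lab_df$sample_id)
  if (length(missing))
    stop("label file missing sample id(s): ", paste(missing, collapse = ", "))
  labels <- lab_df$label[match(mat_df$sample_id, lab_df$sample_id)]
  m <- as.matrix(mat_df[, -1L, drop = FALSE])
  labeled_cohort(m, labels, feature_ids = colnames(m),
                 sample_ids = mat_df$sample_id)
}
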