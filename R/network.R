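#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties — a non-parametric measure of
#' how well the relationship between two features is described by a monotone
#' function. Invariant to strictly monotone transforms of either argument.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\], or `NA` with a warning when either vector
#'   is constant (the correlation is undefined).
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5)) # 0.8 by the rank-difference formula
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Bootstrap inference for a Spearman correlation
#'
#' Resamples the paired observations with replacement `n_boot` times,
#' recomputing the rank correlation each time. The 95% confidence interval is
#' the 2.5/97.5 percentile interval of the bootstrap distribution; the
#' two-sided p-value is `2 * min(frac <= 0, frac >= 0)`, floored at
#' `2 / n_boot` (a resampling p-value of exactly zero is never reported).
#' Degenerate (constant) resamples are skipped and counted.
#'
#' @param x,y paired numeric vectors (lengths >= 10 recommended).
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param seed integer seed; estimates are reproducible given it.
#' @return object of class `correlation_estimate`: `rho_hat`, `ci95`,
#'   `p_value`, `boot` (the resampled correlations), `n_skipped`, `n_boot`,
#'   `seed`.
#' @export
bootstrap_correlation <- function(x, y, n_boot = 5000L, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rho_hat <- spearman_rho(x, y)
  n <- length(x)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      xb <- x[idx]; yb <- y[idx]
      if (stats::sd(xb) < 1e-15 || stats::sd(yb) < 1e-15) return(NA_real_)
      stats::cor(xb, yb, method = "spearman")
    }, numeric(1))
  })
  skipped <- sum(is.na(boot))
  if (skipped)
    message(sprintf("%d degenerate bootstrap resample(s) skipped", skipped))
  bb <- boot[!is.na(boot)]
  if (!length(bb)) stop("all bootstrap resamples were degenerate")
  ci <- stats::quantile(bb, c(0.025, 0.975), names = FALSE)
  p <- 2 * min(mean(bb <= 0), mean(bb >= 0))
  p <- min(1, max(2 / n_boot, p))
  structure(list(rho_hat = rho_hat, ci95 = ci, p_value = p, boot = boot,
                 n_skipped = skipped, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "correlation_estimate")
}

#' @exportS3Method base::print
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("<correlation_estimate> rho = %.3f, 95%% CI (%.3f, %.3f), p = %.4g (%d resamples)\n",
              x$rho_hat, x$ci95[1L], x$ci95[2L], x$p_value, x$n_boot))
  invisible(x)
}

#' Proportion of retained models containing a feature pair
#'
#' @param f,g feature ids.
#' @param model_set a `swag_model_set`.
#' @return proportion of models containing both features, in \[0, 1\].
#' @export
cooccurrence_rate <- function(f, g, model_set) {
  stopifnot(inherits(model_set, "swag_model_set"))
  feats <- model_features(model_set)
  if (!length(feats)) stop("empty model set")
  mean(vapply(feats, function(m) f %in% m && g %in% m, logical(1)))
}

# Deterministically ordered node and edge tables for a model set: node size =
# occurrence %, edge weight = co-occurrence % (pairs never retained together
# get no edge). Correlations, when a cohort is supplied, are Spearman on the
# standardized design.
network_tables <- function(model_set, cohort = NULL) {
  feats <- model_features(model_set)
  nodes <- sort(unique(unlist(feats)))
  n_models <- length(feats)
  occ <- vapply(nodes, function(f) occurrence_rate(f, model_set), numeric(1))
  edges <- list()
  std <- if (!is.null(cohort)) standardize_design(cohort)
  if (length(nodes) >= 2L) {
    for (i in seq_len(length(nodes) - 1L)) {
      for (j in seq.int(i + 1L, length(nodes))) {
        w <- cooccurrence_rate(nodes[i], nodes[j], model_set)
        if (w <= 0) next
        rho <- if (!is.null(std))
          spearman_rho(std$matrix[, nodes[i]], std$matrix[, nodes[j]])
        else NA_real_
        edges[[length(edges) + 1L]] <- data.frame(
          from = nodes[i], to = nodes[j], weight = 100 * w, rho = rho,
          rho_sign = if (is.na(rho)) NA_integer_ else as.integer(sign(rho)),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
    else data.frame(from = character(), to = character(), weight = numeric(),
                    rho = numeric(), rho_sign = integer(),
                    stringsAsFactors = FALSE)
  list(nodes = data.frame(name = nodes, size = 100 * occ,
                          stringsAsFactors = FALSE),
       edges = edges, n_models = n_models)
}

#' Build the co-occurrence network of a model set
#'
#' Nodes are the features occurring in at least one retained model, sized by
#' their occurrence percentage and signed by the sign of their median
#' associative coefficient; undirected edges connect features that appear
#' together in at least one model, weighted by their co-occurrence percentage
#' and annotated with the Spearman correlation (computed on the standardized
#' design when a cohort is supplied). Node/edge ordering is deterministic.
#'
#' @param model_set a `swag_model_set`.
#' @param effect_profiles an [effect_table()] data frame covering every
#'   feature of the model set (or a list of [effect_profile()] objects).
#' @param cohort optional [labeled_cohort()] for edge correlations.
#' @return an undirected `igraph` graph with vertex attributes `sign`, `size`
#'   and edge attributes `weight`, `rho`, `rho_sign`.
#' @export
build_network <- function(model_set, effect_profiles, cohort = NULL) {
  stopifnot(inherits(model_set, "swag_model_set"))
  if (is.list(effect_profiles) && !is.data.frame(effect_profiles)) {
    effect_profiles <- do.call(rbind, lapply(effect_profiles, function(p)
      data.frame(feature = p$feature_id,
                 median_associative = p$median_associative,
                 stringsAsFactors = FALSE)))
  }
  tabs <- network_tables(model_set, cohort)
  missing <- setdiff(tabs$nodes$name, effect_profiles$feature)
  if (length(missing))
    stop("missing effect profile(s) for: ", paste(missing, collapse = ", "))
  med <- effect_profiles$median_associative[
    match(tabs$nodes$name, effect_profiles$feature)]
  g <- igraph::graph_from_data_frame(tabs$edges, directed = FALSE,
                                     vertices = tabs$nodes)
  igraph::V(g)$sign <- as.integer(sign(med))
  g
}

#' Subnetwork of the models containing a focal feature
#'
#' Restricts the model set to the models containing the focal feature and
#' builds the network of its partners: node sizes and edge weights are
#' percentages relative to the restricted set, and node signs are the sign of
#' each partner's *single* (marginal) coefficient. The focal feature itself is
#' not a node (it would trivially connect to everything at 100%).
#'
#' @param focal_feature the focal feature id.
#' @param model_set a `swag_model_set`.
#' @param cohort a [labeled_cohort()] (single effects and edge correlations).
#' @return an undirected `igraph` graph as in [build_network()].
#' @export
focal_subnetwork <- function(focal_feature, model_set, cohort) {
  stopifnot(inherits(model_set, "swag_model_set"))
  feats <- model_features(model_set)
  keep <- vapply(feats, function(m) focal_feature %in% m, logical(1))
  if (!any(keep))
    stop("focal feature ", focal_feature, " occurs in no retained model")
  df <- model_set$models[keep, , drop = FALSE]
  # drop the focal feature from each restricted model
  df$features <- vapply(split_features(df$features), function(m)
    join_features(setdiff(m, focal_feature)), character(1))
  df <- df[nzchar(df$features), , drop = FALSE]
  if (!nrow(df))
    stop("focal feature ", focal_feature,
         " only occurs alone; subnetwork is empty")
  df$dimension <- lengths(split_features(df$features))
  restricted <- new_model_set(df, screening = NULL, config = NULL,
                              thresholds = NULL)
  tabs <- network_tables(restricted, cohort)
  std <- standardize_design(cohort)
  singles <- vapply(tabs$nodes$name, single_beta, numeric(1), cohort = std)
  g <- igraph::graph_from_data_frame(tabs$edges, directed = FALSE,
                                     vertices = tabs$nodes)
  igraph::V(g)$sign <- as.integer(sign(singles))
  g
}

#' Export a network
#'
#' `write_network_graphml` writes GraphML, `write_network_edgelist` a TSV edge
#' list (`from`, `to`, `weight`, `rho`, `rho_sign`), and `write_network_dot` a
#' DOT file for quick rendering.
#'
#' @param graph an `igraph` graph from [build_network()] or
#'   [focal_subnetwork()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edgelist <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_dot <- function(graph, path) {
  igraph::write_graph(graph, path, format = "dot")
  invisible(path)
}
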