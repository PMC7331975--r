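#' Normalized flow vectors of a model set
#'
#' For each model, the per-edge net flows in the canonical transition
#' ordering (lexicographic on from/to class ids), scaled by the vector's
#' Euclidean norm. Norm scaling removes the arbitrary overall rate scale
#' (`k0`), so distances between flow vectors compare mechanisms, not
#' magnitudes.
#'
#' @param x A `model_trajectory`, or a list of `steady_state` objects, or a
#'   numeric matrix of raw flows (models in rows, canonical edge order in
#'   columns).
#' @param space The `state_space` (required for a trajectory input).
#' @param env,cfg Environment and kinetics used to re-solve trajectory
#'   records (default: the trajectory's own sampling environment).
#' @param subset Optional record indices (e.g. from [filter_models()]).
#' @return Numeric matrix with unit-norm rows; rows that were all-zero are
#'   dropped with a warning (attribute `dropped` lists them).
#' @export
flow_vectors <- function(x, space = NULL, env = NULL, cfg = kinetics_config(),
                         subset = NULL) {
  if (inherits(x, "model_trajectory")) {
    space <- x$space
    env <- if (is.null(env)) x$env else env
    cfg <- x$kinetics
    recs <- x$records
    if (!is.null(subset)) recs <- recs[subset]
    V <- t(vapply(recs, function(r) {
      m <- energy_model(space, r$E, r$B, ddG = x$ddG, check = FALSE)
      solve_steady_state(space, m, env, cfg)$flows$flow
    }, numeric(nrow(space$transitions))))
    colnames(V) <- space$transitions$label
  } else if (is.list(x) && all(vapply(x, inherits, logical(1),
                                      "steady_state"))) {
    V <- t(vapply(x, function(s) s$flows$flow,
                  numeric(nrow(x[[1]]$flows))))
    colnames(V) <- x[[1]]$flows$label
  } else {
    V <- as.matrix(x)
  }
  nrm <- sqrt(rowSums(V^2))
  zero <- which(nrm == 0)
  if (length(zero)) {
    warning(length(zero), " all-zero flow vector(s) dropped")
    V <- V[-zero, , drop = FALSE]
    nrm <- nrm[-zero]
  }
  V <- V / nrm
  attr(V, "dropped") <- zero
  V
}

#' Filter a sampled model set for transport performance
#'
#' Keeps records with substrate influx whose cost (ion-to-substrate flux
#' ratio) lies inside `(cost_min, cost_max)` and whose selectivity
#' (substrate-to-decoy flux ratio) exceeds `min_selectivity`. A record with
#' `J_substrate > 0` and `J_decoy <= 0` has selectivity above any finite
#' bound (the decoy flux has vanished or reversed) and passes the
#' selectivity test. The default selectivity bound is ten times the
#' equilibrium discrimination factor, `10 * exp(ddG)`.
#'
#' @param traj A `model_trajectory` (or its [as.data.frame()] form with
#'   `J_*` columns).
#' @param ion,substrate,decoy Species roles. `decoy = NULL` with a finite
#'   `min_selectivity` is a configuration error.
#' @param min_selectivity Lower bound on selectivity; `NULL` or `-Inf`
#'   disables it.
#' @param cost_min,cost_max Cost bounds (main-text filter uses
#'   `cost_min = 0.1`; an upper bound like 10 may be supplied as well).
#' @return Integer vector of record indices passing all predicates.
#' @export
filter_models <- function(traj, ion = "ion", substrate = "substrate",
                          decoy = "decoy",
                          min_selectivity = 10 * exp(if (inherits(traj,
                            "model_trajectory")) traj$ddG else 1),
                          cost_min = 0.1, cost_max = Inf) {
  df <- if (inherits(traj, "model_trajectory")) as.data.frame(traj) else traj
  js <- df[[paste0("J_", substrate)]]
  jn <- df[[paste0("J_", ion)]]
  if (is.null(js) || is.null(jn))
    stop("configuration error: missing flux column for '", substrate,
         "' or '", ion, "'")
  keep <- js > 0 & jn / js > cost_min & jn / js < cost_max
  if (!is.null(min_selectivity) && is.finite(min_selectivity)) {
    jd <- if (!is.null(decoy)) df[[paste0("J_", decoy)]] else NULL
    if (is.null(jd))
      stop("configuration error: selectivity filter requires a decoy flux")
    keep <- keep & (jd <= 0 | js / jd > min_selectivity)
  }
  which(keep)
}

#' Cluster models by their flow vectors
#'
#' Complete-linkage hierarchical clustering on Euclidean distances between
#' unit-norm flow vectors, cut at a distance threshold (default 0.65) to
#' yield mechanistic model classes. The representative of each cluster is
#' its medoid (minimum summed distance to the other members).
#'
#' @param vectors Matrix from [flow_vectors()] (>= 2 rows).
#' @param threshold Flat-cut distance (default 0.65).
#' @return An object of class `flow_clusters`: `dist` (the `dist` object),
#'   `tree` (`hclust`), `labels` (integer cluster per model), `medoids`
#'   (representative row index per cluster), `threshold`.
#' @export
cluster_models <- function(vectors, threshold = 0.65) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) stop("need at least 2 flow vectors")
  d <- stats::dist(vectors)
  tree <- stats::hclust(d, method = "complete")
  labels <- stats::cutree(tree, h = threshold)
  dm <- as.matrix(d)
  medoids <- vapply(sort(unique(labels)), function(k) {
    ix <- which(labels == k)
    ix[which.min(rowSums(dm[ix, ix, drop = FALSE]))]
  }, integer(1))
  structure(list(dist = d, tree = tree, labels = labels, medoids = medoids,
                 threshold = threshold),
            class = "flow_clusters")
}

#' @export
print.flow_clusters <- function(x, ...) {
  k <- length(x$medoids)
  cat("flow_clusters:", length(x$labels), "models,", k,
      "clusters at threshold", x$threshold, "\n")
  tab <- table(x$labels)
  cat("sizes:", paste(sprintf("#%s: %d", names(tab), tab), collapse = ", "),
      "\n")
  cat("medoids (model index):", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}

#' Plot the clustering dendrogram
#'
#' @param x A `flow_clusters`.
#' @param ... Passed to [stats::plot.hclust()].
#' @export
plot.flow_clusters <- function(x, ...) {
  plot(x$tree, xlab = "model", sub = "",
       main = sprintf("complete linkage (cut at %.2f)", x$threshold), ...)
  graphics::abline(h = x$threshold, lty = 2, col = 2)
  invisible(x)
}

#' Export the linkage tree as a Newick string
#'
#' @param clusters A `flow_clusters`.
#' @param path Optional file; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly if written to file).
#' @export
write_newick_tree <- function(clusters, path = NULL) {
  phy <- ape::as.phylo(clusters$tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Cross-run nearest-neighbor distance distributions
#'
#' For every model of run A, the minimum Euclidean distance to any model of
#' run B, and vice versa: small values mean the runs found the same
#' mechanisms, large outliers flag mechanisms unique to one run.
#'
#' @param a,b Flow-vector matrices from [flow_vectors()] over the same state
#'   space (equal column count).
#' @return A list with `a_to_b`, `b_to_a` (numeric vectors of minimum
#'   distances) and `summary` (quantiles of both).
#' @export
compare_runs <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b))
    stop("flow vectors come from different state spaces (dimension mismatch)")
  cross <- function(x, y) {
    ## squared distances via the Gram expansion, clipped for roundoff
    d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
    sqrt(pmax(d2, 0))
  }
  dxy <- cross(a, b)
  res <- list(a_to_b = apply(dxy, 1L, min), b_to_a = apply(dxy, 2L, min))
  res$summary <- rbind(a_to_b = stats::quantile(res$a_to_b),
                       b_to_a = stats::quantile(res$b_to_a))
  res
}
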