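#' Fuzzy c-means clustering of trajectories
#'
#' Soft k-means with fuzzifier `m`: memberships
#' `u_ij = 1 / sum_l (d_ij/d_il)^(2/(m-1))` and centers
#' `sum_i u_ij^m x_i / sum_i u_ij^m`, iterated to convergence
#' (delegated to [e1071::cmeans()] with a seeded initialization from
#' `k` distinct data rows). Euclidean distance on auto-scaled
#' trajectories.
#'
#' @param data features x grid numeric matrix (no missing values).
#' @param k number of clusters (k = 1 returns the data mean with all
#'   memberships 1).
#' @param m fuzzifier (> 1; default 2).
#' @param max_iter iteration cap.
#' @param seed initialization seed.
#' @return list with `centers` (k x grid), `memberships`
#'   (features x k, rows summing to 1) and `k`.
#' @export
fuzzy_cmeans <- function(data, k, m = 2, max_iter = 200, seed = 1) {
  stopifnot(is.matrix(data), !anyNA(data), k >= 1, m > 1)
  if (k == 1) {
    return(list(centers = matrix(colMeans(data), 1,
                                 dimnames = list("1", colnames(data))),
                memberships = matrix(1, nrow(data), 1,
                                     dimnames = list(rownames(data), "1")),
                k = 1L))
  }
  if (k >= nrow(data)) stop("k must be smaller than the number of features")
  set.seed(seed)
  init <- data[!duplicated(data), , drop = FALSE]
  if (nrow(init) < k) stop("fewer than k distinct rows")
  centers0 <- init[sample(nrow(init), k), , drop = FALSE]
  fit <- e1071::cmeans(data, centers = centers0, m = m,
                       iter.max = max_iter, method = "cmeans")
  u <- fit$membership
  rownames(u) <- rownames(data)
  list(centers = fit$centers, memberships = u, k = as.integer(k))
}

#' Select the cluster number from the minimum-centroid-distance curve
#'
#' For each k in `k_grid` a fuzzy c-means model is fitted and
#' `Dmin(k)`, the minimum pairwise distance among the k centers, is
#' recorded as a cluster validity index. With well-separated structure
#' Dmin stays high while k does not exceed the true cluster count and
#' collapses once an extra center splits a cluster; the default
#' `"max_drop"` rule therefore selects the k preceding the largest
#' relative drop of the curve. The `"threshold"` rule instead returns
#' the k preceding the first relative drop exceeding
#' `elbow_threshold`.
#'
#' @param data features x grid matrix.
#' @param k_grid increasing candidate cluster counts (default 2:22).
#' @param m fuzzifier.
#' @param method `"max_drop"` (default) or `"threshold"`.
#' @param elbow_threshold relative-drop threshold for
#'   `method = "threshold"`.
#' @param seed seed (per-k child seeds are derived from it).
#' @return list with `dmin_curve` (named by k), `k_selected`, `fits`
#'   (per-k models).
#' @export
select_k <- function(data, k_grid = 2:22, m = 2,
                     method = c("max_drop", "threshold"),
                     elbow_threshold = 0.1, seed = 1) {
  method <- match.arg(method)
  stopifnot(!is.unsorted(k_grid, strictly = TRUE))
  if (nrow(unique(data)) == 1)
    return(list(dmin_curve = stats::setNames(numeric(0), character(0)),
                k_selected = 1L, fits = list()))
  k_grid <- k_grid[k_grid < nrow(data)]
  fits <- lapply(k_grid, function(k)
    fuzzy_cmeans(data, k, m = m, seed = derive_seed(seed, k)))
  dmin <- vapply(fits, function(f) min(dist(f$centers)), numeric(1))
  names(dmin) <- names(fits) <- k_grid
  if (length(k_grid) == 1)
    return(list(dmin_curve = dmin, k_selected = k_grid, fits = fits))
  drop_rel <- (head(dmin, -1) - tail(dmin, -1)) / head(dmin, -1)
  k_selected <- switch(method,
    max_drop = k_grid[which.max(drop_rel)],
    threshold = {
      hit <- which(drop_rel > elbow_threshold)
      if (length(hit)) k_grid[hit[1]] else k_grid[length(k_grid)]
    })
  list(dmin_curve = dmin, k_selected = as.integer(k_selected), fits = fits)
}

#' Merge correlated clusters and retain confident members
#'
#' Clusters whose center trajectories have Pearson correlation above
#' `cor_threshold` are joined; the merge is transitive (connected
#' components of the correlation graph), so chains of pairwise-similar
#' clusters collapse into one. Each feature follows its highest-
#' membership pre-merge cluster, and only features whose maximum
#' membership exceeds `membership_threshold` are retained.
#'
#' @param fit a [fuzzy_cmeans()] model.
#' @param cor_threshold center-correlation merge threshold (default 0.8).
#' @param membership_threshold retention threshold (default 0.5).
#' @return list of class `cluster_model`: `assignment` (named merged
#'   cluster id per retained feature), `max_membership`, `centers`
#'   (merged; mean of member-cluster centers), `merge_map`
#'   (pre-merge -> merged id), `retained`, `n_clusters`, plus the
#'   pre-merge `fit`.
#' @export
merge_and_retain <- function(fit, cor_threshold = 0.8,
                             membership_threshold = 0.5) {
  centers <- fit$centers
  k <- nrow(centers)
  if (k == 1) {
    merge_map <- stats::setNames(1L, rownames(centers) %||% "1")
  } else {
    cc <- cor(t(centers))
    adj <- cc > cor_threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    merge_map <- igraph::components(g)$membership
  }
  u <- fit$memberships
  pre <- max.col(u, ties.method = "first")
  max_u <- u[cbind(seq_len(nrow(u)), pre)]
  merged_id <- unname(merge_map[pre])
  retained <- max_u > membership_threshold
  merged_centers <- do.call(rbind, lapply(sort(unique(merge_map)), function(g)
    colMeans(centers[merge_map == g, , drop = FALSE])))
  rownames(merged_centers) <- sort(unique(merge_map))
  structure(list(
    assignment = stats::setNames(merged_id, rownames(u))[retained],
    max_membership = stats::setNames(max_u, rownames(u)),
    centers = merged_centers, merge_map = merge_map,
    retained = rownames(u)[retained],
    n_clusters = length(unique(merge_map)), fit = fit),
    class = "cluster_model")
}

#' Cluster smoothed trajectories end to end
#'
#' Auto-scales the smoothed trajectories, selects k on the
#' minimum-centroid-distance curve over `k_grid`, fits fuzzy c-means at
#' the selected k, merges clusters with center correlation above 0.8
#' and retains features with membership above 0.5.
#'
#' @param smoothed a [smooth_trajectories()] result (or a plain
#'   features x grid matrix).
#' @param k_grid,m,seed passed to [select_k()].
#' @param cor_threshold,membership_threshold passed to
#'   [merge_and_retain()].
#' @param method k-selection rule, see [select_k()].
#' @return a `cluster_model` (see [merge_and_retain()]) with extra
#'   elements `dmin_curve`, `k_selected` and `scaled` (the auto-scaled
#'   data).
#' @export
cluster_trajectories <- function(smoothed, k_grid = 2:22, m = 2,
                                 cor_threshold = 0.8,
                                 membership_threshold = 0.5,
                                 method = "max_drop", seed = 1) {
  scaled <- autoscale(smoothed)
  sel <- select_k(scaled, k_grid = k_grid, m = m, method = method, seed = seed)
  fit <- sel$fits[[as.character(sel$k_selected)]] %||%
    fuzzy_cmeans(scaled, sel$k_selected, m = m, seed = derive_seed(seed, 0L))
  model <- merge_and_retain(fit, cor_threshold, membership_threshold)
  model$dmin_curve <- sel$dmin_curve
  model$k_selected <- sel$k_selected
  model$scaled <- scaled
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model>", x$n_clusters, "merged cluster(s) from k =",
      nrow(x$fit$centers), ";", length(x$retained), "retained feature(s)\n")
  print(table(x$assignment))
  invisible(x)
}

#' Plot merged cluster centers
#'
#' @param x a `cluster_model` with an age-grid column naming.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cluster_model <- function(x, ...) {
  ages <- as.numeric(colnames(x$centers))
  graphics::matplot(ages, t(x$centers), type = "l", lty = 1,
                    xlab = "age (years)", ylab = "scaled trajectory", ...)
  graphics::legend("topleft", legend = rownames(x$centers),
                   col = seq_len(nrow(x$centers)), lty = 1, cex = 0.7)
  invisible(x)
}
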