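# Independent oracles used across the suite. Each is a deliberately
# naive implementation (enumeration / quadratic / single-step updates)
# kept separate from the package code paths it checks.

# Exact two-sided Wilcoxon rank-sum p by exhaustive enumeration of all
# C(n, na) rank assignments (tie-free inputs).
enum_wilcoxon_p <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  u_all <- apply(combs, 2, function(idx) sum(seq_len(n)[idx]) -
                   na * (na + 1) / 2)
  lo <- mean(u_all <= u_obs); hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Quadratic-time Benjamini-Hochberg: q_i = min over j with p_j >= p_i
# of m * p_(j) / rank_(j), straight from the step-up definition.
quad_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# All set partitions of n elements (Bell(8) = 4140).
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1)) {
    for (b in seq_along(p)) {
      q <- p; q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

# Exhaustive best-modularity partition of a small igraph.
brute_force_modularity <- function(g) {
  n <- igraph::vcount(g)
  best <- -Inf; bm <- NULL
  for (p in set_partitions(n)) {
    memb <- integer(n)
    for (b in seq_along(p)) memb[p[[b]]] <- b
    m <- igraph::modularity(g, memb)
    if (m > best + 1e-12) { best <- m; bm <- memb }
  }
  list(modularity = best, membership = bm)
}

# Brute-force edge betweenness by shortest-path counting over all
# vertex pairs (unweighted, undirected).
brute_force_edge_betweenness <- function(g) {
  verts <- igraph::V(g)
  eb <- numeric(igraph::ecount(g))
  for (i in seq_along(verts)) for (j in seq_along(verts)) {
    if (i >= j) next
    sp <- igraph::all_shortest_paths(g, from = verts[i], to = verts[j])$res
    if (!length(sp)) next
    for (path in sp) {
      eids <- igraph::get_edge_ids(g, rep(as.integer(path),
                                          each = 2)[-c(1, 2 * length(path))])
      eb[eids] <- eb[eids] + 1 / length(sp)
    }
  }
  eb
}

# Reference fuzzy c-means: plain alternating updates from fixed initial
# centers, run to convergence.
reference_cmeans <- function(x, centers0, m = 2, tol = 1e-8,
                             max_iter = 500) {
  k <- nrow(centers0)
  centers <- centers0
  for (it in seq_len(max_iter)) {
    d2 <- outer(seq_len(nrow(x)), seq_len(k),
                Vectorize(function(i, j) sum((x[i, ] - centers[j, ])^2)))
    d2 <- pmax(d2, 1e-300)
    u <- 1 / (d2^(1 / (m - 1)) * rowSums(1 / d2^(1 / (m - 1))))
    um <- u^m
    new_centers <- (t(um) %*% x) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  list(centers = centers, memberships = u)
}

# Naive hypergeometric upper tail as an explicit sum of point masses.
tail_sum_hyper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
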