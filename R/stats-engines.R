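#' Two-sided Wilcoxon rank-sum p-value
#'
#' Thin wrapper around the standard rank-sum test with an explicit
#' small-sample rule: the exact null distribution is used when the
#' smaller group has at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie and continuity correction
#' is used. If every value is identical across both groups, `p = 1`.
#'
#' @param a,b numeric vectors (each of length >= 2; `NA`s dropped).
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  if (length(unique(c(a, b))) == 1L) return(1)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(length(a), length(b)) <= 8
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

# Vectorized rank-sum test over the rows of a matrix: two-sided normal
# approximation with tie and continuity correction (identical to
# wilcox.test(exact = FALSE, correct = TRUE)). Used by the sliding-window
# scans where both groups exceed the exact-path size anyway.
rank_sum_p_rows <- function(x, idx_a, idx_b) {
  n_a0 <- length(idx_a)
  sub <- x[, c(idx_a, idx_b), drop = FALSE]
  nr <- nrow(sub)
  out <- numeric(nr)
  for (i in seq_len(nr)) {
    v <- sub[i, ]
    ok <- !is.na(v)
    na <- sum(ok[seq_len(n_a0)]); nb <- sum(ok) - na
    if (na < 2 || nb < 2) { out[i] <- NA_real_; next }
    # columns are ordered group-a-first, so after dropping NAs the first
    # `na` entries still belong to group a
    r <- if (all(ok)) rank(v) else rank(v[ok])
    ra_sum <- sum(r[seq_len(na)])
    n <- na + nb
    w <- ra_sum - na * (na + 1) / 2 # Mann-Whitney U for group a
    mu <- na * nb / 2
    tie_term <- 0
    if (anyDuplicated(r)) {
      cnt <- tabulate(match(r, r))
      cnt <- cnt[cnt > 1]
      tie_term <- sum(cnt^3 - cnt)
    }
    sigma2 <- (na * nb / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) { out[i] <- 1; next }
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    out[i] <- min(1, 2 * pnorm(-abs(z)))
  }
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_(j >= i) m * p_(j) / j` capped at 1, returned in the
#' input order (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values.
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Spearman correlation with t-approximation p-value
#'
#' Average-rank transform followed by Pearson correlation; the p-value
#' uses the t approximation (ties handled by average ranks), matching
#' `cor.test(..., method = "spearman", exact = FALSE)`.
#'
#' @param x,y paired numeric vectors (pairwise-complete, n >= 3).
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (var(rank(x)) == 0 || var(rank(y)) == 0)
    stop("zero variance in ranks; correlation undefined")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Permutation p-value for a paired statistic
#'
#' Shuffles `y` only and recomputes `stat_fn(x, y_perm)`; the p-value is
#' `(1 + #permuted |stat| >= |observed|) / (n_perm + 1)`, which is never
#' zero and unbiased under the null.
#'
#' @param stat_fn function of `(x, y)` returning a scalar statistic.
#' @param x,y paired data.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return permutation p-value in `{1/(n_perm+1), ..., 1}`.
#' @export
permutation_p <- function(stat_fn, x, y, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  obs <- abs(stat_fn(x, y))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm),
                 function(i) abs(stat_fn(x, sample(y))), numeric(1))
  (1 + sum(perm >= obs)) / (n_perm + 1)
}

# Vectorized Spearman permutation p-values across the rows of a matrix:
# rank-transforms rows and age, draws n_perm shuffles of the age ranks,
# and computes all permuted correlations by one cross-product. Rows with
# missing values fall back to the scalar path.
spearman_perm_p_rows <- function(x, y, n_perm, seed) {
  set.seed(seed)
  ok_all <- !is.na(y)
  full <- !apply(is.na(x), 1L, any) & all(ok_all)
  p <- rep(NA_real_, nrow(x))
  if (any(full)) {
    xf <- x[full, , drop = FALSE]
    rx <- t(apply(xf, 1L, rank))
    rx <- rx - rowMeans(rx)
    rx <- rx / sqrt(rowSums(rx^2))
    ry <- rank(y); ry <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
    obs <- abs(as.vector(rx %*% ry))
    perms <- vapply(seq_len(n_perm), function(i) sample(ry), ry)
    pm <- abs(rx %*% perms) # features x n_perm
    p[full] <- (1 + rowSums(pm >= obs)) / (n_perm + 1)
  }
  if (any(!full)) {
    for (i in which(!full)) {
      ok <- !is.na(x[i, ]) & !is.na(y)
      p[i] <- permutation_p(function(a, b) cor(rank(a), rank(b)),
                            x[i, ok], y[ok], n_perm,
                            seed = derive_seed(seed, i))
    }
  }
  p
}
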