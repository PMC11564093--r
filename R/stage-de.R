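#' Age-stage scheme
#'
#' Ordered, disjoint age bins covering 25-75 years with a young baseline
#' of 25-40 and exactly six non-baseline bins, so a Bonferroni factor of
#' 6 covers the per-feature comparisons. Bins are half-open `[lo, hi)`
#' with the last bin closed at 75.
#'
#' @param breaks bin edges; defaults to
#'   `c(25, 40, 45, 50, 55, 60, 65, 75)` (baseline plus six stages).
#' @return a `stage_scheme` list with `breaks`, `labels`, `baseline`.
#' @export
stage_scheme <- function(breaks = c(25, 40, 45, 50, 55, 60, 65, 75)) {
  stopifnot(length(breaks) >= 3, !is.unsorted(breaks, strictly = TRUE))
  labels <- paste0("[", head(breaks, -1), ",", tail(breaks, -1),
                   c(rep(")", length(breaks) - 2), "]"))
  structure(list(breaks = breaks, labels = labels, baseline = labels[1]),
            class = "stage_scheme")
}

#' Assign participants to age stages
#'
#' @param ages numeric ages in years, all within the scheme's range.
#' @param scheme a [stage_scheme()].
#' @return character vector of stage labels.
#' @export
assign_stages <- function(ages, scheme = stage_scheme()) {
  stopifnot(inherits(scheme, "stage_scheme"))
  br <- scheme$breaks
  if (any(ages < br[1] | ages > br[length(br)]))
    stop("ages outside the stage scheme range [",
         br[1], ", ", br[length(br)], "]")
  idx <- findInterval(ages, br, rightmost.closed = TRUE)
  scheme$labels[idx]
}

#' Stage-wise dysregulation scan against the young baseline
#'
#' For each feature and each non-baseline stage, a two-sided Wilcoxon
#' rank-sum test compares the stage's participants to the baseline
#' (25-40 years). A permutation p-value re-shuffles group labels and
#' uses the absolute mean difference as the statistic. The per-feature
#' family of six stage comparisons is Bonferroni-corrected by
#' multiplying p by 6 (capped at 1); a feature "changed in at least one
#' stage" has a corrected p below `alpha` in any stage.
#'
#' @param csm adjusted `cross_sectional` matrix.
#' @param scheme a [stage_scheme()].
#' @param alpha significance threshold (default 0.05).
#' @param n_perm label permutations per feature and stage (0 skips).
#' @param min_stage_n stages with fewer participants are skipped.
#' @param seed permutation seed.
#' @return list of class `stage_de`: `results` (long data.frame with
#'   `feature_id`, `stage`, `n_stage`, `wilcoxon_p`, `permutation_p`,
#'   `bonferroni_p`, `direction`), `any_stage_significant` (character
#'   vector of feature ids), `scheme`, `alpha`.
#' @export
stage_scan <- function(csm, scheme = stage_scheme(), alpha = 0.05,
                       n_perm = 1000, min_stage_n = 2, seed = 1) {
  stopifnot(inherits(csm, "cross_sectional"))
  stage <- assign_stages(csm$age, scheme)
  base_idx <- which(stage == scheme$baseline)
  if (!length(base_idx)) stop("baseline stage is empty")
  if (length(base_idx) < 10)
    msg("baseline stage has only ", length(base_idx), " participants")
  other <- setdiff(scheme$labels, scheme$baseline)
  n_comp <- length(other)
  x <- csm$values
  out <- list()
  for (s in other) {
    s_idx <- which(stage == s)
    if (length(s_idx) < min_stage_n) {
      msg("stage ", s, " skipped (", length(s_idx), " participants)")
      next
    }
    wp <- vapply(seq_len(nrow(x)), function(i) {
      a <- x[i, base_idx]; b <- x[i, s_idx]
      if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) return(NA_real_)
      wilcoxon_rank_sum(a, b)
    }, numeric(1))
    dirn <- sign(rowMeans(x[, s_idx, drop = FALSE], na.rm = TRUE) -
                 rowMeans(x[, base_idx, drop = FALSE], na.rm = TRUE))
    pp <- rep(NA_real_, nrow(x))
    if (n_perm > 0)
      pp <- .mean_diff_perm_p(x, base_idx, s_idx, n_perm,
                              derive_seed(seed, match(s, other)))
    out[[s]] <- data.frame(
      feature_id = rownames(x), stage = s, n_stage = length(s_idx),
      wilcoxon_p = wp, permutation_p = pp,
      bonferroni_p = pmin(1, n_comp * wp), direction = dirn,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, c(out, make.row.names = FALSE))
  sig <- unique(results$feature_id[!is.na(results$bonferroni_p) &
                                     results$bonferroni_p < alpha])
  structure(list(results = results, any_stage_significant = sig,
                 scheme = scheme, alpha = alpha),
            class = "stage_de")
}

# Vectorized permutation p for the |mean difference| statistic: group
# membership shuffles expressed as weight vectors, all features at once.
.mean_diff_perm_p <- function(x, idx_a, idx_b, n_perm, seed) {
  cols <- c(idx_a, idx_b)
  xs <- x[, cols, drop = FALSE]
  complete <- !apply(is.na(xs), 1L, any)
  p <- rep(NA_real_, nrow(x))
  na <- length(idx_a); nb <- length(idx_b); n <- na + nb
  w_obs <- c(rep(-1 / na, na), rep(1 / nb, nb))
  set.seed(seed)
  W <- vapply(seq_len(n_perm), function(i) sample(w_obs), w_obs)
  if (any(complete)) {
    xc <- xs[complete, , drop = FALSE]
    obs <- abs(xc %*% w_obs)
    perm <- abs(xc %*% W)
    p[complete] <- (1 + rowSums(perm >= as.vector(obs))) / (n_perm + 1)
  }
  for (i in which(!complete)) {
    ok <- !is.na(xs[i, ])
    if (sum(ok[seq_len(na)]) < 2 || sum(ok[-seq_len(na)]) < 2) next
    grp <- c(rep(0, na), rep(1, nb))[ok]
    p[i] <- permutation_p(function(v, g) mean(v[g == 1]) - mean(v[g == 0]),
                          xs[i, ok], grp, n_perm, seed = derive_seed(seed, i))
  }
  p
}

#' Summarize stage-wise dysregulation
#'
#' Per-stage significant counts plus the partition of any-stage
#' significant features into linear vs non-linear, given a linear-scan
#' result on the same matrix.
#'
#' @param stage_res a [stage_scan()] result.
#' @param linear_res optional [scan_linear()] result.
#' @return list with `per_stage` (data.frame `stage`, `n_significant`),
#'   `n_any_stage`, `frac_any_stage`, and (when `linear_res` is given)
#'   `n_linear_among_changed` and `frac_linear_among_changed`.
#' @export
dysregulation_summary <- function(stage_res, linear_res = NULL) {
  stopifnot(inherits(stage_res, "stage_de"))
  res <- stage_res$results
  alpha <- stage_res$alpha
  per_stage <- do.call(rbind, lapply(split(res, res$stage), function(d)
    data.frame(stage = d$stage[1],
               n_significant = sum(d$bonferroni_p < alpha, na.rm = TRUE),
               n_significant_raw = sum(d$wilcoxon_p < alpha, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  rownames(per_stage) <- NULL
  n_feat <- length(unique(res$feature_id))
  out <- list(per_stage = per_stage,
              n_any_stage = length(stage_res$any_stage_significant),
              frac_any_stage = length(stage_res$any_stage_significant) / n_feat)
  if (!is.null(linear_res)) {
    lin <- linear_res$feature_id[linear_res$significant]
    both <- intersect(stage_res$any_stage_significant, lin)
    out$n_linear_among_changed <- length(both)
    out$frac_linear_among_changed <-
      length(both) / max(1, out$n_any_stage)
  }
  out
}
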