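#' Scan for linearly age-associated features
#'
#' Per feature: Spearman correlation between the adjusted value and
#' participant age (t-approximation p-value), an OLS fit of value on age
#' (slope and its p-value, reported for the rank/linear concordance
#' check), and optionally a permutation p-value obtained by shuffling
#' participants and recomputing the correlation `n_perm` times.
#' Significance is the unadjusted Spearman `p < alpha`, mirroring common
#' practice for these scans.
#'
#' @param csm a confounder-adjusted `cross_sectional` matrix.
#' @param alpha significance threshold on the unadjusted p (default 0.05).
#' @param n_perm permutations for the permutation p (0 skips it;
#'   10000 reproduces the full analysis, 1000 is a fast default).
#' @param min_n minimum pairwise-complete participants per feature;
#'   features below it are skipped.
#' @param seed integer seed for the permutations.
#' @return data.frame (one row per feature): `feature_id`, `omics`, `n`,
#'   `spearman_rho`, `p_value`, `permutation_p`, `ols_slope`, `ols_p`,
#'   `significant`.
#' @export
scan_linear <- function(csm, alpha = 0.05, n_perm = 0, min_n = 20, seed = 1) {
  stopifnot(inherits(csm, "cross_sectional"))
  age <- csm$age
  res <- lapply(rownames(csm$values), function(f) {
    y <- csm$values[f, ]
    ok <- !is.na(y)
    if (sum(ok) < min_n || var(y[ok]) == 0)
      return(data.frame(feature_id = f, omics = unname(csm$omics[f]),
                        n = sum(ok), spearman_rho = NA_real_,
                        p_value = NA_real_, ols_slope = NA_real_,
                        ols_p = NA_real_, stringsAsFactors = FALSE))
    sp <- spearman_cor(age[ok], y[ok])
    fit <- summary(lm(y[ok] ~ age[ok]))$coefficients
    data.frame(feature_id = f, omics = unname(csm$omics[f]), n = sum(ok),
               spearman_rho = sp$rho, p_value = sp$p,
               ols_slope = fit[2, 1], ols_p = fit[2, 4],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  n_skip <- sum(is.na(res$p_value))
  if (n_skip) msg(n_skip, " feature(s) skipped in linear scan")
  res$permutation_p <- NA_real_
  if (n_perm > 0) {
    keep <- !is.na(res$p_value)
    res$permutation_p[keep] <- spearman_perm_p_rows(
      csm$values[res$feature_id[keep], , drop = FALSE], age, n_perm, seed)
  }
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  res
}

#' Age signal of one omics block via PC1
#'
#' Features are z-scored, participants are projected on the first
#' principal component, and the absolute Spearman correlation between
#' PC1 scores and age is returned as the block's age-signal score.
#'
#' @param csm a `cross_sectional` matrix.
#' @param omics_type which omics block to use (`NULL` = all features).
#' @return list with `omics`, `pc1_age_rho` (signed) and
#'   `score = |pc1_age_rho|`.
#' @export
pc1_age_correlation <- function(csm, omics_type = NULL) {
  x <- .omics_block(csm, omics_type)
  if (nrow(x) < 1 || ncol(x) < 5) stop("need >= 1 feature and >= 5 participants")
  xs <- x[apply(x, 1, function(v) !anyNA(v) && sd(v) > 0), , drop = FALSE]
  if (nrow(xs) == 0) stop("no complete, non-constant features in block")
  pc <- prcomp(t(xs), center = TRUE, scale. = TRUE)
  rho <- spearman_cor(pc$x[, 1], csm$age[colnames(xs)])$rho
  list(omics = omics_type %||% "all", pc1_age_rho = rho, score = abs(rho))
}

#' Cross-validated PLS R-squared of age on one omics block
#'
#' A one-response partial-least-squares regression of age on the
#' (z-scored) features, scored by k-fold cross-validation:
#' `R2 = 1 - PRESS / TSS` on held-out folds. The number of components
#' (1 to `max_ncomp`) is chosen by minimum cross-validated PRESS.
#'
#' @param csm a `cross_sectional` matrix.
#' @param omics_type omics block (`NULL` = all features).
#' @param n_folds folds (default 7; reduced with a message if
#'   participants are scarce).
#' @param max_ncomp largest component count tried.
#' @param seed fold-assignment seed.
#' @return list with `omics`, `pls_r2_cv`, `ncomp`.
#' @export
pls_age_r2 <- function(csm, omics_type = NULL, n_folds = 7, max_ncomp = 5,
                       seed = 1) {
  x <- .omics_block(csm, omics_type)
  x <- x[apply(x, 1, function(v) !anyNA(v) && sd(v) > 0), , drop = FALSE]
  if (nrow(x) < 2) stop("need >= 2 usable features for PLS")
  X <- t(x)
  y <- csm$age[rownames(X)]
  n <- length(y)
  if (n < n_folds) {
    msg("reducing folds from ", n_folds, " to ", n)
    n_folds <- n
  }
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  ncomp_max <- min(max_ncomp, ncol(X), n - ceiling(n / n_folds) - 1)
  press <- numeric(ncomp_max)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    # exactly collinear blocks make late components singular (in the
    # fit or in prediction); back off to fewer components
    pred <- NULL
    while (is.null(pred) && ncomp_max >= 1) {
      pred <- tryCatch({
        fit <- mixOmics::pls(X[tr, , drop = FALSE], y[tr],
                             ncomp = ncomp_max, scale = TRUE,
                             mode = "regression")
        predict(fit, newdata = X[!tr, , drop = FALSE])$predict
      }, error = function(e) NULL)
      if (is.null(pred)) ncomp_max <- ncomp_max - 1
    }
    if (is.null(pred)) stop("PLS fit failed for every component count")
    for (k in seq_len(ncomp_max))
      press[k] <- press[k] + sum((y[!tr] - pred[, 1, k])^2)
  }
  press <- press[seq_len(ncomp_max)]
  tss <- sum((y - mean(y))^2)
  k_best <- which.min(press)
  list(omics = omics_type %||% "all",
       pls_r2_cv = 1 - press[k_best] / tss, ncomp = k_best)
}

.omics_block <- function(csm, omics_type) {
  stopifnot(inherits(csm, "cross_sectional"))
  if (is.null(omics_type)) return(csm$values)
  keep <- names(csm$omics)[csm$omics == omics_type]
  if (!length(keep)) stop("no features of omics type '", omics_type, "'")
  csm$values[keep, , drop = FALSE]
}

#' Age signal of every omics block
#'
#' Convenience wrapper running [pc1_age_correlation()] and [pls_age_r2()]
#' per omics type.
#'
#' @inheritParams pls_age_r2
#' @return data.frame with one row per omics type.
#' @export
age_signal_by_omics <- function(csm, n_folds = 7, seed = 1) {
  types <- unique(csm$omics)
  do.call(rbind, lapply(types, function(om) {
    pc <- pc1_age_correlation(csm, om)
    pl <- pls_age_r2(csm, om, n_folds = n_folds, seed = seed)
    data.frame(omics = om, pc1_age_rho = pc$pc1_age_rho,
               pc1_score = pc$score, pls_r2_cv = pl$pls_r2_cv,
               pls_ncomp = pl$ncomp, stringsAsFactors = FALSE)
  }))
}
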