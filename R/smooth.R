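#' LOESS fit with cross-validated span, predicted on an age grid
#'
#' Local quadratic regression (tricube weights) of value on age. The
#' span is chosen from `span_grid` by k-fold cross-validated squared
#' error; the chosen fit is then evaluated on `age_grid`. Spans whose
#' local fits fail (singularities) are discarded; if every span fails,
#' `NULL` is returned so callers can exclude the feature.
#'
#' @param ages,values paired observations (`NA`s dropped).
#' @param age_grid prediction grid (clipped to the observed age range).
#' @param span_grid candidate spans in (0, 1].
#' @param n_folds cross-validation folds.
#' @param seed fold-assignment seed.
#' @return list `predictions`, `chosen_span`, `cv_error` or `NULL`.
#' @export
loess_fit_predict <- function(ages, values,
                              age_grid = seq(min(ages), max(ages), by = 0.5),
                              span_grid = seq(0.3, 1, by = 0.1),
                              n_folds = 5, seed = 1) {
  ok <- !is.na(ages) & !is.na(values)
  ages <- ages[ok]; values <- values[ok]
  if (length(ages) < 10) stop("need >= 10 observations for LOESS smoothing")
  stopifnot(all(span_grid > 0), all(span_grid <= 1))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), length(ages)))
  df <- data.frame(a = ages, v = values)
  cv <- vapply(span_grid, function(sp) {
    sse <- 0; nn <- 0
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- tryCatch(suppressWarnings(
        loess(v ~ a, data = df[tr, ], span = sp, degree = 2,
              control = loess.control(surface = "direct"))),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pred <- tryCatch(suppressWarnings(
        predict(fit, data.frame(a = ages[!tr]))),
        error = function(e) rep(NA_real_, sum(!tr)))
      good <- !is.na(pred)
      sse <- sse + sum((values[!tr][good] - pred[good])^2)
      nn <- nn + sum(good)
    }
    if (nn == 0) NA_real_ else sse / nn
  }, numeric(1))
  if (all(is.na(cv))) return(NULL)
  best <- which.min(cv)
  fit <- tryCatch(suppressWarnings(
    loess(v ~ a, data = df, span = span_grid[best], degree = 2,
          control = loess.control(surface = "direct"))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  grid <- age_grid[age_grid >= min(ages) & age_grid <= max(ages)]
  pred <- suppressWarnings(predict(fit, data.frame(a = grid)))
  list(predictions = stats::setNames(pred, grid),
       chosen_span = span_grid[best], cv_error = cv[best], age_grid = grid)
}

#' Smooth every feature of a cross-sectional matrix onto a half-year grid
#'
#' Applies [loess_fit_predict()] feature-by-feature (value against
#' participant age) and assembles a features x grid matrix. The grid
#' runs in exact half-year steps across the observed age range.
#'
#' @param csm a `cross_sectional` matrix (typically adjusted).
#' @param span_grid,n_folds,seed passed to [loess_fit_predict()].
#' @return object of class `smoothed_trajectories`: `predictions`
#'   (features x grid), `age_grid`, `chosen_span`, `cv_error`, `omics`.
#' @export
smooth_trajectories <- function(csm, span_grid = seq(0.3, 1, by = 0.1),
                                n_folds = 5, seed = 1) {
  stopifnot(inherits(csm, "cross_sectional"))
  lo <- ceiling(min(csm$age) * 2) / 2
  hi <- floor(max(csm$age) * 2) / 2
  grid <- seq(lo, hi, by = 0.5)
  feats <- rownames(csm$values)
  preds <- matrix(NA_real_, length(feats), length(grid),
                  dimnames = list(feats, grid))
  span <- stats::setNames(rep(NA_real_, length(feats)), feats)
  cverr <- span
  excluded <- character()
  for (f in feats) {
    y <- csm$values[f, ]
    ok <- !is.na(y)
    if (sum(ok) < 10) { excluded <- c(excluded, f); next }
    sm <- loess_fit_predict(csm$age[ok], y[ok], age_grid = grid,
                            span_grid = span_grid, n_folds = n_folds,
                            seed = derive_seed(seed, match(f, feats)))
    if (is.null(sm)) { excluded <- c(excluded, f); next }
    preds[f, as.character(sm$age_grid)] <- sm$predictions
    span[f] <- sm$chosen_span
    cverr[f] <- sm$cv_error
  }
  if (length(excluded)) {
    msg(length(excluded), " feature(s) excluded from smoothing")
    keep <- setdiff(feats, excluded)
    preds <- preds[keep, , drop = FALSE]
    span <- span[keep]; cverr <- cverr[keep]
  }
  structure(list(predictions = preds, age_grid = grid, chosen_span = span,
                 cv_error = cverr, omics = csm$omics[rownames(preds)]),
            class = "smoothed_trajectories")
}

#' Auto-scale trajectories to mean 0, SD 1
#'
#' Per-feature z-scoring across the age grid so trajectories are
#' compared by shape rather than magnitude. Zero-variance features are
#' excluded with a message.
#'
#' @param predictions features x grid matrix (or a
#'   `smoothed_trajectories` object).
#' @return z-scored matrix of the retained features.
#' @export
autoscale <- function(predictions) {
  if (inherits(predictions, "smoothed_trajectories"))
    predictions <- predictions$predictions
  sds <- apply(predictions, 1, sd, na.rm = TRUE)
  drop <- is.na(sds) | sds == 0
  if (any(drop)) msg(sum(drop), " zero-variance feature(s) excluded from scaling")
  x <- predictions[!drop, , drop = FALSE]
  z <- t(scale(t(x)))
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}
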