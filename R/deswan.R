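#' Build sliding-window comparison specs
#'
#' Windows of total width `width` years slide in one-year steps; each
#' window is split at its center age `c` into a younger parcel
#' `(c - width/2, c]` and an older parcel `(c, c + width/2]`. The
#' initial window is anchored at the young end of the cohort: its
#' younger parcel covers everything from the minimum age up to the
#' first center (ages 25-40 for the default 20-year window, so the
#' older parcel spans 41-50 at integer ages). Centers run from
#' `first_center` up to the last center whose older parcel fits the
#' observed ages; windows with fewer than `min_n` participants in
#' either parcel are dropped with a message.
#'
#' @param ages participant ages (years).
#' @param width total window width in years (parcels are `width/2`).
#' @param first_center center age of the initial window (default 40).
#' @param step center step (years).
#' @param min_n minimum participants per parcel.
#' @return data.frame with `center`, `left_lo`, `left_hi`, `right_lo`,
#'   `right_hi`, `n_left`, `n_right` (one row per retained window).
#' @export
build_windows <- function(ages, width = 20, first_center = 40, step = 1,
                          min_n = 10) {
  stopifnot(width > 0, step > 0)
  half <- width / 2
  lo <- min(ages); hi <- max(ages)
  if (ceiling(hi) - half < first_center)
    stop("cohort too young for any full window")
  centers <- seq(first_center, ceiling(hi) - half, by = step)
  specs <- lapply(centers, function(cc) {
    left_lo <- if (cc == first_center) lo else cc - half
    left <- if (cc == first_center) ages >= left_lo & ages <= cc
            else ages > left_lo & ages <= cc
    right <- ages > cc & ages <= cc + half
    data.frame(center = cc, left_lo = left_lo, left_hi = cc,
               right_lo = cc, right_hi = min(cc + half, hi),
               n_left = sum(left), n_right = sum(right))
  })
  specs <- do.call(rbind, specs)
  keep <- specs$n_left >= min_n & specs$n_right >= min_n
  if (!any(keep)) stop("no window has >= ", min_n,
                       " participants in both parcels")
  if (any(!keep))
    msg(sum(!keep), " window(s) dropped for insufficient parcel size")
  specs[keep, , drop = FALSE]
}

#' Sliding-window differential-expression scan (modified DE-SWAN)
#'
#' At every window center, each feature is compared between the younger
#' and older parcels with a two-sided Wilcoxon rank-sum test (normal
#' approximation with tie and continuity correction); p-values are
#' Benjamini-Hochberg adjusted across features within the center, and
#' the number of features with `q < cutoff` is recorded per cutoff.
#'
#' @param csm adjusted `cross_sectional` matrix.
#' @param width total window width (years).
#' @param q_cutoffs significance cutoffs on the adjusted p.
#' @param min_n minimum participants per parcel.
#' @param first_center center of the initial window.
#' @param ages optional replacement ages (used by the permutation
#'   null); defaults to `csm$age`.
#' @return object of class `deswan_result`: `centers`, `counts`
#'   (centers x cutoffs), `p` and `q` (features x centers), `windows`,
#'   `width`, `q_cutoffs`.
#' @export
deswan_scan <- function(csm, width = 20,
                        q_cutoffs = c(1e-4, 1e-3, 1e-2, 0.05),
                        min_n = 10, first_center = 40, ages = NULL) {
  stopifnot(inherits(csm, "cross_sectional"))
  ages <- ages %||% csm$age
  windows <- build_windows(ages, width = width, first_center = first_center,
                           min_n = min_n)
  x <- csm$values
  p <- matrix(NA_real_, nrow(x), nrow(windows),
              dimnames = list(rownames(x), windows$center))
  q <- p
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    left <- if (w$center == windows$center[1])
      which(ages >= w$left_lo & ages <= w$left_hi)
    else which(ages > w$left_lo & ages <= w$left_hi)
    right <- which(ages > w$right_lo & ages <= w$right_hi)
    p[, i] <- rank_sum_p_rows(x, left, right)
    q[, i] <- bh_adjust(p[, i])
  }
  counts <- vapply(q_cutoffs, function(ct)
    colSums(q < ct, na.rm = TRUE), numeric(nrow(windows)))
  counts <- matrix(counts, nrow = nrow(windows),
                   dimnames = list(windows$center, as.character(q_cutoffs)))
  structure(list(centers = windows$center, counts = counts, p = p, q = q,
                 windows = windows, width = width, q_cutoffs = q_cutoffs),
            class = "deswan_result")
}

#' Age-permutation null envelope for DE-SWAN counts
#'
#' Participant ages are randomly permuted against the fixed feature
#' matrix and the scan is rerun; per center and q cutoff the 50th, 95th
#' and 99th percentiles of the permuted counts form the null envelope
#' used for crest calling.
#'
#' @inheritParams deswan_scan
#' @param n_perm number of age permutations (>= 20).
#' @param seed permutation seed.
#' @param probs envelope quantiles.
#' @return object of class `deswan_envelope`: `quantiles` (array
#'   centers x probs x cutoffs), `perm_counts` (array
#'   n_perm x centers x cutoffs), `centers`, `width`.
#' @export
age_permutation_null <- function(csm, width = 20,
                                 q_cutoffs = c(1e-4, 1e-3, 1e-2, 0.05),
                                 n_perm = 100, min_n = 10, first_center = 40,
                                 seed = 1, probs = c(0.5, 0.95, 0.99)) {
  stopifnot(n_perm >= 20)
  base <- build_windows(csm$age, width = width, first_center = first_center,
                        min_n = min_n)
  centers <- base$center
  counts <- array(NA_real_,
                  dim = c(n_perm, length(centers), length(q_cutoffs)),
                  dimnames = list(NULL, centers, as.character(q_cutoffs)))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm_ages <- stats::setNames(sample(csm$age), names(csm$age))
    sc <- suppressMessages(
      deswan_scan(csm, width = width, q_cutoffs = q_cutoffs, min_n = min_n,
                  first_center = first_center, ages = perm_ages))
    common <- intersect(as.character(centers), as.character(sc$centers))
    counts[b, common, ] <- sc$counts[common, , drop = FALSE]
  }
  qs <- apply(counts, c(2, 3), quantile, probs = probs, na.rm = TRUE)
  qs <- aperm(qs, c(2, 1, 3)) # centers x probs x cutoffs
  # family-wise null: quantiles of each permutation's maximum count over
  # centers; guards crest calls against multiplicity across ~26 centers,
  # where the per-center 95th percentile alone rejects far too often
  fam <- apply(apply(counts, c(1, 3), max, na.rm = TRUE), 2,
               quantile, probs = probs, na.rm = TRUE)
  fam <- matrix(fam, nrow = length(probs),
                dimnames = list(NULL, as.character(q_cutoffs)))
  structure(list(quantiles = qs, family = fam, perm_counts = counts,
                 centers = centers, width = width, q_cutoffs = q_cutoffs,
                 probs = probs),
            class = "deswan_envelope")
}

#' Detect crests in a DE-SWAN count curve
#'
#' A crest is a center age whose count is maximal within `radius` years
#' on both sides and, when a null envelope is supplied, exceeds the null
#' threshold at that center: the larger of the per-center count quantile
#' and the family-wise quantile of the per-permutation maximum count
#' over centers. The family-wise component controls the rate of false
#' crests across the whole curve — with ~26 centers, a per-center
#' percentile alone calls single-feature blips crests whenever the null
#' counts are mostly zero. Plateaus of tied qualifying counts are
#' reported at the plateau midpoint (rounded down). Crests at the first
#' or last center carry an `edge` flag since one side of the
#' neighbourhood is unobserved.
#'
#' @param scan a `deswan_result`, or a numeric count vector named by
#'   center age.
#' @param q_cutoff which count column to use when `scan` is a
#'   `deswan_result` (default 0.05).
#' @param envelope optional `deswan_envelope` (or numeric vector of
#'   per-center thresholds).
#' @param radius neighbourhood half-width in years (default 3).
#' @param percentile envelope percentile used as the null threshold
#'   (one of the envelope's `probs`; default 0.95).
#' @return data.frame with `age`, `count`, `edge` (possibly 0 rows).
#' @export
detect_crests <- function(scan, q_cutoff = 0.05, envelope = NULL,
                          radius = 3, percentile = 0.95) {
  if (inherits(scan, "deswan_result")) {
    counts <- scan$counts[, as.character(q_cutoff)]
    centers <- scan$centers
  } else {
    counts <- scan
    centers <- as.numeric(names(scan))
  }
  thr <- rep(-Inf, length(centers))
  if (!is.null(envelope)) {
    if (inherits(envelope, "deswan_envelope")) {
      pidx <- match(percentile, envelope$probs)
      if (is.na(pidx)) stop("percentile not in envelope probs")
      ev <- envelope$quantiles[, pidx, as.character(q_cutoff)]
      idx <- match(as.character(centers), as.character(envelope$centers))
      thr <- ifelse(is.na(idx), -Inf, ev[idx])
      if (!is.null(envelope$family))
        thr <- pmax(thr, envelope$family[pidx, as.character(q_cutoff)])
    } else thr <- rep_len(envelope, length(centers))
  }
  is_max <- vapply(seq_along(centers), function(i) {
    nb <- abs(centers - centers[i]) <= radius
    counts[i] >= max(counts[nb])
  }, logical(1))
  qual <- is_max & counts > thr
  if (!any(qual))
    return(data.frame(age = numeric(0), count = numeric(0),
                      edge = logical(0)))
  # collapse plateaus: runs of adjacent qualifying centers with equal count
  out <- list()
  i <- 1
  while (i <= length(centers)) {
    if (qual[i]) {
      j <- i
      while (j < length(centers) && qual[j + 1] &&
             counts[j + 1] == counts[i] &&
             centers[j + 1] - centers[j] <= radius) j <- j + 1
      mid <- centers[i + floor((j - i) / 2)]
      out[[length(out) + 1]] <- data.frame(
        age = mid, count = counts[i],
        edge = i == 1 || j == length(centers))
      i <- j + 1
    } else i <- i + 1
  }
  do.call(rbind, out)
}

#' Robustness grid over window widths and q cutoffs
#'
#' Reruns the scan for every window width, calls crests at every
#' (width, cutoff) combination, and tabulates the detected crest ages
#' so their stability across the grid can be assessed.
#'
#' @inheritParams deswan_scan
#' @param widths total window widths to try.
#' @param envelopes optional named list of `deswan_envelope`s keyed by
#'   width (as character); `n_perm > 0` computes them on the fly.
#' @param n_perm permutations per width for on-the-fly envelopes
#'   (0 = crest calling without a null threshold).
#' @param seed envelope seed.
#' @param radius,percentile passed to [detect_crests()].
#' @return list of class `deswan_grid`: `scans` (per width),
#'   `crests` (data.frame `width`, `q_cutoff`, `age`, `count`, `edge`),
#'   `envelopes`.
#' @export
robustness_grid <- function(csm, widths = c(15, 20, 25, 30),
                            q_cutoffs = c(1e-4, 1e-3, 1e-2, 0.05),
                            min_n = 10, first_center = 40,
                            envelopes = NULL, n_perm = 0, seed = 1,
                            radius = 3, percentile = 0.95) {
  scans <- lapply(widths, function(w)
    deswan_scan(csm, width = w, q_cutoffs = q_cutoffs, min_n = min_n,
                first_center = first_center))
  names(scans) <- widths
  if (is.null(envelopes) && n_perm > 0) {
    envelopes <- lapply(widths, function(w)
      age_permutation_null(csm, width = w, q_cutoffs = q_cutoffs,
                           n_perm = n_perm, min_n = min_n,
                           first_center = first_center,
                           seed = derive_seed(seed, w)))
    names(envelopes) <- widths
  }
  rows <- list()
  for (w in as.character(widths)) {
    for (ct in q_cutoffs) {
      cr <- detect_crests(scans[[w]], q_cutoff = ct,
                          envelope = envelopes[[w]],
                          radius = radius, percentile = percentile)
      if (nrow(cr))
        rows[[length(rows) + 1]] <- cbind(
          data.frame(width = as.numeric(w), q_cutoff = ct), cr)
    }
  }
  crests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(width = numeric(0), q_cutoff = numeric(0), age = numeric(0),
               count = numeric(0), edge = logical(0))
  structure(list(scans = scans, crests = crests, envelopes = envelopes,
                 widths = widths, q_cutoffs = q_cutoffs),
            class = "deswan_grid")
}

#' Per-omics DE-SWAN count curves
#'
#' Runs the scan separately within each omics stratum (BH adjustment is
#' per stratum and center). Strata with fewer than `min_features`
#' features are skipped with a message.
#'
#' @inheritParams deswan_scan
#' @param min_features minimum features per stratum.
#' @return named list of `deswan_result`, one per omics type.
#' @export
per_omics_waves <- function(csm, width = 20,
                            q_cutoffs = c(1e-4, 1e-3, 1e-2, 0.05),
                            min_n = 10, first_center = 40,
                            min_features = 10) {
  types <- unique(csm$omics)
  out <- list()
  for (om in types) {
    feats <- names(csm$omics)[csm$omics == om]
    if (length(feats) < min_features) {
      msg("omics stratum ", om, " skipped (", length(feats), " features)")
      next
    }
    sub <- csm
    sub$values <- csm$values[feats, , drop = FALSE]
    sub$omics <- csm$omics[feats]
    out[[om]] <- suppressMessages(
      deswan_scan(sub, width = width, q_cutoffs = q_cutoffs, min_n = min_n,
                  first_center = first_center))
  }
  out
}

#' @export
print.deswan_result <- function(x, ...) {
  cat("<deswan_result> width", x$width, "y;", length(x$centers),
      "centers (", min(x$centers), "-", max(x$centers), ")\n")
  cat("  counts at q<0.05:",
      paste(x$counts[, ncol(x$counts)], collapse = " "), "\n")
  invisible(x)
}

#' Plot a DE-SWAN count curve
#'
#' @param x a `deswan_result`.
#' @param q_cutoff which cutoff column to draw.
#' @param envelope optional `deswan_envelope` drawn as a dashed line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.deswan_result <- function(x, q_cutoff = 0.05, envelope = NULL, ...) {
  cnt <- x$counts[, as.character(q_cutoff)]
  graphics::plot(x$centers, cnt, type = "b", pch = 16,
                 xlab = "window center age (years)",
                 ylab = paste0("features with q < ", q_cutoff), ...)
  if (!is.null(envelope)) {
    ev <- envelope$quantiles[, match(0.95, envelope$probs),
                             as.character(q_cutoff)]
    graphics::lines(envelope$centers, ev, lty = 2)
  }
  invisible(x)
}
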