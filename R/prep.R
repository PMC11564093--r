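#' Collapse microbiome taxa to genus level
#'
#' Genus abundance in each sample is the sum of member-taxon relative
#' abundances; features of non-microbiome omics types are untouched.
#' Taxa missing from the taxonomy map are assigned to `"unclassified"`
#' (within their omics type) with a message.
#'
#' @param cohort an `aging_cohort`.
#' @param taxonomy data.frame `feature_id`, `genus`; defaults to the
#'   cohort's own taxonomy table.
#' @return the cohort with microbiome features replaced by genus-level
#'   features.
#' @export
collapse_microbiome_to_genus <- function(cohort, taxonomy = cohort$taxonomy) {
  stopifnot(inherits(cohort, "aging_cohort"))
  samples <- data.table::as.data.table(cohort$samples)
  is_mb <- grepl("microbiome", samples$omics)
  if (!any(is_mb) || is.null(taxonomy)) return(cohort)
  mb <- samples[is_mb]
  map <- stats::setNames(taxonomy$genus, taxonomy$feature_id)
  genus <- map[mb$feature_id]
  if (anyNA(genus)) {
    msg(sum(is.na(genus)), " microbiome measurements lack a taxonomy entry; ",
        "assigned to 'unclassified'")
    genus[is.na(genus)] <- paste0(mb$omics[is.na(genus)], "_unclassified")
  }
  mb$feature_id <- unname(genus)
  mb <- mb[, list(value = sum(value)),
           by = c("participant_id", "visit_age", "healthy", "omics",
                  "feature_id")]
  cohort$samples <- data.table::rbindlist(list(samples[!is_mb], mb),
                                          use.names = TRUE)
  cohort$collapsed <- TRUE
  cohort
}

#' Aggregate a longitudinal cohort into a cross-sectional matrix
#'
#' Each participant is represented by the mean of their healthy visits
#' per feature; the participant's age is the mean age across all their
#' sample collection time points. Participants without any healthy visit
#' are dropped with a message.
#'
#' @param cohort an `aging_cohort` (or a list with `samples` and
#'   `metadata` in the same layout).
#' @param log_microbiome transform microbiome relative abundances with
#'   `log10(x + 1e-5)` so downstream linear residual models act on a
#'   roughly additive scale.
#' @return an object of class `cross_sectional`: `values`
#'   (features x participants matrix), `age` (named numeric),
#'   `omics` (named by feature), `metadata`, `adjusted` flag.
#' @export
aggregate_participants <- function(cohort, log_microbiome = TRUE) {
  samples <- data.table::as.data.table(cohort$samples)
  if (nrow(samples) == 0) stop("empty cohort")
  value <- healthy <- visit_age <- participant_id <- NULL # data.table NSE
  keep <- samples[, list(any_healthy = any(healthy)), by = "participant_id"]
  dropped <- keep$participant_id[!keep$any_healthy]
  if (length(dropped))
    msg("dropping ", length(dropped),
        " participant(s) without a healthy visit")
  ages <- samples[!(participant_id %in% dropped),
                  list(age = mean(unique(visit_age))), by = "participant_id"]
  agg <- samples[healthy == TRUE & !(participant_id %in% dropped),
                 list(value = mean(value)),
                 by = c("participant_id", "omics", "feature_id")]
  feat <- unique(agg[, c("feature_id", "omics")])
  parts <- sort(unique(agg$participant_id))
  m <- matrix(NA_real_, nrow = nrow(feat), ncol = length(parts),
              dimnames = list(feat$feature_id, parts))
  m[cbind(match(agg$feature_id, feat$feature_id),
          match(agg$participant_id, parts))] <- agg$value
  omics <- stats::setNames(feat$omics, feat$feature_id)
  if (log_microbiome) {
    mb <- grepl("microbiome", omics)
    if (any(mb)) m[mb, ] <- log10(m[mb, , drop = FALSE] + 1e-5)
  }
  age <- stats::setNames(ages$age, ages$participant_id)[parts]
  meta <- cohort$metadata
  if (!is.null(meta)) meta <- meta[meta$participant_id %in% parts, ]
  structure(list(values = m, age = age, omics = omics, metadata = meta,
                 adjusted = FALSE), class = "cross_sectional")
}

# Confounder design matrix (no intercept column; lm adds it).
.confounder_design <- function(metadata, confounders) {
  known <- list(
    sex = function(m) factor(m$sex),
    bmi = function(m) as.numeric(m$bmi),
    iris = function(m) factor(m$iris_class),
    ethnicity = function(m) factor(m$ethnicity))
  miss <- setdiff(confounders, names(known))
  if (length(miss)) stop("unknown confounder(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(lapply(known[confounders], function(f) f(metadata)))
  rownames(df) <- metadata$participant_id
  df
}

#' Adjust a cross-sectional matrix for confounders
#'
#' Per feature, an ordinary-least-squares model of the value on
#' `[intercept, BMI, sex, IRIS class, ethnicity]` is fitted over the
#' participants with a non-missing value, and the residuals replace the
#' values. Aliased (rank-deficient) design columns are dropped by the
#' `lm` fit. Missing IRIS status is kept as its own category level.
#'
#' @param csm a `cross_sectional` object.
#' @param metadata participant metadata (defaults to `csm$metadata`).
#' @param confounders subset of `c("bmi", "sex", "iris", "ethnicity")`.
#' @param min_n features with fewer non-missing values than `min_n` are
#'   left unadjusted (all-`NA`) and reported.
#' @return the matrix with `values` replaced by residuals and
#'   `adjusted = TRUE`.
#' @export
adjust_confounders <- function(csm, metadata = csm$metadata,
                               confounders = c("bmi", "sex", "iris",
                                               "ethnicity"),
                               min_n = 20) {
  stopifnot(inherits(csm, "cross_sectional"))
  if (is.null(metadata)) stop("participant metadata required for adjustment")
  design <- .confounder_design(metadata, confounders)
  design <- design[colnames(csm$values), , drop = FALSE]
  if (anyNA(design)) stop("confounders missing for some participants")
  vals <- csm$values
  skipped <- 0L
  for (i in seq_len(nrow(vals))) {
    y <- vals[i, ]
    ok <- !is.na(y)
    if (sum(ok) < max(min_n, ncol(design) + 2)) {
      vals[i, ] <- NA_real_
      skipped <- skipped + 1L
      next
    }
    fit <- lm(y ~ ., data = cbind(y = y[ok], design[ok, , drop = FALSE]))
    vals[i, ok] <- residuals(fit)
  }
  if (skipped) msg(skipped, " feature(s) skipped in adjustment (n < ",
                   max(min_n, ncol(design) + 2), ")")
  csm$values <- vals
  csm$adjusted <- TRUE
  csm$confounders <- confounders
  csm
}

#' One-call preparation: collapse, aggregate, adjust
#'
#' @inheritParams aggregate_participants
#' @inheritParams adjust_confounders
#' @return an adjusted `cross_sectional` matrix.
#' @export
prep_cross_sectional <- function(cohort,
                                 confounders = c("bmi", "sex", "iris",
                                                 "ethnicity"),
                                 log_microbiome = TRUE) {
  cohort <- collapse_microbiome_to_genus(cohort)
  csm <- aggregate_participants(cohort, log_microbiome = log_microbiome)
  adjust_confounders(csm, confounders = confounders)
}

#' @export
print.cross_sectional <- function(x, ...) {
  cat("<cross_sectional>", nrow(x$values), "features x", ncol(x$values),
      "participants;", if (x$adjusted) "confounder-adjusted" else "unadjusted",
      "\n  age range:", sprintf("%.1f-%.1f", min(x$age), max(x$age)), "\n")
  invisible(x)
}
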