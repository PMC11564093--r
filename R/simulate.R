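#' Configure a synthetic longitudinal multi-omics cohort
#'
#' The generator emulates an observational aging cohort: participants
#' aged 25-75 at enrollment, sampled every 3-6 months over a follow-up
#' whose median is about 1.7 years, with roughly ten omics assays per
#' visit. Each feature's expectation at age `a` is
#' `baseline + archetype(a) + sum of confounder effects`; repeated visits
#' of one participant share a participant-level random intercept, and
#' independent Gaussian noise is added per visit. Omics types whose name
#' contains `"microbiome"` are emitted as logistic-normal relative
#' abundances (per-sample softmax over that type's taxa) together with a
#' taxon-to-genus map.
#'
#' @param n_participants number of participants (default 108).
#' @param n_features named integer vector: features per omics type.
#' @param archetypes data.frame as produced by [archetype_assignment()]
#'   (one row per feature, recycled across omics types in order);
#'   `NULL` means all stable.
#' @param confounder_effects named numeric vector of effect sizes in SD
#'   units for `sex`, `bmi`, `iris`, `ethnicity`. Each confounder's
#'   effect enters additively through a standardized covariate
#'   (indicator or z-score), with a per-feature random sign.
#' @param noise_sd per-visit measurement noise SD.
#' @param within_participant_sd SD of the participant-level random
#'   intercept shared by a participant's repeat visits.
#' @param baseline_sd SD of per-feature baselines.
#' @param age_range enrollment age range in years.
#' @param visit_gap range (years) of the uniform between-visit gap
#'   (default 3-6 months).
#' @param follow_up_meanlog,follow_up_sdlog log-normal follow-up duration
#'   parameters (median `exp(meanlog)` = 1.7 years by default).
#' @param follow_up_max truncation of follow-up duration (years).
#' @param healthy_prob probability a visit is flagged healthy (each
#'   participant is guaranteed at least one healthy visit).
#' @param iris_unknown_prob fraction of participants with undetermined
#'   insulin-resistance status (38/108 by default).
#' @param taxa_per_genus genus size used for microbiome taxonomy.
#' @param seed integer seed; a fixed seed yields an identical cohort.
#' @return a `generator_config` list.
#' @export
cohort_config <- function(n_participants = 108,
                          n_features = c(transcriptomics = 800,
                                         proteomics = 300,
                                         metabolomics = 500,
                                         cytokines = 100,
                                         clinical = 300),
                          archetypes = NULL,
                          confounder_effects = c(sex = 0.3, bmi = 0.2,
                                                 iris = 0.2, ethnicity = 0.2),
                          noise_sd = 1, within_participant_sd = 0.3,
                          baseline_sd = 2,
                          age_range = c(25, 75),
                          visit_gap = c(0.25, 0.5),
                          follow_up_meanlog = log(1.7), follow_up_sdlog = 0.6,
                          follow_up_max = 6.8,
                          healthy_prob = 0.9,
                          iris_unknown_prob = 38 / 108,
                          taxa_per_genus = 3L,
                          seed = 1L) {
  if (n_participants <= 0) stop("n_participants must be positive")
  if (any(n_features <= 0)) stop("all omics feature counts must be positive")
  if (is.null(names(n_features)) || any(!nzchar(names(n_features))))
    stop("n_features must be a named vector (one entry per omics type)")
  if (noise_sd < 0 || within_participant_sd < 0 || baseline_sd < 0)
    stop("standard deviations must be non-negative")
  total <- sum(n_features)
  if (!is.null(archetypes)) {
    stopifnot(is.data.frame(archetypes))
    if (nrow(archetypes) != total)
      stop("archetypes must have one row per feature (", total, " total)")
  }
  structure(list(
    n_participants = as.integer(n_participants), n_features = n_features,
    archetypes = archetypes, confounder_effects = confounder_effects,
    noise_sd = noise_sd, within_participant_sd = within_participant_sd,
    baseline_sd = baseline_sd, age_range = age_range, visit_gap = visit_gap,
    follow_up_meanlog = follow_up_meanlog, follow_up_sdlog = follow_up_sdlog,
    follow_up_max = follow_up_max, healthy_prob = healthy_prob,
    iris_unknown_prob = iris_unknown_prob,
    taxa_per_genus = as.integer(taxa_per_genus),
    seed = as.integer(seed)), class = "generator_config")
}

# Participant-level metadata and visit schedules.
.simulate_participants <- function(cfg) {
  n <- cfg$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  enroll <- runif(n, cfg$age_range[1], cfg$age_range[2])
  follow <- pmin(rlnorm(n, cfg$follow_up_meanlog, cfg$follow_up_sdlog),
                 cfg$follow_up_max)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.519, 0.481))
  ethnicity <- sample(c("caucasian", "asian", "hispanic", "other"), n,
                      replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1))
  bmi <- pmin(pmax(rnorm(n, 28.2, 4), 19.1), 40.8)
  iris <- ifelse(runif(n) < cfg$iris_unknown_prob, "unknown",
                 sample(c("IS", "IR"), n, replace = TRUE))
  meta <- data.frame(participant_id = ids, sex = sex, ethnicity = ethnicity,
                     bmi = bmi, iris_class = iris, enrollment_age = enroll,
                     stringsAsFactors = FALSE)
  visits <- lapply(seq_len(n), function(i) {
    ages <- enroll[i]
    repeat {
      nxt <- ages[length(ages)] + runif(1, cfg$visit_gap[1], cfg$visit_gap[2])
      # follow-up ends at its sampled duration or the cohort age ceiling
      if (nxt > enroll[i] + follow[i] || nxt > cfg$age_range[2]) break
      ages <- c(ages, nxt)
    }
    healthy <- runif(length(ages)) < cfg$healthy_prob
    if (!any(healthy)) healthy[1] <- TRUE
    data.frame(participant_id = ids[i], visit_age = ages, healthy = healthy,
               stringsAsFactors = FALSE)
  })
  list(metadata = meta, visits = do.call(rbind, visits))
}

# Standardized confounder covariates used by the generator (one column
# per confounder named in confounder_effects).
.confounder_covariates <- function(meta) {
  cbind(sex = as.numeric(meta$sex == "F"),
        bmi = as.numeric(scale(meta$bmi)),
        iris = as.numeric(meta$iris_class == "IR"),
        ethnicity = as.numeric(meta$ethnicity == "asian"))
}

#' Simulate a longitudinal multi-omics cohort
#'
#' @param config a [cohort_config()].
#' @return an object of class `aging_cohort`: a list with `samples`
#'   (long-format data.table: `participant_id`, `visit_age`, `healthy`,
#'   `omics`, `feature_id`, `value`), `metadata`, `truth` (per-feature
#'   archetype table, see [ground_truth_table()]), `taxonomy`
#'   (taxon-to-genus map for microbiome types, or `NULL`) and `config`.
#' @examples
#' cfg <- cohort_config(n_participants = 20,
#'                      n_features = c(proteomics = 10), seed = 7)
#' coh <- simulate_cohort(cfg)
#' head(coh$samples)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  pp <- .simulate_participants(config)
  meta <- pp$metadata
  visits <- pp$visits
  covs <- .confounder_covariates(meta)
  rownames(covs) <- meta$participant_id
  vis_cov <- covs[visits$participant_id, , drop = FALSE]

  truth <- ground_truth_table(config)
  lib <- template_library()
  n_visits <- nrow(visits)
  conf_names <- intersect(names(config$confounder_effects), colnames(covs))

  blocks <- list()
  taxonomy <- NULL
  for (om in names(config$n_features)) {
    rows <- which(truth$omics == om)
    nf <- length(rows)
    baseline <- rnorm(nf, 0, config$baseline_sd)
    # random sign per feature x confounder so adjustment has both
    # directions to remove
    signs <- matrix(sample(c(-1, 1), nf * length(conf_names), replace = TRUE),
                    nrow = nf, dimnames = list(NULL, conf_names))
    # mean matrix: features x visits
    mu <- matrix(baseline, nrow = nf, ncol = n_visits)
    arch_key <- do.call(paste, c(truth[rows, c("kind", "amplitude", "slope",
                                               "t0", "steepness", "t1",
                                               "steepness2", "template_id")],
                                 sep = "\r"))
    for (key in unique(arch_key)) {
      idx <- which(arch_key == key)
      arch <- .arch_from_row(truth[rows[idx[1]], ], lib)
      av <- archetype_value(arch, visits$visit_age)
      mu[idx, ] <- mu[idx, , drop = FALSE] + rep(av, each = length(idx))
    }
    for (cn in conf_names) {
      eff <- config$confounder_effects[[cn]]
      if (eff != 0)
        mu <- mu + (eff * signs[, cn]) %o% vis_cov[, cn]
    }
    # participant random intercept shared across a participant's visits
    b <- matrix(rnorm(nf * nrow(meta), 0, config$within_participant_sd),
                nrow = nf, dimnames = list(NULL, meta$participant_id))
    mu <- mu + b[, visits$participant_id, drop = FALSE]
    vals <- mu + matrix(rnorm(nf * n_visits, 0, config$noise_sd), nrow = nf)

    fids <- truth$feature_id[rows]
    if (grepl("microbiome", om)) {
      # logistic-normal relative abundances per sample
      ex <- exp(vals)
      vals <- sweep(ex, 2, colSums(ex), "/")
      genus <- sprintf("%s_g%03d", om,
                       ceiling(seq_len(nf) / config$taxa_per_genus))
      taxonomy <- rbind(taxonomy,
                        data.frame(feature_id = fids, genus = genus,
                                   stringsAsFactors = FALSE))
    }
    dimnames(vals) <- list(fids, NULL)
    blocks[[om]] <- data.table::data.table(
      participant_id = rep(visits$participant_id, each = nf),
      visit_age = rep(visits$visit_age, each = nf),
      healthy = rep(visits$healthy, each = nf),
      omics = om,
      feature_id = rep(fids, times = n_visits),
      value = as.vector(vals))
  }
  samples <- data.table::rbindlist(blocks)
  structure(list(samples = samples, metadata = meta, truth = truth,
                 taxonomy = taxonomy, config = config),
            class = "aging_cohort")
}

#' Per-feature ground-truth archetype table
#'
#' @param config a [cohort_config()].
#' @return data.frame with one row per feature: `feature_id`, `omics`,
#'   and the archetype columns of [archetype_assignment()].
#' @export
ground_truth_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  total <- sum(config$n_features)
  arch <- config$archetypes %||%
    data.frame(kind = rep("stable", total), amplitude = 0, slope = 0,
               t0 = 50, steepness = 1, t1 = NA_real_, steepness2 = 1,
               template_id = NA_character_, stringsAsFactors = FALSE)
  omics <- rep(names(config$n_features), times = config$n_features)
  ids <- unlist(lapply(names(config$n_features), function(om)
    sprintf("%s_f%04d", om, seq_len(config$n_features[[om]]))),
    use.names = FALSE)
  cbind(data.frame(feature_id = ids, omics = omics, stringsAsFactors = FALSE),
        arch)
}

#' @export
print.aging_cohort <- function(x, ...) {
  cat("<aging_cohort>", nrow(x$metadata), "participants,",
      length(unique(x$samples$feature_id)), "features,",
      nrow(x$samples), "measurements\n")
  cat("  omics:", paste(names(x$config$n_features), collapse = ", "), "\n")
  invisible(x)
}
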