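#' Run the full analysis pipeline
#'
#' Orchestrates the stages in order: preparation (genus collapse,
#' healthy-visit aggregation, confounder adjustment), linear scan,
#' stage-wise dysregulation, LOESS smoothing plus trajectory
#' clustering, and the sliding-window wave scan with permutation
#' envelope and crest calls. Each stage's tables are written under
#' `out_dir` together with the resolved configuration, and every
#' stage's randomness derives deterministically from the single seed.
#'
#' @param cohort an `aging_cohort` (simulated or read from disk).
#' @param out_dir output directory (`NULL` = return results only).
#' @param stages character subset of
#'   `c("scan_linear", "stage_de", "cluster", "deswan")`; preparation
#'   always runs.
#' @param alpha significance threshold shared by the scans.
#' @param n_perm permutations for the linear/stage permutation p-values.
#' @param deswan_width window width for the wave scan.
#' @param q_cutoffs DE-SWAN q cutoffs.
#' @param envelope_perm age permutations for the null envelope.
#' @param k_grid candidate cluster numbers.
#' @param seed master seed.
#' @return list with the per-stage results (`csm`, `linear`, `stage`,
#'   `smoothed`, `clusters`, `deswan`, `envelope`, `crests`).
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         stages = c("scan_linear", "stage_de", "cluster",
                                    "deswan"),
                         alpha = 0.05, n_perm = 0, deswan_width = 20,
                         q_cutoffs = c(1e-4, 1e-3, 1e-2, 0.05),
                         envelope_perm = 20, k_grid = 2:22, seed = 1) {
  stopifnot(inherits(cohort, "aging_cohort"))
  res <- list()
  res$csm <- prep_cross_sectional(cohort)
  if ("scan_linear" %in% stages)
    res$linear <- scan_linear(res$csm, alpha = alpha, n_perm = n_perm,
                              seed = derive_seed(seed, 1))
  if ("stage_de" %in% stages) {
    res$stage <- stage_scan(res$csm, alpha = alpha, n_perm = n_perm,
                            seed = derive_seed(seed, 2))
    res$summary <- dysregulation_summary(res$stage, res$linear)
  }
  if ("cluster" %in% stages) {
    res$smoothed <- smooth_trajectories(res$csm, seed = derive_seed(seed, 3))
    res$clusters <- cluster_trajectories(res$smoothed, k_grid = k_grid,
                                         seed = derive_seed(seed, 4))
  }
  if ("deswan" %in% stages) {
    res$deswan <- deswan_scan(res$csm, width = deswan_width,
                              q_cutoffs = q_cutoffs)
    res$envelope <- age_permutation_null(res$csm, width = deswan_width,
                                         q_cutoffs = q_cutoffs,
                                         n_perm = envelope_perm,
                                         seed = derive_seed(seed, 5))
    res$crests <- detect_crests(res$deswan, envelope = res$envelope)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cross_sectional(res$csm, file.path(out_dir, "cross_sectional"))
    if (!is.null(res$linear))
      data.table::fwrite(res$linear, file.path(out_dir, "linear_scan.tsv"),
                         sep = "\t")
    if (!is.null(res$stage))
      data.table::fwrite(res$stage$results,
                         file.path(out_dir, "stage_de.tsv"), sep = "\t")
    if (!is.null(res$smoothed))
      data.table::fwrite(
        data.table::as.data.table(res$smoothed$predictions,
                                  keep.rownames = "feature_id"),
        file.path(out_dir, "trajectories.tsv"), sep = "\t")
    if (!is.null(res$clusters))
      data.table::fwrite(
        data.frame(feature_id = names(res$clusters$assignment),
                   cluster = unname(res$clusters$assignment),
                   max_membership =
                     unname(res$clusters$max_membership[
                       names(res$clusters$assignment)])),
        file.path(out_dir, "clusters.tsv"), sep = "\t")
    if (!is.null(res$deswan)) {
      data.table::fwrite(
        data.table::as.data.table(res$deswan$counts,
                                  keep.rownames = "center"),
        file.path(out_dir, "deswan_counts.tsv"), sep = "\t")
      jsonlite::write_json(res$crests, file.path(out_dir, "crests.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(
      list(stages = stages, alpha = alpha, n_perm = n_perm,
           deswan_width = deswan_width, q_cutoffs = q_cutoffs,
           envelope_perm = envelope_perm,
           k_grid = range(k_grid), seed = seed),
      file.path(out_dir, "run_config.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
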