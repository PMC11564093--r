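#' Trajectory archetypes
#'
#' An archetype encodes the deterministic age component of a simulated
#' feature's mean trajectory, in units of the feature's residual standard
#' deviation. Supported kinds:
#'
#' * `stable`: no age effect (always 0).
#' * `linear`: `slope * (age - 25)` SD per year from the cohort entry age.
#' * `logistic`: a sigmoidal mean shift
#'   `amplitude / (1 + exp(-steepness * (age - t0)))`, i.e. a transition
#'   of total height `amplitude` centred at age `t0` with rate
#'   `steepness` per year.
#' * `double_logistic`: the sum of two logistic transitions, producing a
#'   two-step "staircase" (or a peak/dip when the amplitudes have
#'   opposite sign).
#' * `cluster_template`: an arbitrary shape given as a function of age,
#'   scaled by `amplitude`; used to plant cluster-recovery fixtures.
#'
#' @param kind one of `"stable"`, `"linear"`, `"logistic"`,
#'   `"double_logistic"`, `"cluster_template"`.
#' @param amplitude total effect size in SD units (logistic kinds and
#'   templates).
#' @param slope per-year change in SD units (linear kind).
#' @param t0,steepness centre age (years) and rate (1/years) of the
#'   (first) logistic transition; `steepness` must be positive.
#' @param t1,steepness2,amplitude2 centre, rate and amplitude of the
#'   second transition (`double_logistic` only; `amplitude2` defaults to
#'   `amplitude`).
#' @param template a function of age returning the template shape
#'   (`cluster_template` only).
#' @param template_id optional identifier carried into the ground-truth
#'   table.
#' @return an object of class `trajectory_archetype`.
#' @examples
#' arch <- trajectory_archetype("logistic", amplitude = 2, t0 = 50, steepness = 1)
#' archetype_value(arch, 50)  # amplitude / 2
#' @export
trajectory_archetype <- function(kind = c("stable", "linear", "logistic",
                                          "double_logistic", "cluster_template"),
                                 amplitude = 0, slope = 0,
                                 t0 = 50, steepness = 1,
                                 t1 = NA_real_, steepness2 = 1,
                                 amplitude2 = NULL,
                                 template = NULL, template_id = NA_character_) {
  kind <- match.arg(kind)
  if (!is.finite(amplitude)) stop("archetype amplitude must be finite")
  if (kind %in% c("logistic", "double_logistic")) {
    if (!is.finite(steepness) || steepness <= 0)
      stop("logistic steepness must be > 0")
    if (t0 < 25 || t0 > 75) stop("transition age t0 must lie in [25, 75]")
  }
  if (kind == "double_logistic") {
    if (!is.finite(t1)) stop("double_logistic requires a second transition age t1")
    if (!is.finite(steepness2) || steepness2 <= 0)
      stop("second steepness must be > 0")
  }
  if (kind == "cluster_template" && !is.function(template))
    stop("cluster_template requires a template function of age")
  structure(
    list(kind = kind, amplitude = amplitude, slope = slope,
         t0 = t0, steepness = steepness, t1 = t1, steepness2 = steepness2,
         amplitude2 = amplitude2 %||% amplitude,
         template = template, template_id = template_id),
    class = "trajectory_archetype")
}

#' Evaluate an archetype's mean trajectory at given ages
#'
#' @param arch a [trajectory_archetype()].
#' @param age numeric vector of ages in years.
#' @return numeric vector of mean shifts in SD units.
#' @export
archetype_value <- function(arch, age) {
  stopifnot(inherits(arch, "trajectory_archetype"))
  switch(arch$kind,
    stable = rep(0, length(age)),
    linear = arch$slope * (age - 25),
    logistic = arch$amplitude / (1 + exp(-arch$steepness * (age - arch$t0))),
    double_logistic =
      arch$amplitude  / (1 + exp(-arch$steepness  * (age - arch$t0))) +
      arch$amplitude2 / (1 + exp(-arch$steepness2 * (age - arch$t1))),
    cluster_template = arch$amplitude * arch$template(age),
    stop("unknown archetype kind: ", arch$kind)
  )
}

#' @export
print.trajectory_archetype <- function(x, ...) {
  cat("<trajectory_archetype>", x$kind)
  if (x$kind == "linear") cat(sprintf(" slope=%.3g/yr", x$slope))
  if (x$kind %in% c("logistic", "double_logistic"))
    cat(sprintf(" amplitude=%.3g t0=%.1f k=%.3g", x$amplitude, x$t0, x$steepness))
  if (x$kind == "double_logistic")
    cat(sprintf(" + amplitude=%.3g t1=%.1f k=%.3g", x$amplitude2, x$t1, x$steepness2))
  cat("\n")
  invisible(x)
}

# Eleven reference trajectory shapes used for cluster-recovery fixtures:
# monotone ramps, early/late transitions, a mid-life peak/dip between the
# two canonical crest ages, an early transient and a U shape. All are
# defined on ages 25-75; z-scaling downstream removes offset/scale. The
# shapes are chosen so every pairwise Pearson correlation of the scaled
# templates stays below the 0.8 cluster-merge threshold, keeping planted
# clusters distinct by construction.
template_library <- function() {
  lg <- function(t0, k = 1) function(a) 1 / (1 + exp(-k * (a - t0)))
  list(
    ramp_up      = function(a) (a - 25) / 50,
    ramp_down    = function(a) -(a - 25) / 50,
    step34_up    = lg(34),
    step34_down  = function(a) -lg(34)(a),
    step66_up    = lg(66),
    step66_down  = function(a) -lg(66)(a),
    midlife_peak = function(a) lg(44)(a) - lg(60)(a),
    midlife_dip  = function(a) -lg(44)(a) + lg(60)(a),
    early_peak   = function(a) lg(33)(a) - lg(46)(a),
    early_dip    = function(a) -lg(33)(a) + lg(46)(a),
    u_shape      = function(a) ((a - 50) / 25)^2
  )
}

#' Archetype assignment tables
#'
#' Helpers that build the `archetypes` data.frame consumed by
#' [cohort_config()]: one row per feature with the archetype kind and its
#' parameters.
#'
#' `archetype_assignment()` assigns kinds by fraction (rounded to whole
#' features, remainder going to `stable`). `dual_crest_assignment()`
#' plants two blocks of logistic transitions at the canonical crest ages
#' (44 and 60 by default) on an otherwise stable background.
#' `template_assignment()` spreads features evenly over the 11 reference
#' templates.
#'
#' @param n_features total number of features.
#' @param fractions named fractions for kinds `linear`, `logistic`, `stable`.
#' @param slope linear slope (SD/year) for planted linear features.
#' @param amplitude,steepness logistic parameters for planted transitions.
#' @param t0 transition age(s).
#' @return data.frame with columns `kind`, `amplitude`, `slope`, `t0`,
#'   `steepness`, `t1`, `steepness2`, `template_id`.
#' @export
archetype_assignment <- function(n_features,
                                 fractions = c(linear = 0.066, logistic = 0.25,
                                               stable = 0.684),
                                 slope = 0.05, amplitude = 1.5,
                                 t0 = 50, steepness = 1) {
  stopifnot(n_features > 0, all(fractions >= 0))
  n_lin <- round(n_features * (fractions["linear"] %||% 0))
  n_log <- round(n_features * (fractions["logistic"] %||% 0))
  n_sta <- n_features - n_lin - n_log
  if (n_sta < 0) stop("archetype fractions exceed 1")
  t0s <- rep_len(t0, n_log)
  data.frame(
    kind = c(rep("linear", n_lin), rep("logistic", n_log), rep("stable", n_sta)),
    amplitude = c(rep(0, n_lin), rep(amplitude, n_log), rep(0, n_sta)),
    slope = c(rep(slope, n_lin), rep(0, n_log + n_sta)),
    t0 = c(rep(50, n_lin), t0s, rep(50, n_sta)),
    steepness = steepness, t1 = NA_real_, steepness2 = 1,
    template_id = NA_character_,
    stringsAsFactors = FALSE)
}

#' @rdname archetype_assignment
#' @param n_shift number of features planted at each transition age.
#' @param crest_ages the two transition ages.
#' @export
dual_crest_assignment <- function(n_features = 2000, n_shift = 300,
                                  crest_ages = c(44, 60),
                                  amplitude = 1.5, steepness = 1) {
  stopifnot(length(crest_ages) == 2, 2 * n_shift <= n_features)
  n_sta <- n_features - 2 * n_shift
  data.frame(
    kind = c(rep("logistic", 2 * n_shift), rep("stable", n_sta)),
    amplitude = c(rep(amplitude, 2 * n_shift), rep(0, n_sta)),
    slope = 0,
    t0 = c(rep(crest_ages[1], n_shift), rep(crest_ages[2], n_shift),
           rep(50, n_sta)),
    steepness = steepness, t1 = NA_real_, steepness2 = 1,
    template_id = NA_character_,
    stringsAsFactors = FALSE)
}

#' @rdname archetype_assignment
#' @param n_per_template features per template.
#' @export
template_assignment <- function(n_per_template = 100, amplitude = 2) {
  lib <- template_library()
  ids <- names(lib)
  data.frame(
    kind = "cluster_template",
    amplitude = amplitude, slope = 0, t0 = 50, steepness = 1,
    t1 = NA_real_, steepness2 = 1,
    template_id = rep(ids, each = n_per_template),
    stringsAsFactors = FALSE)
}

# Build trajectory_archetype objects from an assignment row.
.arch_from_row <- function(row, lib = template_library()) {
  if (row$kind == "cluster_template") {
    trajectory_archetype("cluster_template", amplitude = row$amplitude,
                         template = lib[[row$template_id]],
                         template_id = row$template_id)
  } else {
    trajectory_archetype(row$kind, amplitude = row$amplitude,
                         slope = row$slope, t0 = row$t0,
                         steepness = row$steepness,
                         t1 = row$t1, steepness2 = row$steepness2)
  }
}
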