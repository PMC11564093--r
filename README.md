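# agewave

Nonlinear trajectory and wave analysis for longitudinal multi-omics
aging cohorts.

Most molecular markers of human aging do not drift linearly: their
levels shift in waves, with dysregulation concentrating around specific
chronological ages. `agewave` implements the analysis stack for
detecting such structure in a longitudinal cohort profiled across many
omics platforms (transcriptome, proteome, metabolome, cytokines,
clinical labs, microbiomes):

1. **Cross-sectional preparation** — microbiome taxa are collapsed to
   genus, each participant is summarized by the mean of their healthy
   visits, and every feature is replaced by the residuals of an
   ordinary-least-squares fit on BMI, sex, insulin-resistance (IRIS)
   class and ethnicity, so downstream statistics act on
   confounder-adjusted values.
2. **Linear scan** — per feature, Spearman correlation of the adjusted
   value with age (t-approximation, optional permutation p), plus an
   OLS slope for the rank/linear concordance check; PCA-PC1 age
   correlation and cross-validated PLS *R²* quantify how much age
   signal each omics block carries.
3. **Stage-wise dysregulation** — two-sided Wilcoxon rank-sum tests of
   each age stage against the 25–40-year baseline, with the six
   stage comparisons Bonferroni-corrected (×6).
4. **Trajectory clustering** — LOESS smoothing (cross-validated span)
   onto a half-year age grid, per-feature z-scaling, fuzzy c-means with
   the minimum-centroid-distance validity index over k = 2…22, merging
   of clusters whose centers correlate above 0.8, and retention of
   features with membership above 0.5.
5. **Modified DE-SWAN** — the sliding-window wave statistic: at every
   center age *c* (one-year steps) the younger parcel (*c*−10, *c*] is
   compared to the older parcel (*c*, *c*+10] per feature
   (20-year window; the first window pools everything from age 25),
   p-values are BH-adjusted within the center, and the count of
   features with *q* below a cutoff traces the wave. Crests are local
   maxima of the count curve that exceed an age-permutation null
   envelope; a robustness grid repeats the scan over window widths
   {15, 20, 25, 30} and cutoffs {10⁻⁴, 10⁻³, 10⁻², 0.05}.
6. **Functional modules** — hypergeometric over-representation against
   GMT gene sets, then redundancy collapse: similarity networks (Wang
   similarity on the GO ontology graph, cutoff 0.7; Jaccard on member
   sets, cutoff 0.5), Girvan–Newman edge-betweenness communities, one
   representative per module (smallest adjusted p), and a final
   cross-database merge on member-feature unions.

A synthetic-cohort generator (`simulate_cohort()`) plants trajectory
archetypes — stable, linear, logistic transitions, double transitions,
template shapes — together with confounder effects, participant-level
random intercepts and noise, so every stage of the pipeline can be
verified against ground truth without access to any real cohort.

## Worked example

```r
library(agewave)

# a cohort with two planted waves: 300 features shifting at age 44,
# 300 at age 60 (1.5 SD logistic transitions), 1,400 stable features
cfg <- cohort_config(
  archetypes = dual_crest_assignment(n_features = 2000, n_shift = 300,
                                     crest_ages = c(44, 60),
                                     amplitude = 1.5),
  seed = 1)
cohort <- simulate_cohort(cfg)
csm <- prep_cross_sectional(cohort)

scan <- deswan_scan(csm, width = 20)
env  <- age_permutation_null(csm, width = 20, n_perm = 20, seed = 101)
detect_crests(scan, q_cutoff = 0.05, envelope = env)
```

```
   age count  edge
43  43   313 FALSE
61  61   311 FALSE
```

The count curve peaks at window centers 43 and 61 — within the
sampling error of the planted transition ages 44 and 60 — and both
peaks clear the 95th percentile of the 20-permutation age-shuffle
envelope, so they are called as crests. `plot(scan, envelope = env)`
draws the wave with its null band; `robustness_grid()` repeats the
call across window widths and q cutoffs.

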