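---
title: "Methods: detecting nonlinear aging dynamics in longitudinal multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting nonlinear aging dynamics in longitudinal multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(agewave)
```

This vignette documents the statistical model behind `agewave`, the
assumptions each stage makes, the tunable parameters and their
defaults, and the design decisions taken where the methodology was
genuinely open.

## The data model

The raw input is a long-format longitudinal table: one row per
participant, visit, and molecular feature, with the visit age in
years, a healthy flag, and the omics type. The cohort emulated by the
synthetic generator (and assumed by the defaults) has roughly 108
participants aged 25–75, visited every 3–6 months over a follow-up
with median about 1.7 years, and measured on several omics platforms.

All statistics operate on the **cross-sectional matrix**: features ×
participants, where

* microbiome taxa are first summed into genera per sample (only the
  genus level is analyzed);
* each cell is the mean of the participant's *healthy* visits;
* the participant's age is the mean age over all their collection
  time points;
* microbiome relative abundances are transformed `log10(x + 1e-5)` so
  the residual model below acts on a roughly additive scale (the
  pseudocount is far below any abundance the generator produces);
* each feature is replaced by the residuals of an OLS fit on
  `[intercept, BMI, sex, IRIS class, ethnicity]`.

Averaging visits trades longitudinal resolution for robustness: with a
median follow-up under two years, within-person aging trends are not
identifiable per participant, while the visit mean gives a low-noise
estimate of the participant's level at their mean age. Missing IRIS
status is kept as its own factor level rather than dropped, preserving
sample size. Features with fewer than 20 complete participants are
excluded from adjustment and scans — below that, rank tests and OLS
residuals are too unstable to interpret.

Confounder adjustment by residualization assumes effects are additive
on the (log-like) feature scale and age-independent. Residuals of a
model that includes an intercept are exactly orthogonal to the design,
so adjusting twice equals adjusting once; this idempotence is tested.

## Linear scan and omics-level age signal

Per feature, the scan reports the Spearman correlation of the adjusted
value with participant age. The p-value uses the t approximation with
average-rank ties — the behaviour of `cor.test(exact = FALSE)` — and is
deliberately left unadjusted: the scan is a descriptive census of
monotone trends, not a discovery procedure, and the fraction of
features passing `p < 0.05` is interpreted against the 5% null
expectation (the all-stable calibration test makes this explicit). An
optional permutation p shuffles participants and recomputes the
correlation; the reported value is `(r + 1) / (N + 1)`, which cannot be
zero and is uniform on its grid under the null. OLS slope and p are
reported alongside because rank and linear detections should, and in
simulation do, agree closely on truly linear features.

Block-level age signal is summarized two ways: the absolute Spearman
correlation between ages and the first principal component of the
z-scored block, and the cross-validated R² of a one-response PLS
regression of age on the block (sevenfold; 1–5 components chosen by
minimum cross-validated PRESS; features z-scored since scales differ
across platforms). R² is computed as `1 - PRESS/TSS` on held-out folds,
so a block with no signal scores near or below zero.

## Stage-wise dysregulation

Participants are binned by age: baseline `[25, 40)` and six stages
`[40,45), [45,50), [50,55), [55,60), [60,65), [65,75]`. Bins are
half-open with the last closed. The six non-baseline bins are a design
choice: the multiple-testing correction multiplies each p by exactly 6
(capped at 1), so the bin count and the correction factor must agree.
Five-year bins up to 65 and a terminal decade balance resolution
against per-bin sample size in a 25–75 cohort whose oldest decade is
sparse.

Each feature × stage comparison against baseline uses the two-sided
Wilcoxon rank-sum test: exact null distribution when the smaller group
has ≤ 8 observations and no ties occur, otherwise the normal
approximation with tie and continuity correction. The permutation
variant shuffles group labels and uses the absolute mean difference as
its statistic — a deliberate pairing of a rank-based primary test with
a mean-based permutation check; the two agree in rejection on the
overwhelming majority of planted-effect features, which the suite
asserts.

## Trajectory smoothing and clustering

Each feature is smoothed by LOESS (local quadratic, tricube weights)
of adjusted value against participant age, with the span chosen from
`{0.3, 0.4, …, 1.0}` by 5-fold cross-validated squared error, and
evaluated on a half-year age grid spanning the observed range. The
`surface = "direct"` evaluation is used so held-out fold predictions
remain defined near the range edges. Local quadratic fits reproduce
linear and constant signals exactly, which the suite uses as an
oracle.

Smoothed trajectories are z-scored per feature (shape, not magnitude,
is clustered) and clustered by fuzzy c-means (fuzzifier m = 2, the
conventional default; Euclidean distance). The cluster number is
chosen on the minimum-centroid-distance curve Dmin(k) for k = 2…22:
with separated structure, Dmin stays high while k does not exceed the
true cluster count and collapses once an extra center splits a real
cluster. The default rule therefore selects the k *preceding the
largest relative drop* of the curve. A literal "first k whose next
drop falls below 10%" threshold rule is also available, but on planted
clouds it fires before the collapse (the curve is flat on both sides
of the true k) and selects too few clusters, so it is not the default.

After fitting, clusters whose center trajectories have Pearson
correlation above 0.8 are merged. Merging is transitive — connected
components of the thresholded correlation graph — because pairwise
merging of chains is order-dependent, while components are not. Only
features with maximum membership above 0.5 are retained. The
11-template fixture used in the recovery tests was built so that all
pairwise template correlations stay at or below about 0.73: planted
clusters are then distinct *by construction* under the 0.8 merge rule,
and recovery failures indicate real pipeline defects rather than
template overlap.

## The modified DE-SWAN wave statistic

For every window center age c (one-year steps from 40), features are
compared between a younger parcel `(c − w/2, c]` and an older parcel
`(c, c + w/2]` (total window width w = 20 years by default; the first
window instead pools all participants from the cohort minimum age,
giving parcels 25–40 and 41–50 at integer ages, so the sparse young
end is never split). Centers run to the last age whose full older
parcel fits the observed range — 40 through 65 for a 25–75 cohort —
and any window with fewer than 10 participants in either parcel is
dropped. Per center, the two-sided Wilcoxon p-values are BH-adjusted
*across features within that center* (each center is one comparison
family; pooling across centers would couple the curve to itself), and
the wave is the count of features with q below a cutoff, as a function
of c.

Crest calling is intentionally simple and explicit, since a visual
"two crests" judgement is not testable: a crest is a center whose
count is maximal within a ±3-year neighbourhood *and* exceeds the null
threshold there. The null comes from shuffling participant ages
against the fixed feature matrix and rerunning the scan (20
permutations by default in tests and the acceptance run); the envelope
keeps the per-center 50th/95th/99th count percentiles *and* the same
quantiles of each permutation's maximum count over centers, and the
crest threshold is the larger of the two at the chosen level. The
family-wise component matters: null BH counts are mostly zero, so the
per-center 95th percentile alone is zero almost everywhere and a
single-feature blip at any of ~26 (positively correlated) centers
would be called a crest far more often than 5% of the time. Requiring
exceedance of the maximum-count quantile calibrates "no crests under
the null" at the stated level, while planted crests sit one to two
orders of magnitude above either threshold.
Plateaus resolve to their midpoint (rounded down); crests at the first
or last center carry an edge flag because one side of their
neighbourhood is unobserved. Robustness is assessed on a full
factorial of window widths {15, 20, 25, 30} — read as *total* width,
with parcels of half that — and q cutoffs {1e-4, 1e-3, 1e-2, 0.05}.

## Pathway enrichment and functional modules

Over-representation uses the hypergeometric upper tail with the
database universe as population; by default the universe is all
annotatable (measured) features of the matching omics type, which is
the conservative choice when the measured panel is a biased subset of
the annotation. P-values are BH-adjusted; pathways with adjusted
p < 0.05 are significant.

Redundancy collapse proceeds in two rounds. Within each source
database, significant pathways form a similarity network — Wang
semantic similarity on the ontology graph for GO (edge weights 0.8 for
`is_a`, 0.6 for `part_of`; edges above 0.7), Jaccard similarity of
member sets for KEGG/Reactome-style collections (edges above 0.5) —
partitioned by Girvan–Newman edge-betweenness communities with the
dendrogram cut at maximum modularity; each module is represented by
its smallest-adjusted-p member. Surviving modules from all sources are
then merged once more by Jaccard similarity of their member-feature
unions (cutoff 0.5, the same threshold as the within-source Jaccard
round) with the same community procedure.

One caveat is worth recording: the maximum-modularity cut of a
Girvan–Newman dendrogram is restricted to partitions reachable along
the edge-removal sequence, and on small unstructured graphs it can
miss the global modularity optimum. The suite therefore checks exact
agreement with exhaustive modularity maximization on structured
reference graphs (bridged triangles, bridged cliques, stars) and
bounds — rather than equates — the Girvan–Newman modularity on random
graphs.

## The synthetic generator

`simulate_cohort()` draws enrollment ages uniform on 25–75, visit gaps
uniform on 3–6 months, follow-up log-normal with median 1.7 years
(truncated at 6.8), healthy flags Bernoulli(0.9) with at least one
healthy visit guaranteed, sex ≈ 52% female, BMI normal around
28.2 kg/m², and IRIS unknown at rate 38/108 — each matching the cohort
composition the defaults emulate. A feature's value is

```
baseline + archetype(age) + confounder effects + participant intercept + noise
```

with Gaussian noise (SD 1) and a participant-level random intercept
(SD 0.3) shared across a participant's visits. Confounders enter
additively in SD units through standardized covariates, with a random
sign per feature. Microbiome omics types are emitted as
logistic-normal relative abundances (per-sample softmax over the
type's taxa) plus a taxon→genus map, exercising the genus-collapse and
log-transform paths.

What the generator does **not** emulate — and what passing tests
therefore do not certify about real data: platform-specific noise
(count overdispersion, batch effects, detection limits, compositional
coupling beyond the softmax), informative missingness, within-person
autocorrelation beyond the shared intercept, and confounder–age
interactions. The generator's distributions are stand-ins chosen for
verifiability, not realism of any single platform.

## Problem sizes and numerical choices

The verification runs use desk-scale presets chosen as the package's
reference conditions: 108 participants and 2,000 features (300 + 300
of them carrying 1.5-SD logistic shifts at ages 44 and 60) for the
wave analysis; 11 templates × 100 features for cluster recovery;
1,000 stable features for null calibration; 20 age permutations for
envelopes. Degenerate inputs are handled explicitly: zero-variance
features are excluded from scaling and correlation with a message;
features coincident with a cluster center take membership 1 by the
limit convention; rank-deficient confounder designs drop aliased
columns; empty significant-pathway sets yield an empty module table
rather than an error. All randomness flows from a single integer seed
through a deterministic child-seed derivation, so every result in the
pipeline is bit-reproducible at fixed seed.
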