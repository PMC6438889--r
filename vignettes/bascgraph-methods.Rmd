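---
title: "Methods: bootstrap-stable cluster connectomes and cost-thresholded graph analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bootstrap-stable cluster connectomes and cost-thresholded graph analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bascgraph` implements a two-step analysis of multi-subject resting-state
region time series, together with a synthetic-cohort generator that supplies
ground truth for every stage. This vignette documents the models, the
tunable parameters and their defaults, the numerical choices, and the known
limits of what the synthetic validation can show.

## The analysis in outline

**Step 1 — data-driven parcels and connectome contrasts.** Regional time
series are scrubbed of high-motion frames and residualised against slow
drifts. Parcels are derived by bootstrap analysis of stable clusters (BASC):
Ward clustering of the regions is replicated under a circular block
bootstrap of frames, giving each subject a region-by-region *stability
matrix* (the probability that two regions co-cluster); subjects are then
bootstrapped, the resampled average stability is re-clustered, and a final
consensus clustering of the group stability matrix yields the partition at
each resolution of a multiresolution grid. Per subject and resolution, a
cluster-by-cluster Fisher-z connectome is computed; each connection is
tested between groups with an ordinary linear model, discoveries are
controlled per resolution by Benjamini–Hochberg FDR, and a label-permutation
*omnibus* test on the total discovery count pooled over resolutions gates
any per-resolution interpretation.

**Step 2 — cost-thresholded graphs and hubs.** At one chosen resolution,
each subject's cluster correlation matrix is thresholded into binary graphs
over a range of *costs* (the retained fraction of all node pairs). Global,
local, and cost efficiency and the small-world index omega are computed as
cost curves; node degree and betweenness centrality are averaged over a
fixed cost range; hubs are clusters whose group-mean degree exceeds the
pooled mean + 1 SD in at least one group; and the cost-averaged metrics
feed group t-tests/GLMs, two-way group-by-subgroup ANOVAs, and
degree–cognition correlations.

## The synthetic cohort generator

Each of the `n_true_clusters` planted clusters has one latent Gaussian
signal; the latent correlation matrix has `rho_between` off the diagonal,
optionally *boosted* for hub clusters (the boost adds to every latent
correlation of that cluster) and shifted by planted per-edge, per-group
effects. A region's series is its cluster latent plus white noise scaled so
the expected within-cluster region correlation equals `rho_within`; the
realised between-cluster region correlation is therefore
`rho_between * rho_within` (attenuation by the region noise). The additive
latent parameterisation means planted structure composes transparently and
positive definiteness is *checked*, with an error naming the modified
entries, never silently repaired.

Per-frame displacement is i.i.d. log-normal with moment-matched `fd_mean`
and `fd_sd`; the per-run mean displacement is carried forward as the motion
covariate in all group models. Subject covariates (age, sex, depression
score) are drawn per group from the configured demography; the default
demography mirrors a four-group aging/Parkinson's design (young controls in
their twenties; older controls near 70 y; patients with higher depression
scores; the cognitively impaired patient group with mean cognition about
1 SD below norms, 150 frames per run at TR 2.6 s, three runs).

Cognition is coupled to network structure through the subject's realised
hub strength `b`: `mean_z = baseline(group) + coupling * b + noise`, and
the five domain scores scatter around `mean_z` with centred deviations (so
their mean reproduces `mean_z` exactly). The default
`cognition_coupling = 7` was fixed from the generator's own variance
decomposition: with `corr(degree, b) ≈ 0.70` at the default desk-scale
geometry, `sd(b) = 0.05` and `z_noise_sd = 0.5`, the induced population
degree–cognition correlation is
`0.70 * c * 0.05 / sqrt(c^2 * 0.05^2 + 0.5^2) ≈ 0.4` at `c = 7`. Note that
a *single-cohort* estimate of that correlation at n = 35 still carries the
irreducible Pearson sampling error `SE ≈ (1 - rho^2)/sqrt(n - 3) ≈ 0.15`;
recovery is therefore assessed on the mean across seeds, and no per-seed
band tighter than that SE can have high coverage at this sample size.

Desk-scale defaults (100 regions, 10 clusters, T = 150, three runs, groups
of 10) keep the full chain fast while preserving the shape of a
~1000-region, 150-volume study. What the generator does *not* emulate:
hemodynamics, spatially structured noise, motion artefacts correlated with
the signal, site effects, or non-Gaussian tails — so green tests show the
*estimators and inference machinery* behave as designed, not that the
pipeline is robust to every artefact of real fMRI.

## Preprocessing

Frames with displacement strictly greater than `fd_threshold` (default
0.5 mm) are removed; a run retaining fewer than `min_volumes` (default 40)
frames is rejected. Confound regression removes, per region, the
least-squares fit of an intercept, a discrete-cosine drift basis with all
frequencies below `highpass_hz` (default 0.01 Hz at `tr_s = 2.6` s), and
any supplied confound columns; collinear regressors are dropped with a
warning rather than an error.

## BASC numerical choices

* **Distances.** Ward clustering of time series uses
  `d = sqrt(2 (1 - r))`, the Euclidean distance between standardised
  series, so Ward's variance criterion is meaningful; clustering of
  stability matrices uses `1 - stability`. Agglomeration is
  `stats::hclust(method = "ward.D2")`; merge ties are resolved by its
  deterministic ordering.
* **Block length** defaults to `ceiling(sqrt(T))`, the standard
  rate-optimal order for dependent-data block bootstraps; the study design
  this emulates does not fix a value.
* **Replications.** Individual level defaults to 1000 at study scale (the
  package-level helpers default to 100 for desk-scale work); the group
  level, for which no published value is fixed, defaults to 500 (100 at
  desk scale). Stability entries are exact multiples of `1/n_boot`.
* **Multi-run subjects** are concatenated after scrubbing and confound
  regression for individual stability — concatenation maximises usable
  frames where the source design is silent.
* **Group stability** clusters the raw bootstrap-average of individual
  stability matrices; no intermediate thresholding is applied.
* The multiscale resolution-selection step of the original BASC literature
  is not implemented; the resolution grid is configuration, with
  `c(4, 10, 19, 35, 63, 118, 221, 393)` as the study-scale default.

## Connectomes

Region series are standardised before cluster averaging, which makes the
connectome invariant to per-region affine rescaling (without it, a
rescaled region would dominate its cluster mean). Between-cluster entries
are `atanh` of the Pearson correlation of cluster mean series;
within-cluster diagonal entries are `atanh` of the *average pairwise*
correlation over distinct region pairs (self-correlations excluded —
including them would make the transform undefined); singleton clusters get
`NaN` and are skipped by the statistics. Runs are combined by the entrywise
mean in z-space, matching the per-run transform; whether averaging happens
in r- or z-space is not fixed by the source design, and z-space is the
common practice.

## Connection-wise statistics and the omnibus gate

Each unique connection (upper triangle including the within-cluster
diagonal) is fit by OLS with intercept, group dummy, mean frame
displacement, and optionally mean-centred age; with no extra covariates the
dummy t equals the pooled two-sample t exactly. FDR is controlled *within*
each resolution across its connections. The omnibus statistic is the total
discovery count pooled over resolutions, referenced to its permutation
distribution under group-label exchange (all other covariates travel with
their subjects); `p = (1 + #{perm >= obs}) / (1 + n_perm)`. This
permutation form was chosen because the pooled-FDR omnibus procedure it
stands in for is not spelled out in the source design; permutation keeps
the family-wise guarantee assumption-light. One practical property worth
knowing: when every affected edge carries an *identical* strong effect, the
permutation distribution of the pooled count becomes nearly two-valued
(either an imbalanced permutation rediscovers everything or nothing), so
achievable p-values saturate; graded effect sizes — the realistic case —
restore a well-behaved null.

## Graph analysis choices

* **Edge ranking** for cost thresholding uses the signed weight
  (most-positive first), not the absolute value: at the 18–24% costs used
  for node metrics this retains only strong positive couplings, consistent
  with the resting-state literature this design builds on. Ties break by
  lexicographic (i, j) order; edge count per cost is
  `floor(cost * k(k-1)/2)`. Any strictly increasing transform of the
  weights (including Fisher z) gives identical graphs, which the tests
  assert.
* **Efficiency.** Disconnected pairs contribute zero inverse path length.
  Local efficiency of a node is the global efficiency of its neighbour
  subgraph (zero below degree 2).
* **Betweenness** is standard unnormalised Brandes betweenness with
  fractional credit among tied shortest paths and endpoints excluded; the
  verbal "number of shortest paths through the node" definition is
  imprecise, and the unnormalised scale matches the magnitudes this kind of
  study reports.
* **Omega** is `L_rand / L − C / C_latt` with 10 degree-preserving
  randomised surrogates for `L_rand` and 10 latticized surrogates (double
  edge swaps accepted only when they shorten total ring distance) for
  `C_latt`, 10 rewiring attempts per edge, seeded. Complete graphs give
  exactly 0; ring lattices are negative; dense random graphs positive.
  Disconnected graphs fall back to the largest component with a warning.
* **Cost range.** Node metrics average over 18–24% in 0.5% steps (13
  graphs). The pipeline also recomputes each group's cost-efficiency argmax
  and warns when the configured range excludes it, rather than silently
  trusting the default.
* **Hub rule.** The rule mean and SD pool all subject-by-cluster
  cost-averaged degrees across groups; a cluster is a hub when any group
  mean exceeds mean + 1 SD; a-priori clusters are united into the analysis
  set regardless.

## Group, subgroup, and cognition statistics

Group contrasts of node metrics use the pooled two-sample Student t (an
explicit degenerate branch handles zero-variance metrics) or an OLS model
with mean-centred age; BH correction runs across the analysis-set clusters
within each metric, and both raw and adjusted p-values are reported. The
subgroup ANOVA is a fixed-effects two-way model (group × subgroup) with
Type II sums of squares via `car::Anova`, splitting numeric covariates at a
configurable threshold (the pipeline uses the cohort mean, mirroring the
"split at the whole-group average" convention, e.g. 67.6 y for age and 6.9
for the depression score in the design this emulates) and flagging empty
cells as degenerate instead of failing. Degree–cognition association is the
Pearson correlation per cluster, with age partialled by residualising both
variables when requested, BH-corrected across the tested clusters.

## Problem sizes used in the shipped validation

The packaged tests and the acceptance script run the chain at reduced but
structurally faithful sizes chosen as desk-scale study conditions: planted
-partition recovery at 100 regions / 10 clusters / 100 bootstrap
replications; omnibus family-wise calibration over 100–200 null cohorts of
16 subjects at 99 permutations; BH calibration on 2000-hypothesis uniform
nulls; power checks over 10 generator seeds per scenario. The 118-node
cost-range mean degree (24.6 to one decimal) is an analytic identity of the
thresholding rule — `mean over costs of 2*floor(cost*k(k-1)/2)/k` — and is
asserted on arbitrary full-rank weight matrices.

## Known limitations

Stability and consensus clustering inherit `hclust`'s O(k^2 log k) cost per
replication, so very large region counts need the caching layer and
patience. The omnibus count statistic saturates under uniformly strong
effects (above). Hub detection at coarse resolutions (few nodes) is noisy
because degree takes few distinct values over a narrow cost range. The
generator's covariate–outcome couplings are linear and Gaussian; none of
the inference corrects for non-normality, which real cohorts may require.
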