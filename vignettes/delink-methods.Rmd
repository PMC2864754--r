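---
title: "Detecting condition-specific network rewiring: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting condition-specific network rewiring: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delink)
```

## The setting

`delink` analyses a replicated two-condition developmental time course —
log10 expression ratios against a common reference pool, five days,
control and treated arms, about four biological replicates per cell (one
array may be missing, leaving 39 samples) — on top of a *backbone*
functional-coupling network whose edges carry a confidence score (FBS).
The backbone is consumed as input; the package's contribution is the
dynamic layer: which backbone interactions are supported by
co-expression, and under which condition.

## Per-gene model

Each gene's profile is fit by a fixed-effects two-way ANOVA with factors
DAY (5 levels) and TREATMENT (2 levels) plus interaction. Sums of
squares are Type II — each term adjusted for the terms that do not
contain it — because the degraded-array design is mildly unbalanced and
Type II reduces to the classical balanced decomposition when no cell is
short. The per-day treatment contrast tests the treated-vs-control mean
difference within day *d* against the pooled residual variance of the
full model (pooled residual degrees of freedom maximise power at n = 4
per cell); the day-*d* fold change is `10^(mean_treated - mean_control)`.
A gene is *differentially expressed on day d* when that contrast's raw
p-value is below `alpha` (default 0.01; raw rather than adjusted,
because the calls feed network analyses that carry their own nulls), and
*developmental* when the DAY main effect is significant. The *first DE
day* is the minimum DE day, also for genes whose significant days are
non-contiguous. Variance fractions (eta squared, `SS_factor/SS_total`)
summarise what drives a gene, with bootstrap confidence intervals over
within-cell resampling. Degenerate inputs follow documented conventions:
an all-constant profile has F = 0, p = 1; a zero-residual fit declares
non-zero effects exact (p = 0).

All genes share the design matrix, so the implementation computes all
complete-case genes in one set of QR fits and falls back to per-gene
fits only where values are missing (missingness is handled by pairwise
deletion in correlations and by refitting on complete rows in ANOVA).
Unit tests pin the fast path to `car::Anova(type = 2)` and to a
cell-mean oracle.

## Link model and the classification cascade

For each backbone edge the package computes Pearson correlations (PLC)
over all samples, over treated samples and over control samples, and —
for candidate edges — a three-way ANOVA on the stacked two-gene response
with factors GENE, DAY, TREATMENT and all interactions. The cascade:

1. **enabled**: `plc_trt >= plc_high` and `plc_ctl < plc_low` and
   `min(p_GENExTREAT, p_GENExDAYxTREAT) < alpha`;
2. **sensitive**: the mirror image;
3. both correlations at or above `plc_high`: **developmental** when the
   per-day mean profiles correlate at `plc_high` in both conditions *and*
   both genes have a significant DAY effect, else **resistant**;
4. **ambiguous** when only the overall correlation clears `plc_high`;
5. **none** otherwise, including any edge with fewer than `min_pairs`
   (default 10) complete pairs in either condition.

Defaults: `plc_high = 0.75` (over a 39-sample profile this corresponds
to p far below 0.01 — see `plc_pvalue(0.75, 39)`), `plc_low = 0.5`,
`alpha = 0.01`, `fbs_min = 3`. The `plc_low` ceiling and the ANOVA gate
are design choices of this package: the absent-side cutoff is not a
published constant, so it is a conservative midpoint exposed as a
parameter, and the gate uses the minimum of the two GENE-by-treatment
interaction p-values because either pattern — a day-independent or a
day-modulated differential response — marks a genuine rewiring. Parallel
shifts of two genes leave all GENE interactions at zero, which is
exactly the case the gate must reject. The three-way fit goes through
`lm` + `car::Anova(type = 2)`; only enabled/sensitive candidates (by the
correlation pattern) need it, which keeps the per-edge cost low.

The per-day-mean developmental test uses the 5-point day-mean profiles
per condition. Five points is a weak basis for a correlation, and random
developmental trajectories correlate by chance at an appreciable rate;
the developmental and ambiguous classes absorb this, and the
enabled/sensitive calls are protected from it by the `plc_low` ceiling
plus the ANOVA gate. This is a real limitation of any 5-day design, not
of the implementation, and it is why the permutation FDR is reported
alongside the calls.

**Permutation FDR.** Treatment labels are permuted within each
(day, replicate) stratum, which preserves the day structure and the
unbalanced cell; the FDR estimate is the mean permuted count of
enabled + sensitive calls over the observed count, truncated to [0, 1],
and undefined (NA) when nothing was observed.

## Module discovery

Modules enriched in DELs are grown greedily from each DEL seed edge:
starting at the seed's endpoints, the neighbouring node that most
decreases the hypergeometric upper-tail probability of the module's
induced DEL count is added until no addition improves it (or 130 nodes).
Ties break on the lexicographically smallest gene id, so growth is
deterministic; connectivity holds by construction. Polarity P modules
grow from enabled seeds against the enabled universe, N from sensitive,
PN from either against the union (and must contain at least one internal
link of each sign). Modules of one polarity merge when their node
Jaccard exceeds 0.5 (the better p survives); survivors are BH-corrected
and kept at q < 0.05. The original in-house clustering this re-creates
is undescribed beyond its name, so this is a documented reimplementation
chosen for determinism and testability, not a reproduction; absolute
module counts are therefore not comparable across implementations, and
the tests assert planted-truth recovery (node Jaccard ≥ 0.8 on planted
cliques) rather than counts. GO annotation of modules is the standard
hypergeometric enrichment against the annotated measured universe with
BH correction.

## Day-1 linkage and the meta-flow network

`linkage_stats()` measures the fraction of genes first DE on days 2–5
that are directly adjacent to at least one day-1 gene, with an empirical
p-value `(1 + #{null >= obs}) / (1 + n_draws)` against random seed sets
of equal size. The null is uniform over measured network genes by
default, with a degree-matched option (log2 degree bins): altered genes
tend to sit on hubs, so the uniform null answers "more than random
genes?" and the matched null "more than random genes of the same
connectivity?" — both are informative and the choice is the user's.

The GO–GO network generalises gene-level links to biological-process
links. Eligible gene links connect two DE, GO-annotated genes at
`fbs > 3`. Each link is labelled by its endpoints' first-DE days; only
same-day (d -- d) and consecutive (d -> d+1) patterns are admissible —
exactly nine over five days — and links whose endpoints are two or more
days apart carry no pattern. Per pattern, the observed count `O_ij` over
category pairs is compared with `E_ij = N_i(a) N_j(b) / T`, where the
marginals count occurrences of any pattern links involving category i on
day a (resp. j on b) and T is the pattern total; this closed form is
chosen because it normalises (`sum(E) = sum(O)` identically, which the
tests assert) and matches the verbal definition of expectation from
category occurrences. Same-day patterns are tallied ordered (both
orientations) and folded by halving the diagonal, which yields the
`N_i N_j / (2T)` convention for unordered pairs. The score is the
one-cell goodness-of-fit `(O - E)^2 / E`, retained at `chi2 > 6.64`
(the 1-df 0.99 quantile, i.e. p < 0.01) with `O >= 3` and `E > 0.5`.
Genes with several GO memberships contribute to each (multiple counting
is the documented default; direct annotations are used as given — an
ontology-propagation step is deliberately out of scope). Consecutive
edges are oriented from the earlier day, giving the day-by-day flow its
arrow semantics.

## The synthetic generator

`simulate_dataset()` emulates the study conditions: 2 conditions × 5
days × 4 replicates with the treated day-2 replicate dropped by default
(39 arrays), per-gene developmental baselines as random walks over days
(step 0.3 on the log10 scale, so developmental variance dominates the
typical gene), treated-only mean shifts from a DE schedule (default
effect 0.3 ≈ 2-fold), and planted condition-specific co-expression via a
latent day trajectory shared by each planted set within its active
condition.

Choices that matter, and why:

* **Latent trajectory, standardised.** The latent is drawn per (day,
  condition) and shared across replicates — co-regulation produces
  day-coherent, not sample-level, covariation, and this is also what
  makes the ANOVA gate detectable in principle. It is standardised to
  fixed day-variance so the coupling calibration below is exact rather
  than in expectation; without this, whole planted sets succeed or fail
  together on the luck of five draws.
* **Calibrated coupling.** The base loading is derived in closed form
  from `target_plc` (default 0.9): `lambda = sqrt(rho/(1-rho) *
  noise_sd^2 / 0.8)`, anchoring the weakest planted gene at the target
  within-condition correlation.
* **Loading spread.** Per-gene loadings multiply the base by
  U(1, 10). Response magnitudes within a co-regulated set span about an
  order of magnitude in strongly induced pathways, and this spread is
  precisely what gives the GENE × DAY × TREATMENT interaction its power:
  with equal loadings the two genes' treated profiles are parallel and
  the gate (correctly) sees nothing. Correlation is loading-invariant as
  long as each gene's own signal-to-noise stays high, so the spread
  costs little PLC.
* **Flat baselines for planted genes.** Planted genes model
  condition-driven, not developmental, co-expression (their correlation
  must be *absent* in the other condition), so their developmental
  baseline is flat and their off-condition profiles are pure noise.
* **What the generator does not model.** Probe effects, dye bias,
  intensity-dependent variance, correlated replicate batches, and any
  hybridisation noise model. Passing recovery tests on this generator
  shows the statistical machinery is correct and calibrated under its
  assumptions; it does not certify performance on real arrays, where the
  unavailable preprocessing chain (error-weighted replicate averaging,
  probe-to-gene mapping) adds further variation.

`plant_propagation()` assigns first-DE days so that each requested
GO-to-GO flow is supported by a chosen number of backbone links,
erroring on infeasible requests, which gives the meta-flow analysis an
exact planted truth.

## Problem sizes and numerical conventions

The test suite and the acceptance script run on backbones of 150–400
nodes, planted sets of 8–10 genes, 1000-gene null panels for type-I
calibration, 20 permutations for FDR and day-label nulls, and 100–1000
null draws for linkage statistics; these sizes give stable rates (the
planted-link recovery pools three replicate simulations, about 50
planted links) while keeping a full run in the tens of seconds.
Correlations use pairwise-complete observations and return NA below 3
pairs or for constant vectors; classification requires 10 complete pairs
per condition; tiny negative sums of squares from floating-point
cancellation are clamped to zero; every stochastic routine takes an
explicit seed and restores the caller's RNG state.

## Known limitations

* The enabled/sensitive gate's exact published criteria are not
  recoverable; the cascade here is a faithful, parameterised
  reconstruction, so absolute class counts on real data will differ from
  any original implementation even where both are sensible.
* With five days, spurious day-profile correlation is common; the
  developmental/ambiguous classes absorb it, and enabled/sensitive
  false positives concentrate on edges where an unplanted neighbour's
  trajectory happens to align with the treated latent — the permutation
  FDR is the honest summary of that rate.
* The GO–GO expected-count form is a reconstruction constrained by its
  normalisation property; it is exposed (`expected_count()`) for
  replacement.
* Module discovery explores one greedy path per seed; it is
  deterministic but not optimal, and `max_size` caps worst-case growth.
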