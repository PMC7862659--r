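---
title: "Identifying key OTUs for potato tuber storage stability"
author: "tuberstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying key OTUs for potato tuber storage stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuberstab)
```

## The scientific question

Potato tubers sprout after a cultivar- and batch-specific dormancy period;
premature sprouting is a major source of post-harvest loss. Beyond genotype
and storage conditions, the bacterial community a tuber carries out of the
soil may influence when it sprouts. Given 16S rRNA amplicon OTU tables of
tubers sampled through storage (harvest, dormancy break, sprouting) together
with each batch's *storage stability* — the number of days from harvest until
the batch sprouted — the question is which community members are associated
with short or long storage.

`tuberstab` implements the full selection procedure as a reusable, testable
pipeline:

1. **rOTU filtering** — keep OTUs with at least 0.01 % mean relative
   abundance that are present in at least 2 of 3 replicate tubers of some
   cultivar × soil × timepoint cell ("reproducibly occurring OTUs").
2. **Diversity** — rarefaction, observed richness and the Gini–Simpson
   index with a permutation ANOVA per design factor; Bray–Curtis
   dissimilarity with PERMANOVA and (constrained) principal-coordinates
   ordination.
3. **Indicator selection, route A** — random-forest backward elimination
   (varSelRF-style) of OTUs that discriminate short / medium / long
   storage-stability classes, run per storage timepoint and pooled.
4. **Indicator selection, route B** — a Spearman correlation matrix over
   ties-filtered rOTUs plus a `storage_days` node, thresholded at
   |r| ≥ 0.5 and p ≤ 0.001.
5. **Key OTUs** — OTUs selected by *both* routes, labelled `long` / `short`
   by the sign of their storage correlation (class-mean fallback for OTUs
   linked only to other OTUs).
6. **Sprouting assay statistics** — BBCH stage sums, a one-way linear
   model, ANOVA and estimated-marginal-mean contrasts of every treatment
   against the sterile-medium control with a many-to-one (Dunnett-style)
   adjustment.

A Dirichlet–multinomial simulator generates complete studies with *planted*
storage-associated taxa so every stage can be validated against a known
ground truth.

## The data model

An `OtuExperiment` extends `SummarizedExperiment`: a `counts` assay (OTUs ×
samples, non-negative integers), `colData` with the design (cultivar, soil,
timepoint, replicate, `storage_days`, and a derived `stability_class`), and
an optional `taxonomy` column in `rowData`. Validity enforces unique
identifiers and `storage_days` constant within a cultivar × soil batch —
storage stability is a *batch-level* phenotype, replicated over that batch's
tubers. Sample names follow the `cultivar_timepoint_soil_replicate` scheme
but are treated as opaque strings; design factors come only from metadata
columns, because parsing names is fragile.

## Statistical choices and their rationale

**Relative-abundance floor.** "0.01 % relative abundance" is read as the
*mean* per-sample relative abundance over the analysis samples (the most
common convention; `abundance_stat` switches to `max` or the pooled read
fraction). Replicate presence means count > 0, with no minimum count, and
the presence criterion must hold in at least one replicate cell
(`presence_scope = "all"` for the stricter reading). Under-complete cells
rescale the threshold to `ceiling(min_present / of_replicates * available)`
with a warning.

**Ties filter.** Before correlation analysis, OTUs whose modal count occurs
in strictly more than two-thirds of samples are dropped (their ranks are
mostly ties, usually zeros). The fraction is held exactly as 2/3 with a
strict comparison, so an OTU tied in exactly 4 of 6 samples is retained;
passing `max_tie_fraction = 0.6666` reproduces the decimal-truncated
reading, which flips that boundary case.

**Rarefaction and alpha diversity.** A single subsampling draw without
replacement to the minimum sample total (overridable); samples below depth
are dropped and reported. "Simpson's index" is the Gini–Simpson form
1 − Σpᵢ² (a `variant` switch provides 1/Σpᵢ²). The permutation ANOVA tests
each factor marginally: the classic one-way F statistic with a p-value from
random relabelling of the response, `p = (1 + #{F* ≥ F}) / (1 + n_perm)`.
A joint multi-way model is *not* fitted — with one F and p reported per
factor, marginal tests are the transparent choice.

**Beta diversity.** Bray–Curtis on per-sample proportions (library size must
not carry signal). PERMANOVA partitions squared distances (Anderson's
pseudo-F) with unrestricted label permutation; a `strata` argument allows
restricted permutation within blocks, and `exact = TRUE` enumerates all
two-group assignments, which the test suite compares against a brute-force
oracle. Negative PCoA eigenvalues are reported, not corrected, with a
warning when their mass exceeds 5 % of the positive mass. CAP is the
discriminant rotation of the PCoA axes that explain ≥ 85 % of the positive
eigenvalue mass (configurable), giving at most groups − 1 constrained axes.

**Random-forest backward elimination.** Storage-stability classes are
batch-level tertiles of the distinct `storage_days` values (ties go to the
lower class; the lowest tertile — earliest sprouting — is `short`). The
forest sees relative abundances, removing library-size signal. Impurity
(Gini) importances from the initial full fit are reused throughout the
elimination (recomputing them at every step is known to bias the selection;
a flag enables it), 20 % of the remaining OTUs are dropped per step down to
2, and the selected set is the smallest whose out-of-bag error is within
`se_multiplier` (default 1) standard errors of the path minimum,
SE = √(e(1−e)/n). 2000 trees per forest keep OOB errors stable at this
sample size. The pipeline runs one elimination per timepoint plus one pooled
over all samples and unions the selections, recording each OTU's origin —
the per-stratum and joint readings of the procedure are both defensible, and
the union preserves indicators that only one stratum resolves.

**Correlation network.** Spearman correlations (average ranks for ties) over
ties-filtered rOTU relative abundances plus the batch-level `storage_days`
replicated per sample; two-sided p-values from the t approximation
t = ρ√((n−2)/(1−ρ²)) (a permutation null is available by flag). Thresholding
keeps |r| ≥ 0.5 and p ≤ 0.001. The default `mode = "absolute"` keeps
*negative* correlations: taxa anti-correlated with storage days are exactly
the short-stability candidates, so a literal positive-only reading
(`mode = "positive"`) would discard half the biology. The p cut-off is
applied unadjusted, matching the fixed 0.001 convention; a BH flag exists
but defaults off.

**Key OTUs.** Any surviving edge qualifies an RF-selected OTU (a
`storage_edge_only` switch restricts to direct storage-node edges);
direction comes from the storage-correlation sign, since that is the
quantitative evidence, with the class-mean argmax only as fallback —
which is how `medium` labels arise.

**Assay statistics.** The model unit is the per-disc final BBCH stage
(codes 00/01/02/03/05 mapped to 0/1/2/3/5); reporting also provides the
per-repetition stage sums and their averages. The many-to-one adjustment
uses the deterministic multivariate-t approximation (`"dunnettx"` in
emmeans); the exact mvt integration is Monte-Carlo and would break
bit-reproducibility. Treatments with a negative estimate and adjusted
p < 0.05 are flagged as sprouting inhibitors.

## What the simulator emulates — and what it does not

`simulationConfig()` defaults define the reference study conditions:

* **Design**: 3 cultivars × 3 soils × 3 timepoints (T2 harvest, T6 dormancy
  break, T7 sprouting) × 3 replicate tubers = 81 samples; 9 cultivar × soil
  batches. Batch sprouting times span 135–169 days evenly and are assigned
  to batches at random — a designed storage experiment follows every batch
  to its own sprouting date, and even coverage avoids degenerate tertile
  geometries in which the three stability classes collapse.
* **Community**: 500 OTUs with a log-normal baseline (σ = 1.5 on the log
  scale), which reproduces the usual few-dominants / long-tail shape of
  amplicon tables.
* **Counts**: per sample, proportions ~ Dirichlet(concentration × expected
  composition), reads ~ multinomial at a library size drawn uniformly from
  7,000–40,000 (typical post-QC 16S depths; rarefaction then lands near the
  minimum, as in real studies). The Dirichlet precision of 5000 gives a
  replicate-to-replicate CV of ≈ 14 % for a 1 % taxon and over 100 % for a
  0.01 % taxon — tight for abundant organisms, noisy for rare ones, as in a
  controlled greenhouse/storage experiment with homogenized bud-disc pools.
* **Planted signal**: 10 "long" and 10 "short" OTUs at ≈ 1 % baseline
  abundance whose expected relative abundance changes by e^±0.02 per storage
  day (about two-fold across the 34-day spread) — the scale of the
  storage-associated genera such studies report.
* **Community shift**: 5 unplanted OTUs change by a total log-fold change of
  1.2 across the timepoints with random sign, mimicking the handful of
  strongly dynamic genera that dominate the harvest → sprouting shift. The
  shift module is deliberately small: large coherent shift modules create
  their own |r| ≥ 0.5 co-occurrence cliques and would leak
  storage-*unrelated* taxa into any intersection-based selection — a real
  limitation of co-occurrence screening that the simulator makes visible if
  `shift_fraction` is raised.

Not emulated: sequencing error and chimeras, taxonomy beyond placeholder
lineages, phylogenetic structure, overdispersion heterogeneity between
taxa, soil chemistry, or any direct causal effect of taxa on sprouting.
Passing recovery tests therefore shows that the *procedure* finds planted
monotone storage associations under compositional count noise at realistic
depth — not that real tuber communities behave this way.

## Numerical and degenerate-input conventions

* Permutation p-values use the add-one estimator, so p ≥ 1/(n_perm + 1).
* One-way F is defined as 0 when the between-group sum of squares vanishes
  and +∞ when groups separate perfectly (within-SS 0, between-SS > 0), so
  permutation counting remains well defined.
* Constant correlation nodes are recorded as r = 0, p = 1 with a warning
  (the ties filter normally removes them first).
* Zero-total samples are an error everywhere they would silently corrupt a
  proportion.
* A zero-variance assay short-circuits to F = 0, p = 1 and no inhibitor
  flags rather than propagating 0/0.
* Every random step takes an explicit seed; `runPipeline()` derives
  per-stage seeds from one global seed by stage-name hashing, so single
  stages can be re-run in isolation with identical randomness, and two runs
  with the same seed write byte-identical reports.

## Problem sizes used in validation

The test suite validates the statistics against brute-force oracles at
small n (8–30 samples), calibrates the permutation tests on 500 null data
sets (199 permutations each) and the Dunnett procedure on 1000 null assays,
and exercises the full pipeline at the reference conditions above: 10
planted-effect studies for recovery and 20 null studies for false-positive
control. These sizes give stable Monte-Carlo estimates at desk scale; the
pipeline itself handles study-scale tables (hundreds of samples, thousands
of OTUs) without changes.

## Known limitations

* The intersection inherits both routes' blind spots: the RF route's 1-SE
  rule is parsimony-seeking, so among highly redundant indicators it may
  keep only representatives from a single stratum — pooling across strata
  (and the pooled run) is what restores coverage.
* Spearman + hard thresholds ignore compositional coupling
  (SparCC/SPIEC-EASI-style estimators are out of scope).
* The t approximation for Spearman p-values is asymptotic; at n < 10 use
  the permutation flag.
* Tertile stability classes are a convention; `method = "manual"` accepts
  explicit day cut-offs when the phenotype suggests them.
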