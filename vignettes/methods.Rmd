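---
title: "Methods: tertile survival screening, cross-dataset consensus, and pathway activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tertile survival screening, cross-dataset consensus, and pathway activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `gbmscreen`, the
choices made where the design was genuinely open, and what the
simulation-backed tests do and do not establish.

## The screening model

The screen treats each feature (a gene's log-normalized expression, or
a pathway's activation level) separately. Samples are split at the
33rd and 66th percentiles of the feature's value; the middle third is
discarded and the top third ("high") is compared with the bottom third
("low"). Two complementary statistics are computed on the two groups:

- the **log-rank test**, a nonparametric comparison of the two survival
  curves — at each distinct event time the observed number of events in
  the high group is compared with its hypergeometric expectation given
  the risk sets, and `(ΣO − ΣE)² / ΣV` is referred to χ²(1);
- the **two-group Cox fit**, the partial-likelihood estimate β̂ of the
  log hazard ratio of high vs low, with a Wald p-value. For a single
  binary covariate with untied event times the log-rank test is exactly
  the Cox score test, so the two p-values are deliberately redundant
  under the null and differ mainly in their behaviour at strong
  effects and small groups.

A feature is *differential* only when **both** p-values fall strictly
below α. The dual filter is therefore slightly conservative relative to
a single test at the same α (the two tests are highly correlated but
not identical). Differential features are partitioned by `sign(β̂)`
into *plus* (high expression, higher hazard — an adverse marker) and
*minus* sets; β̂ = 0 lands in neither, keeping the sets disjoint.

Assumptions worth stating: proportional hazards between the tertile
groups, independent right-censoring, and per-endpoint completeness
(samples lacking a survival record are dropped for that endpoint only).
The screen fits no multivariate models; confounders such as age or
treatment are out of scope by design.

## Consensus across datasets

Each dataset is screened against its own universe (the features that
actually produced a usable tertile split). Plus sets are intersected
across datasets, minus sets separately, never pooled. Significance of
an observed overlap of size *k* is assessed by a size-matched
permutation: per iteration, draw from each dataset's own universe a
uniform random subset with that dataset's observed set cardinality,
intersect, and record the size; `p = #(size ≥ k) / n_iterations`
(default 1000). Drawing from per-dataset universes (rather than a
pooled one) reflects that cohorts measure different gene panels; the
random intersections then live on the shared universe automatically.

With the verbatim "equal or higher" counting rule, p can be exactly 0
at finite iteration counts; the report carries the `(count + 1) /
(n + 1)` corrected value as an auxiliary field. For two datasets the
permutation null has the closed form implemented in
`exact_two_set_p()` (hypergeometric mixing over how many shared-universe
features each draw captures); the test suite requires the permutation
estimate to sit within 3 Monte-Carlo standard deviations of it. Plus
and minus tests use independent draws.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `alpha` | 0.05 | dual p-value threshold, strict |
| `low_pct`, `high_pct` | 33, 66 | percentile cut points of the split |
| `min_group_size` | 2 | smallest usable tertile group; smaller ⇒ feature skipped, not errored |
| `tie_method` | `"efron"` | Cox tie handling; `"breslow"` available for cross-checks |
| `n_iterations` | 1000 | permutation intersections |
| `min_genes` (PAL) | 10 | minimum measured members per retained pathway |
| FDR threshold (enrichment) | 0.05 | on BH q-values, strict |

Percentiles use linear interpolation of order statistics (R's default
type 7, index `(n − 1)·q`), and group membership uses strict
inequalities, so constant features produce two empty groups and are
skipped as degenerate. Monotone-likelihood Cox fits (all events in one
group) are flagged non-converged with `NA` β̂ rather than returning an
infinite estimate, and are excluded from the differential sets.

## Preprocessing choices

Quantile normalization forces every sample onto the reference
distribution (row-wise means of the column-sorted matrix). Ties within
a column receive the **mean of the reference values at their tied
ranks** — the dominant bioinformatics convention. Note this means a
column with ties does not reproduce the reference multiset exactly at
the tied entries; the exact identical-distribution and idempotence
properties hold on tie-free columns and are tested there. Each dataset
is normalized independently: batches are deliberately treated as
separate datasets rather than being corrected, so no cross-dataset
normalization (and no batch correction) is performed anywhere.

The log transform is `log10(x + 1)`: counts contain zeros, and the
pseudocount keeps the transform total while mapping 0 to 0. Because the
transform is strictly monotone, tertile membership is identical whether
the split is computed on normalized or log-normalized values.

## Pathway activation levels

The PAL score is this package's own reconstruction of the signed
pathway-activation score family used in oncological transcriptomics:

    PAL(p, s) = Σ_g ARR(g, p) · log10 CNR(g, s) / Σ_g |ARR(g, p)|

with CNR the case-to-normal ratio (expression over the gene's geometric
mean across the dataset's samples, computed on quantile-normalized
values shifted by +1 so logs are finite) and ARR the signed
activator/repressor role (+1/−1 by convention; arbitrary finite weights
are accepted). The defining properties are preserved: the sign tracks
up/down-regulation, the reference is the per-dataset geometric mean,
and pathways with fewer than 10 measured members are dropped. The exact
weighting of the original proprietary implementation is not public;
this reconstruction is linear in log-ratios (doubling all log-ratios
doubles PAL) and antisymmetric under a global role flip, and both
properties are tested. PAL matrices feed the identical screen and
consensus code paths as genes.

## Enrichment

Over-representation only (one-sided hypergeometric tail), with BH
step-up correction and a strict q < 0.05 filter. The background
universe is the shared screened universe of the contributing datasets,
not the whole genome: the null must describe the pool the consensus
members were actually drawn from. Term databases are plain GMT inputs
treated as flat sets — no ontology-graph propagation.

## The synthetic-study generator

`generate_study()` emulates the structure the screen assumes, not any
particular tumor biology:

- counts: gene-wise negative binomial (dispersion 0.3) around lognormal
  gene means (SD 1.5 on the natural-log scale, median mean ≈ 100
  counts); shared genes keep one base mean across datasets;
- batch structure: a per-dataset, per-gene normal shift (SD 0.5) on the
  log mean, which makes datasets separate on a PCA the way distinct
  cohorts and sequencing batches do;
- survival: exponential proportional hazards, sample hazard
  `baseline_hazard · exp(Σ β · z)` with `z` the standardized log1p
  count of each planted marker in its dataset. The baseline 0.05
  events/month and Uniform(0, 60 months) independent censoring give a
  mean survival near 20 months and roughly two thirds observed events,
  matching the scale of the motivating glioblastoma cohorts. The
  exponential baseline was chosen for closed-form sampling — the screen
  assumes only proportional hazards, so a richer baseline would add
  nothing testable;
- PFS: an independent draw with the time scale shortened to 0.7× the
  OS scale (hazard divided by 0.7), mirroring the empirical PFS/OS
  mean ratio of the motivating cohort; endpoints are deliberately
  independent so tests can tell them apart;
- uniform (rather than administrative) censoring, so censored records
  interleave with events throughout follow-up and exercise the
  risk-set bookkeeping.

What the generator does **not** emulate: gene–gene correlation,
expression subtypes, FFPE degradation, or library-size artifacts.
Passing the simulation tests therefore shows the pipeline recovers
markers under its own model assumptions and stays calibrated under the
null — it does not certify performance on real cohorts with correlated
genes and confounded batches.

The calibration conditions used by the test suite and the acceptance
script are 4 datasets × 2000 genes × 200 samples over 20 seeds: a
planted shared marker at β = 1 must come out as the sole plus-direction
consensus member in at least 80% of seeds, the null dual-filter pass
rate must stay at or below 5% per dataset on average, and the null
consensus permutation p must exceed 0.05 in at least 90% of seeds.

## Cohort summaries

`summarize_cohort()` reports demographic and endpoint summaries at full
precision, with half-even rounding to two decimals applied only when
printing. Endpoint analysis sets are gated by an explicit inclusive
range in months (`os_range`, `pfs_range`): the packaged 16-patient
fixture reproduces its published endpoint summaries with ranges (2, 58)
and (2, 37), which exclude one patient whose 91-month OS / 90-month
progression was recorded after the original analysis set was frozen.
The range parameter makes that otherwise-implicit exclusion rule
visible and auditable. Missing clinical values (encoded `/` or
`Not performed` in the source table) map to `NA`, never to zero.

## Known limitations

- No multivariate adjustment; the screen is univariate by construction.
- No multiple-testing correction inside the screen itself (BH is
  applied only in enrichment); the consensus-and-permutation layer is
  the screen's guard against false positives.
- The two-dataset exact oracle does not extend to k > 2 datasets in
  closed form here; the permutation test covers that case.
- The log-rank statistic is the plain (uncorrected) version; with heavy
  ties at event times Efron-based Cox p-values and log-rank p-values
  can drift apart slightly.
- Both screen tests are asymptotic. At the calibration conditions (200
  samples, tertile groups of ~66, ~135 events) the simulation suite
  measures their null pass rate marginally above the nominal level
  (the dual filter tracks the Wald rate at about 5.1% rather than
  strictly below 5%); exact small-sample tests are not provided.
- p-values from 1000 permutations have a granularity of 0.001, and a
  reported 0 means "below 1/n_iterations", which is why the corrected
  value is also carried.
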