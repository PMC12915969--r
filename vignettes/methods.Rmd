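---
title: "Methods: scoring, adjusted correlations, mediation and symptom networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, adjusted correlations, mediation and symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nursenet` analyses ordinal questionnaire cohorts measuring sleep quality
(PSQI), depressive symptoms (PHQ-9) and nurse safety behavior (NSBQ). This
vignette documents the statistical models behind each stage, the defaults
and why they were chosen, and what the synthetic-data generator does and
does not emulate.

## Quality control and scoring

A record passes QC unless it (1) misses more than 5% of its questionnaire
fields, (2) fails the reverse-item consistency screen, or (3) carries an
anomaly label. The rules are checked in that order and a record is counted
once, under the first rule it fails, so the exclusion tallies add up to the
collected total exactly.

Two of the decisions here were genuinely open:

* **The 5% denominator.** We count all questionnaire fields — the 12
  categorical covariates plus the 29 scored items and the reverse check
  (41 fields) — rather than items alone. A respondent who skips demographic
  questions is as suspect as one who skips items, and the wider denominator
  is the stricter reading. With 41 fields the rule bites at 3 or more
  missing fields.
* **Unobservable anomalies.** "Multiple selections" and "irrelevant or
  contradictory answers" cannot be detected in a clean rectangular export —
  the information is destroyed upstream by the survey platform. They are
  therefore modeled as labels on the `qc_flag` column, which the generator
  plants and the filter consumes; this keeps the full QC accounting
  reproducible end-to-end.

The reverse-item screen pairs PHQ-9 item 1 with a reverse-worded twin:
answering both "not at all" (0/0) or both "nearly every day" (3/3) is
logically impossible for an attentive respondent. The reverse item is used
only for QC and never scored.

Totals are exact item sums (PSQI 0–21, PHQ-9 0–27, NSBQ 12–60), left
missing while any constituent item is missing. Missing **totals** are then
imputed with the median of observed totals (`impute_total_median()`),
the median being preferred over the mean because the score distributions
are skewed. Item-level cells that survive QC (at most 5% of a record) are
filled with the item median only where an analysis needs a complete item
matrix — reliability, the common-method-bias screen and the item-level
network (`complete_items()`); totals are never derived from imputed items.

Cronbach's α uses sample (n−1) variances throughout, the dominant
convention in psychometric software. Harman's single-factor screen is the
share of variance of the first principal component of the standardized item
matrix, equivalently the largest eigenvalue of the item correlation matrix
divided by the number of items, compared against the conventional 40% bar.

## Descriptives and group comparisons

Continuous scores are summarised as median and IQR with the
linear-interpolation quantile rule (`quantile()` type 7); the rule is fixed
and documented so published IQRs can be audited. Two-level covariates are
compared with the Mann–Whitney U test — U reported for the first-listed
level; exact enumeration for small tie-free groups, normal approximation
with tie and continuity correction otherwise — and multi-level covariates
with the tie-corrected Kruskal–Wallis H. When every observation is tied the
statistic is defined as 0 with p = 1 rather than NaN.

## Covariate-adjusted Spearman partial correlations

Confounding is removed by residualization: each analysis variable is
regressed on the dummy-coded covariates with a GLM and replaced by its
deviance residuals; Spearman's ρ between two residual vectors is the
partial correlation. The default adjustment set is the seven covariates
used for both the totals analysis and the item network: age band, marital
status, work experience, professional title, number of children, night
shifts per month, and off days after night shifts.

Numerical choices:

* **Family.** Gaussian with identity link for score totals. Deviance
  residuals then equal raw residuals, the residualization is a linear
  projection, and the subsequent rank correlation is well defined. The
  family is a parameter for users whose outcomes warrant otherwise.
* **Reference levels.** The first listed category of each covariate, so the
  design matrix is reproducible; rank deficiency raises an error naming the
  aliased columns rather than silently dropping them.
* **Ties and p-values.** Average ranks for ties; two-sided p from the t
  approximation on n − 2 degrees of freedom. The naive n is used — no
  degrees-of-freedom charge for the residualization — which makes p-values
  slightly anti-conservative when the covariate count is non-trivial
  relative to n; at cohort sizes in the thousands the effect is negligible.
* **Confidence intervals.** Percentile bootstrap over participant
  resamples (default 95%), seeded and recorded in the result.

## Mediation decomposition

Three covariate-adjusted GLM fits on one design give the path
decomposition: M ~ X + W (path a), Y ~ X + M + W (path b and direct c′),
Y ~ X + W (total c). The indirect effect is a·b. The total effect is taken
from its own regression rather than as c′ + a·b; under Gaussian identity
links the two agree to numerical precision (the package asserts the gap
< 1e−8 on every fit), but reporting the separate regression keeps the
definition family-agnostic. Confidence intervals are percentile bootstrap
(default 1,000 replicates), resampling participants and refitting all three
models per replicate; replicates where a focal coefficient is inestimable
are dropped and counted, with an error if more than 1% fail. Wald z
statistics come from the analytic fits for the a, b, direct and total
paths; no Sobel test is attached to the indirect path — its uncertainty is
carried by the bootstrap interval. Rare covariate levels (a level with a
handful of respondents drops out of ~1/e of resamples) are the reason z
statistics are not recomputed inside the bootstrap loop.

## Symptom network

The network has 17 nodes — the 7 PSQI components, the 9 PHQ-9 items, and
the NSBQ total — and an edge wherever the absolute adjusted partial
correlation strictly exceeds the threshold τ = 0.20. Signs and magnitudes
are kept as edge attributes; all centralities and global metrics are
computed on the **unweighted** thresholded graph. That choice is forced by
the quantities the method reports: integer degrees, and closeness values of
the form (n−1)/Σd.

Definitions (n nodes, E edges):

* degree — neighbor count;
* closeness — (n−1)/Σd on a connected graph; on a disconnected graph,
  distances are restricted to the node's component and scaled by
  (reachable/(n−1)), the standard component-aware normalization, with a
  logged note; isolated nodes score 0;
* betweenness — shortest-path betweenness normalized by (n−1)(n−2)/2;
* clustering — closed-triangle fraction among neighbor pairs, 0 for
  degree < 2;
* density 2E/(n(n−1)); diameter and average path length over unordered
  connected pairs (largest component, with a warning, if disconnected);
  degree variance with the population (÷n) denominator — logged so the
  alternative (÷(n−1)) can be audited.

Bridge symptoms are read off the betweenness ranking: a node carrying many
shortest paths between the sleep and depression clusters is the network's
bottleneck and hence the natural intervention target.

**Stability.** The correlation-stability (CS) coefficient is the mean
Pearson correlation between original and post-dropping degree centralities
over repeated bootstrap iterations (default 2,500, dropping 10%), with
values above 0.5 read as adequate. Two dropping modes exist because the
procedure is described in the literature both ways: `node_drop` removes
nodes and recomputes degrees on the induced subgraph (the default here),
while `case_drop` removes participants and re-estimates the whole
correlation matrix, network and degrees per subsample. The mode is recorded
in the result so consumers know which was run. Drop counts round to the
nearest integer with a floor of 1 (10% of 17 nodes → 2). Iterations with
fewer than 3 surviving nodes or constant degrees are skipped and counted; a
regular graph (constant degrees throughout) is reported as degenerate
rather than given a fabricated value.

**Sensitivity.** `sensitivity_rerank()` rebuilds the network at a stricter
threshold — inclusive |ρ| ≥ 0.25, against the strict |ρ| > 0.20 baseline,
matching how the two rules are conventionally stated — and reports the
top-3 nodes per metric plus a per-node verdict: `unchanged` (identical
adjacency row), `stable` (keeps all its top-3 memberships), `attenuated`
(loses a top-3 position or more than half its edges).

## The synthetic-cohort generator

The generator exists so that every stage of the pipeline is testable
without the original survey data. It emulates the *statistical shape* of a
large rotating-shift-nurse cohort, not any respondent-level record:

* covariates drawn categorically from frequencies typical of such cohorts
  (94% female, half aged 30–40, 80% bachelor-educated, 85% urban);
* standardized latent variables with an explicit mediation structure:
  S (sleep problems), M = aS + shifts + noise (depressive symptoms),
  Y = cS + bM + shifts + noise (safety behavior). The default paths
  a = 0.64, b = −0.325, c = 0 were derived from the three adjusted
  correlations the method targets via the standardized path algebra
  (r_SM = a, r_MY = ca + b, r_SY = c + ab) and then refined by simulation;
* small covariate shifts on the latents (divorce and junior titles worsen
  sleep and mood; youth, inexperience and many children lower safety
  behavior) so that the covariate adjustment has genuine confounding to
  remove;
* ordinal items as loading × latent + noise, discretized at standard-normal
  cut-points parameterized directly by marginal category probabilities —
  so item marginals are exact by construction. Loadings are heterogeneous
  (e.g., the sleep-medication component loads weakly; most PHQ-9 items load
  strongly), calibrated at n = 50,000 against the instruments' published
  reliabilities, medians/IQRs and screen prevalences;
* a shared "sleep-disturbance" factor loading on the insomnia item (D_3)
  and the sleep-duration component (PSQI_C3), plus direct sleep-latent
  loadings on D_3 and D_7, which reproduces a bridge-like topology in the
  thresholded network;
* planted QC anomalies (102 inconsistent reverse pairs, 135 labeled
  irrelevant rows on 1,986 collected) and 10 missing PSQI components, so
  the QC accounting and the imputation step run exactly as in a real
  ingest.

Fixed seeds give bit-identical cohorts; ground-truth latents are returned
alongside the records, and `validate_cohort()` compares realized structure
against the configuration.

**What it does not emulate.** Items are conditionally Gaussian before
discretization, so the generator cannot produce the zero-inflation,
response styles (straight-lining, acquiescence) or floor/ceiling
pathologies of real Likert data beyond what the cut-points induce; the
within-instrument correlation structure is single-factor (plus the bridge
factor), whereas real PSQI components have richer structure; and
covariate–latent effects are additive shifts. Passing tests on synthetic
cohorts therefore demonstrates that the *pipeline* is correct and that the
*study conditions* are reproducible — not that the generator matches any
real cohort row for row. A structural consequence worth knowing: with the
published IQRs for the three totals, a latent model cannot make the PHQ-9
and NSBQ total variances equal while keeping all reliabilities at their
published values, so the mediation coefficients on the totals scale carry a
few-percent calibration offset relative to the correlations.

## Problem sizes and determinism

The test suite works at the study's own scale — cohorts of 1,986 collected
/ 1,749 valid — using three replicate cohorts for the correlation and
mediation checks (averaging over replicates controls the ±0.025 Monte-Carlo
error a single cohort leaves on a rank correlation at that n), 100
replicate cohorts with 200-replicate bootstraps for the bias/coverage
study, a 100,000-row cohort to pin pseudo-true totals-scale coefficients,
and 2,500 iterations for the stability bootstrap. Exhaustive brute-force
oracles (BFS distances, shortest-path enumeration, triangle counts) verify
every centrality and global metric on all random graphs up to 8 nodes.
Every stochastic step — generation, both bootstraps, subsampling — is
seeded, and fixed seeds reproduce results bit for bit.

## Known limitations

* The p-values after residualization use the naive n (see above).
* The percentile bootstrap is first-order accurate; bias-corrected
  intervals are not implemented.
* Centralities are computed on the unweighted thresholded graph by design;
  weighted or regularized (e.g., graphical-lasso) network estimation is out
  of scope.
* `case_drop` stability at item level re-estimates 136 rank correlations
  per iteration and is noticeably slower than `node_drop`.
* XLSX ingest requires `readxl`; CSV needs only the hard imports.
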