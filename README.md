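# nursenet

Sleep quality, depressive symptoms and safety behavior form a tightly coupled
system in shift-working nurses: chronic circadian disruption degrades sleep,
poor sleep feeds depressive symptoms, and both may erode the safety behaviors
that protect patients. `nursenet` implements, as a tested and reusable R
pipeline, the complete analysis chain used to study that system in
cross-sectional questionnaire cohorts:

* **QC and scoring** of the three instruments — the Pittsburgh Sleep Quality
  Index (7 component scores, global score 0–21, > 7 screening poor sleep),
  the Patient Health Questionnaire-9 (9 items, total 0–27, ≥ 10 screening
  moderate-to-severe depressive symptoms), and the Nurse Safety Behavior
  Questionnaire (12 items, total 12–60) — with exclusion filters (missingness
  > 5%, reverse-item logical-consistency screen, planted anomaly labels),
  median imputation of missing totals, Cronbach's α reliability, and Harman's
  single-factor screen for common method bias.
* **Descriptives**: median/IQR summaries with Mann–Whitney U and
  Kruskal–Wallis H group comparisons across sociodemographic covariates.
* **Covariate-adjusted Spearman partial correlations**: each outcome is
  regressed on dummy-coded covariates with a GLM, and Spearman's ρ is
  computed between the deviance residuals, with percentile-bootstrap CIs.
* **Bootstrap mediation**: the decomposition X → M → Y
  (sleep → depression → safety behavior) from three covariate-adjusted GLMs,
  with a (X→M), b (M→Y | X), direct c′, indirect a·b and total effects, and
  1,000-replicate percentile bootstrap confidence intervals.
* **Symptom network analysis**: a 17-node network (7 PSQI components, 9
  PHQ-9 items, NSBQ total) with edges where |ρ| > 0.20; degree, closeness,
  betweenness and clustering centralities; density, diameter, path length and
  degree-variance summaries; bridge-symptom identification; the
  correlation-stability (CS) coefficient from a 2,500-iteration 10%-dropping
  bootstrap; and a sensitivity re-analysis at threshold 0.25.
* **A calibrated synthetic-cohort generator**: ordinal items from latent
  Gaussian factors with a configurable mediation structure, realistic
  covariate frequencies, planted QC anomalies and missing totals — so every
  stage of the pipeline is testable end-to-end without access to the original
  survey data, and parameter recovery can be verified against ground truth.

The package is aimed at researchers in nursing, occupational health and
psychiatric epidemiology who work with ordinal questionnaire batteries and
want partial-correlation networks and mediation decompositions that are
reproducible down to the seed.

## Worked example

```r
library(nursenet)

cohort <- generate_cohort(seed = 42)     # 1,986 collected questionnaires
qc     <- apply_exclusion_filters(cohort$records)
qc$report
#> Questionnaire QC report
#>   collected: 1986
#>   excluded (missing_gt_5pct): 0
#>   excluded (logical_inconsistency): 102
#>   excluded (multiple_selection): 0
#>   excluded (irrelevant_or_contradictory): 135
#>   valid: 1749 (effective response rate 88.07%)

scored  <- score_instruments(qc$records)
scored  <- impute_total_median(scored, "psqi", verbose = TRUE)
#> imputed 10 missing psqi_total value(s) with median 9
records <- complete_items(qc$records)

spec <- covariate_spec()  # age, marital status, experience, title,
                          # children, night shifts, off days
res_x <- residualize(scored$psqi_total, records, spec)
res_m <- residualize(scored$phq9_total, records, spec)
spearman_partial(res_x, res_m)
#>           rho             p
#>  5.501558e-01 6.057926e-139
```

Sleep quality and depressive symptoms remain strongly rank-correlated
(ρ ≈ 0.55) after adjusting for the seven confounders. The mediation
decomposition shows that the sleep → safety-behavior effect flows almost
entirely through depressive symptoms:

```r
fit_mediation(scored$psqi_total, scored$phq9_total, scored$nsbq_total,
              records, spec, n_boot = 1000, seed = 42)
#> Mediation decomposition (family: gaussian, n = 1749, 1000 bootstrap reps)
#>      path estimate ci_low ci_high       z         p
#>         a    0.840  0.782   0.899  26.947 6.13e-160
#>         b   -0.313 -0.374  -0.249 -10.124  4.31e-24
#>    direct   -0.044 -0.135   0.040  -0.919  3.58e-01
#>  indirect   -0.263 -0.319  -0.208      NA        NA
#>     total   -0.307 -0.385  -0.233  -7.443  9.86e-14
#> additivity gap |total - (direct + indirect)| = 5.55e-17
```

Each extra PSQI point predicts 0.84 more PHQ-9 points (path a); given sleep
quality, each PHQ-9 point predicts 0.31 fewer NSBQ points (path b). The
direct path is null (CI spans 0) while the indirect path a·b ≈ −0.26 carries
the total effect. The item-level symptom network makes the bridge visible:

```r
resid17 <- residualize_network_variables(records, scored, spec)
net <- build_network(pairwise_matrix(resid17), tau = 0.20)
global_metrics(net)
#> Network summary
#>   nodes/edges: 17 / 92
#>   density: 0.676
#>   diameter: 2
#>   average path length: 1.233
#>   average clustering: 0.828
#>   degree variance: 15.322
#>   nodes with clustering > 0.90: 47.1%

cen <- node_centralities(net)
head(cen[order(-cen$degree), ], 3)
#>   node    degree closeness betweenness clustering
#> 1 D_3         15     0.938      0.0447      0.733
#> 2 D_7         15     0.938      0.0447      0.733
#> 3 PSQI_C1     14     0.879      0.0251      0.802

cs_coefficient(net, n_iter = 2500, seed = 42)
#> CS coefficient (node_drop, drop 10%, 2500 iterations, 0 skipped): 0.993
```

D_3 ("insomnia / disturbed sleep") tops the degree and closeness rankings —
the bridge symptom connecting the sleep and depression clusters — and the
degree centralities are highly stable under the dropping bootstrap
(CS ≈ 0.99, far above the 0.5 adequacy bar). `sensitivity_rerank(...)`
repeats the centrality analysis at |ρ| ≥ 0.25, and `plot(net)` or
`export_graphml(net, "net.graphml")` render or export the graph.

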