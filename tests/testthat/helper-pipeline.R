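# Full-pipeline runs on study-calibrated synthetic cohorts are used by
# several acceptance checks; cache them per seed so each cohort is generated
# and analysed once per test session.

.pipeline_cache <- new.env(parent = emptyenv())

study_scale_pipeline <- function(seed, n_boot = 250L) {
  key <- paste0("s", seed, "_b", n_boot)
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  coh <- generate_cohort(seed = seed)
  qc <- apply_exclusion_filters(coh$records)
  scored <- score_instruments(qc$records)
  for (w in c("psqi", "phq9", "nsbq")) scored <- impute_total_median(scored, w)
  rec <- complete_items(qc$records)
  spec <- covariate_spec()
  res_x <- residualize(scored$psqi_total, rec, spec)
  res_m <- residualize(scored$phq9_total, rec, spec)
  res_y <- residualize(scored$nsbq_total, rec, spec)
  med <- fit_mediation(scored$psqi_total, scored$phq9_total, scored$nsbq_total,
                       rec, spec, n_boot = n_boot, seed = seed)
  resn <- residualize_network_variables(rec, scored, spec)
  pc <- pairwise_matrix(resn)
  net <- build_network(pc, tau = 0.20)
  out <- list(cohort = coh, qc = qc, scored = scored, records = rec,
              spec = spec, res_x = res_x, res_m = res_m, res_y = res_y,
              mediation = med, residuals = resn, pcorr = pc, net = net)
  .pipeline_cache[[key]] <- out
  out
}
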