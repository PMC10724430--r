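# End-to-end validation runs shared by the cohort-level tests: simulate a
# cohort of 12 SLE patients (+2 HC), run the full pipeline with the
# consensus counted over the SLE samples, and summarise recovery,
# prediction accuracy and the delta/SLEDAI correlation.

validation_run <- function(seed, slope = 3, noise_sd = 0.2) {
  p <- simulation_params(outcome_link = list(slope = slope, noise_sd = noise_sd),
                         seed = seed)
  co <- simulate_cohort(p, n_per_group = c(HC = 2, aSLE = 6, rSLE = 6))
  out <- run_dnb(co, restrict_to_group = c("aSLE", "rSLE"))
  planted <- planted_truth(co)$module_names
  sle <- out$report$patients$group != "HC"
  pat <- out$report$patients[sle, ]
  rho <- clinical_correlation(
    stats::setNames(pat$delta, pat$patient_id), co$clinical, "SLEDAI")$rho
  list(recovered = length(intersect(out$core$markers, planted)),
       n_correct = sum(pat$prediction == pat$outcome),
       n_sle = nrow(pat),
       rho_sledai = rho)
}

# memoised batches, so several acceptance properties can share one set of
# simulated cohorts
.validation_cache <- new.env(parent = emptyenv())
validation_batch <- function(seeds, slope, noise_sd = 0.2) {
  key <- paste0("s", slope, "_", seeds[1], "_", length(seeds))
  if (is.null(.validation_cache[[key]]))
    .validation_cache[[key]] <- lapply(seeds, validation_run,
                                       slope = slope, noise_sd = noise_sd)
  .validation_cache[[key]]
}
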