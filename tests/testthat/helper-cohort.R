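# Shared synthetic fixtures, built once per test run and cached.
#
# Validation problem sizes (scaled-down relative to a clinical cohort, with
# the default effect sizes): the reference cohort keeps 10 patients with
# the default 8/2 outcome split but 10-14 contacts per patient and 100 s of
# analysed signal; the per-seed end-to-end cohorts use 5-7 contacts and
# 50 s.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

ref_sim_config <- function(seed = 1) {
  sim_config(n_patients = 10, n_responders = 8,
             contacts_per_patient = c(12, 14),
             contacts_per_patient_nonresponder = c(10, 12),
             tc_fraction = 0.3, seed = seed)
}

small_sim_config <- function(seed = 1) {
  sim_config(n_patients = 10, n_responders = 8,
             contacts_per_patient = c(5, 7),
             contacts_per_patient_nonresponder = c(5, 7),
             tc_fraction = 0.3, seed = seed)
}

analyze_cohort_features <- function(cohort, total_s = 100) {
  ft <- dplyr::bind_rows(lapply(cohort$recordings, function(rec) {
    suppressWarnings(
      compute_features(preprocess_recording(rec, cohort$contacts,
                                            total_s = total_s)))
  }))
  ftz <- zscore_within_subject(ft)
  cm <- contact_average(ftz)
  list(features = ftz, contact_means = cm)
}

ref_cohort <- function() {
  memo("ref_cohort", generate_cohort(ref_sim_config(seed = 1)))
}

ref_analysis <- function() {
  memo("ref_analysis", {
    coh <- ref_cohort()
    an <- analyze_cohort_features(coh, total_s = 100)
    an$comparisons <- run_comparisons(an$contact_means, coh$contacts,
                                      coh$outcomes)
    an$delta <- build_delta_samples(an$contact_means, coh$contacts,
                                    coh$outcomes)
    an
  })
}

# run the whole chain (generation -> prediction) for one seed and report
# whether all 10 patient labels are recovered
end_to_end_recovery <- function(seed, total_s = 50) {
  cfg <- small_sim_config(seed = seed)
  coh <- generate_cohort(cfg)
  an <- analyze_cohort_features(coh, total_s = total_s)
  ds <- build_delta_samples(an$contact_means, coh$contacts, coh$outcomes)
  rep <- suppressWarnings(
    run_outcome_prediction(ds, plan = split_plan(seed = seed)))
  pat <- dplyr::left_join(rep$patients, coh$outcomes, by = "patient_id")
  list(all_correct = all(pat$predicted_outcome == pat$outcome),
       report = rep, cohort = coh, delta = ds)
}

# the per-band, per-feature cells in which the generator's defaults encode
# a TC-contact effect (Fig-4a-style pattern: pre-operative TC vs non-TC)
configured_tc_cells <- function() {
  tibble::tribble(
    ~band,        ~feature,
    "filtered",   "ll",
    "high_gamma", "ll",
    "ripple",     "ll",
    "filtered",   "apen",
    "low",        "apen",
    "ripple",     "apen"
  )
}

# cells with configured post-operative shifts on non-TC contacts and the
# expected direction of the pre-minus-post difference
configured_post_cells <- function(group) {
  if (group == "responders") {
    tibble::tribble(
      ~band,        ~feature, ~tail,
      "filtered",   "ll",     "right",
      "low",        "ll",     "right",
      "high_gamma", "ll",     "right",
      "ripple",     "ll",     "right",
      "high_gamma", "apen",   "right",
      "ripple",     "apen",   "right"
    )
  } else {
    tibble::tribble(
      ~band,      ~feature, ~tail,
      "filtered", "ll",     "left",
      "low",      "ll",     "left",
      "ripple",   "ll",     "left",
      "filtered", "apen",   "right",
      "low",      "apen",   "right",
      "ripple",   "apen",   "right"
    )
  }
}
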