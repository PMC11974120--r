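#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis: input source (a
#' simulation configuration or a cohort directory), preprocessing windowing,
#' approximate-entropy parameters, the train/test split plan and the
#' classifier grid. The configuration is serialized into the output
#' directory before any computation so a run can be reproduced from its own
#' output.
#'
#' @param simulate Logical; when `TRUE` the cohort is generated with
#'   [generate_cohort()] from `sim`, otherwise it is read from
#'   `input_dir` (a [write_cohort()] bundle).
#' @param sim Named list of [sim_config()] overrides.
#' @param input_dir Cohort directory when `simulate = FALSE`.
#' @param window_s,total_s Windowing (see [extract_windows()]).
#' @param apen_m,apen_r_factor Entropy parameters (see [apen_params()]).
#' @param test_fraction,subsets_k Split plan (see [split_plan()]).
#' @param folds Cross-validation folds for model selection.
#' @param seed Global seed: drives the simulation (unless `sim$seed` is
#'   given) and the prediction plan.
#' @return List with class `run_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = list(), input_dir = NULL,
                            window_s = 10, total_s = 200,
                            apen_m = 2, apen_r_factor = 0.2,
                            test_fraction = 1 / 6, subsets_k = 5,
                            folds = 25, seed = 1) {
  if (!simulate && is.null(input_dir)) {
    stop("`input_dir` is required when simulate = FALSE")
  }
  structure(list(simulate = simulate, sim = sim, input_dir = input_dir,
                 window_s = window_s, total_s = total_s,
                 apen_m = apen_m, apen_r_factor = apen_r_factor,
                 test_fraction = test_fraction, subsets_k = subsets_k,
                 folds = folds, seed = as.integer(seed)),
            class = "run_config")
}

write_stage_manifest <- function(out_dir, stage, outputs) {
  man <- list(stage = stage, outputs = outputs)
  jsonlite::write_json(man,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

require_stage <- function(out_dir, stage) {
  f <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  if (!file.exists(f)) {
    stop("stage '", stage, "' has not been run in ", out_dir,
         " (missing ", basename(f), ")")
  }
  man <- jsonlite::read_json(f)
  missing <- Filter(function(p) !file.exists(file.path(out_dir, p)),
                    unlist(man$outputs))
  if (length(missing)) {
    stop("stage '", stage, "' outputs missing: ",
         paste(missing, collapse = ", "))
  }
  invisible(man)
}

write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
}

#' Individual pipeline stages
#'
#' Each stage writes its results and a manifest into `out_dir` and refuses
#' to run before the stages it depends on. [run_pipeline()] chains them.
#'
#' `stage_simulate` materializes the cohort metadata (and keeps the
#' recordings in memory); `stage_features` preprocesses every recording and
#' writes the normalized feature table and contact means; `stage_stats`
#' writes the group-comparison table and a text report; `stage_predict`
#' writes delta samples, the cross-validation grid, sensor metrics and the
#' per-patient prediction table.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param cohort A `seeg_cohort` (for `stage_features`).
#' @return The stage's principal result, invisibly where it is a file.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config, out_dir) {
  sim_args <- config$sim
  if (is.null(sim_args$seed)) sim_args$seed <- config$seed
  scfg <- do.call(sim_config, sim_args)
  cohort <- generate_cohort(scfg)
  utils::write.table(cohort$contacts, file.path(out_dir, "contacts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$outcomes, file.path(out_dir, "outcomes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_stage_manifest(out_dir, "simulate",
                       list("contacts.tsv", "outcomes.tsv"))
  cohort
}

#' @rdname pipeline_stages
#' @export
stage_features <- function(config, out_dir, cohort) {
  params <- apen_params(m = config$apen_m, r_factor = config$apen_r_factor)
  ft <- dplyr::bind_rows(lapply(cohort$recordings, function(rec) {
    ws <- preprocess_recording(rec, cohort$contacts,
                               window_s = config$window_s,
                               total_s = config$total_s)
    compute_features(ws, params = params)
  }))
  ft <- zscore_within_subject(ft)
  cm <- contact_average(ft)
  write_table_csv(ft, file.path(out_dir, "features.csv"))
  write_table_csv(cm, file.path(out_dir, "contact_means.csv"))
  write_stage_manifest(out_dir, "features",
                       list("features.csv", "contact_means.csv"))
  list(features = ft, contact_means = cm)
}

read_contact_means <- function(out_dir) {
  cm <- tibble::as_tibble(utils::read.csv(
    file.path(out_dir, "contact_means.csv")))
  attr(cm, "normalized") <- TRUE
  cm
}

read_meta <- function(out_dir) {
  list(contacts = tibble::as_tibble(
         utils::read.delim(file.path(out_dir, "contacts.tsv"))),
       outcomes = tibble::as_tibble(
         utils::read.delim(file.path(out_dir, "outcomes.tsv"))))
}

#' @rdname pipeline_stages
#' @export
stage_stats <- function(config, out_dir) {
  require_stage(out_dir, "simulate")
  require_stage(out_dir, "features")
  meta <- read_meta(out_dir)
  cm <- read_contact_means(out_dir)
  comp <- run_comparisons(cm, meta$contacts, meta$outcomes)
  write_table_csv(comp, file.path(out_dir, "comparisons.csv"))
  rep_lines <- c(
    "Group comparisons (one-tailed, Bonferroni-corrected within each",
    "group x design family of 8 tests; alpha = 0.05)", "",
    utils::capture.output(print(as.data.frame(comp), digits = 4)))
  writeLines(rep_lines, file.path(out_dir, "comparisons.txt"))
  write_stage_manifest(out_dir, "stats",
                       list("comparisons.csv", "comparisons.txt"))
  comp
}

#' @rdname pipeline_stages
#' @export
stage_predict <- function(config, out_dir) {
  require_stage(out_dir, "simulate")
  require_stage(out_dir, "features")
  meta <- read_meta(out_dir)
  cm <- read_contact_means(out_dir)
  samples <- build_delta_samples(cm, meta$contacts, meta$outcomes)
  plan <- split_plan(test_fraction = config$test_fraction,
                     subsets_k = config$subsets_k, seed = config$seed)
  report <- run_outcome_prediction(samples, plan = plan,
                                   folds = config$folds)
  write_table_csv(samples, file.path(out_dir, "delta_samples.csv"))
  write_table_csv(report$selection$cv,
                  file.path(out_dir, "model_selection.csv"))
  write_table_csv(tibble::as_tibble(report$sensor_metrics),
                  file.path(out_dir, "sensor_metrics.csv"))
  patients <- dplyr::left_join(report$patients, meta$outcomes,
                               by = "patient_id")
  write_table_csv(patients, file.path(out_dir, "prediction_patients.csv"))
  txt <- c(
    "Two-level outcome prediction",
    sprintf("  selected subset %d, cost %g, gamma %s",
            report$selection$chosen_subset, report$selection$cost,
            report$selection$gamma),
    sprintf("  sensor level (test): accuracy %.3f precision %.3f recall %.3f F1 %.3f AUC %.3f",
            report$sensor_metrics$accuracy, report$sensor_metrics$precision,
            report$sensor_metrics$recall, report$sensor_metrics$f1,
            report$sensor_metrics$auc),
    "",
    "  Note: the split is contact-level and class-stratified; contacts of",
    "  one patient can appear in both train and test sets, and response",
    "  possibilities are computed over all of a patient's contacts.",
    "",
    utils::capture.output(print(as.data.frame(patients), digits = 3)))
  writeLines(txt, file.path(out_dir, "prediction_report.txt"))
  write_stage_manifest(out_dir, "predict",
                       list("delta_samples.csv", "model_selection.csv",
                            "sensor_metrics.csv", "prediction_patients.csv",
                            "prediction_report.txt"))
  report
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess/features -> group statistics
#' -> outcome prediction, writing all tables, manifests and a run log into
#' `out_dir`. Re-running with the serialized configuration reproduces the
#' tables byte for byte.
#'
#' @param config A [pipeline_config()] or the path to a YAML file with the
#'   same fields.
#' @param out_dir Output directory (created if needed).
#' @return List with `cohort`, `features`, `contact_means`, `comparisons`,
#'   `prediction`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_plain <- unclass(config)
  cfg_plain$input_dir <- if (is.null(config$input_dir)) NULL else
    as.character(config$input_dir)
  yaml::write_yaml(cfg_plain, file.path(out_dir, "run_config.yaml"))

  if (isTRUE(config$simulate)) {
    cohort <- stage_simulate(config, out_dir)
  } else {
    if (!dir.exists(config$input_dir)) {
      stop("input cohort directory not found: ", config$input_dir)
    }
    cohort <- read_cohort(config$input_dir)
    utils::write.table(cohort$contacts, file.path(out_dir, "contacts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cohort$outcomes, file.path(out_dir, "outcomes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_stage_manifest(out_dir, "simulate",
                         list("contacts.tsv", "outcomes.tsv"))
  }
  feats <- stage_features(config, out_dir, cohort)
  comparisons <- stage_stats(config, out_dir)
  prediction <- stage_predict(config, out_dir)
  log <- list(package_version = as.character(utils::packageVersion("seegrftc")),
              seed = config$seed,
              n_recordings = length(cohort$recordings),
              n_contacts = nrow(cohort$contacts))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, features = feats$features,
                 contact_means = feats$contact_means,
                 comparisons = comparisons, prediction = prediction))
}
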