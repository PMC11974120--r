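delta_feature_names <- function() {
  c("ll_filtered", "ll_low", "ll_high_gamma", "ll_ripple",
    "apen_filtered", "apen_low", "apen_high_gamma", "apen_ripple")
}

#' Build contact-level delta samples for outcome prediction
#'
#' One sample per non-TC contact: the 8-dimensional vector of pre-operative
#' minus post-operative contact means (line length and approximate entropy
#' in the four bands, in canonical order), labelled `positive` when the
#' contact belongs to a responder and `negative` otherwise.
#'
#' @param contact_means Normalized contact means from [contact_average()]
#'   (must contain both features and all four bands).
#' @param contacts Contact metadata (`patient_id`, `channel_name`,
#'   `is_tc`).
#' @param outcomes Per-patient outcomes (`patient_id`, `outcome`).
#' @return Tibble with `patient_id`, `channel_name`, `label` (factor,
#'   levels `negative`, `positive`) and the 8 delta feature columns.
#' @export
build_delta_samples <- function(contact_means, contacts, outcomes) {
  fcols <- feature_cols(contact_means)
  if (!setequal(fcols, c("ll", "apen"))) {
    stop("delta samples need both features (ll, apen) in the contact means")
  }
  cm <- dplyr::left_join(contact_means,
                         contacts[, c("patient_id", "channel_name", "is_tc")],
                         by = c("patient_id", "channel_name"))
  cm <- cm[!cm$is_tc, , drop = FALSE]
  long <- tidyr::pivot_longer(cm, dplyr::all_of(c("ll", "apen")),
                              names_to = "feature", values_to = "value")
  wide <- tidyr::pivot_wider(long, names_from = "period",
                             values_from = "value")
  if (!all(c("pre", "post") %in% names(wide))) {
    stop("contact means must contain both periods")
  }
  incomplete <- unique(wide$channel_name[is.na(wide$pre) | is.na(wide$post)])
  if (length(incomplete)) {
    warning("contact(s) missing a period excluded from delta samples: ",
            paste(utils::head(incomplete, 10), collapse = ", "),
            if (length(incomplete) > 10) ", ...")
    wide <- wide[!is.na(wide$pre) & !is.na(wide$post), , drop = FALSE]
  }
  wide$delta <- wide$pre - wide$post
  wide$col <- paste(wide$feature, wide$band, sep = "_")
  samples <- tidyr::pivot_wider(
    wide[, c("patient_id", "channel_name", "col", "delta")],
    names_from = "col", values_from = "delta")
  miss <- setdiff(delta_feature_names(), names(samples))
  if (length(miss)) {
    stop("missing delta feature column(s): ", paste(miss, collapse = ", "))
  }
  samples <- samples[, c("patient_id", "channel_name",
                         delta_feature_names())]
  samples <- dplyr::left_join(samples, outcomes, by = "patient_id")
  samples$label <- factor(
    ifelse(samples$outcome == "responder", "positive", "negative"),
    levels = c("negative", "positive"))
  samples$outcome <- NULL
  samples
}

#' Train/test split plan for contact-level classification
#'
#' @param test_fraction Held-out fraction per class (default 1/6, the
#'   139/834 and 27/163 proportions).
#' @param subsets_k Number of positive-class training subsets used to
#'   balance the classes (default 5).
#' @param seed Integer seed driving the split, the subset partition and
#'   the cross-validation folds.
#' @return List with class `split_plan`.
#' @export
split_plan <- function(test_fraction = 1 / 6, subsets_k = 5, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  if (subsets_k < 1) stop("subsets_k must be >= 1")
  structure(list(test_fraction = test_fraction,
                 subsets_k = as.integer(subsets_k),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Class-stratified random train/test split
#'
#' Draws `round(n * test_fraction)` test samples within each class
#' (rounding to nearest), deterministically under `seed`.
#'
#' @param samples Delta-sample tibble from [build_delta_samples()].
#' @param test_fraction Held-out fraction per class.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return List with `train` and `test` tibbles.
#' @export
split_train_test <- function(samples, test_fraction = 1 / 6, seed = NULL) {
  counts <- table(samples$label)
  if (length(unique(samples$label)) < 2 || any(counts < 2)) {
    stop("both classes must be present with at least 2 samples each")
  }
  impl <- function() {
    test_idx <- integer(0)
    for (cl in levels(samples$label)) {
      idx <- which(samples$label == cl)
      n_test <- round(length(idx) * test_fraction)
      n_test <- max(1L, min(length(idx) - 1L, n_test))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
    list(train = samples[-test_idx, , drop = FALSE],
         test = samples[test_idx, , drop = FALSE])
  }
  if (is.null(seed)) impl() else withr::with_seed(seed, impl())
}

#' Partition training positives into balancing subsets
#'
#' Randomly partitions the positive training samples into `k` disjoint
#' near-equal subsets (sizes differ by at most 1), each comparable in size
#' to the negative training arm.
#'
#' @param train_positives Tibble of positive-class training samples.
#' @param k Number of subsets.
#' @param seed Optional seed.
#' @return List of `k` tibbles.
#' @export
subdivide_positives <- function(train_positives, k = 5, seed = NULL) {
  n <- nrow(train_positives)
  if (n < k) stop("need at least k = ", k, " positive samples")
  impl <- function() {
    perm <- sample.int(n)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    split(perm, rep(seq_len(k), sizes))
  }
  groups <- if (is.null(seed)) impl() else withr::with_seed(seed, impl())
  lapply(groups, function(i) train_positives[sort(i), , drop = FALSE])
}

#' Hyperparameter grid for the RBF-kernel classifier
#'
#' @param cost Regularization values.
#' @param gamma Kernel-scale values; `"auto"` resolves to 1 / n_features.
#' @return Tibble of grid points.
#' @export
svm_grid <- function(cost = c(0.1, 1, 10, 100),
                     gamma = c("auto", 0.01, 0.1, 1)) {
  grid <- expand.grid(cost = cost, gamma = as.character(gamma),
                      stringsAsFactors = FALSE)
  tibble::as_tibble(grid)
}

resolve_gamma <- function(gamma, n_features) {
  if (identical(gamma, "auto")) 1 / n_features else as.numeric(gamma)
}

sample_matrix <- function(samples) {
  as.matrix(samples[, delta_feature_names(), drop = FALSE])
}

fit_svm <- function(train, cost, gamma) {
  e1071::svm(x = sample_matrix(train), y = train$label, kernel = "radial",
             cost = cost, gamma = resolve_gamma(gamma, length(delta_feature_names())),
             scale = FALSE)
}

# decision scores oriented so that larger means more "positive"
decision_scores <- function(model, samples) {
  pr <- stats::predict(model, sample_matrix(samples), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- dv[, 1]
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (first != "positive") s <- -s
  unname(s)
}

#' Area under the ROC curve from continuous scores
#'
#' Rank (Mann-Whitney) form of the AUC with midrank tie handling:
#' the probability that a random positive scores above a random negative.
#'
#' @param scores Numeric decision scores (larger = more positive).
#' @param labels Factor or character with `"positive"` / `"negative"`.
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(scores, labels) {
  pos <- labels == "positive"
  np <- sum(pos)
  nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("AUC undefined: one class is empty")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification metrics with responder contacts as the positive class
#'
#' @param truth,predicted Factors/characters in `"positive"`/`"negative"`.
#' @param scores Optional continuous scores for the AUC.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1` and (when
#'   scores are given) `auc`.
#' @export
classification_metrics <- function(truth, predicted, scores = NULL) {
  tp <- sum(predicted == "positive" & truth == "positive")
  fp <- sum(predicted == "positive" & truth == "negative")
  fn <- sum(predicted == "negative" & truth == "positive")
  tn <- sum(predicted == "negative" & truth == "negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  out <- list(accuracy = (tp + tn) / length(truth),
              precision = precision, recall = recall, f1 = f1)
  if (!is.null(scores)) out$auc <- auc_from_scores(scores, truth)
  out
}

#' Select the balancing subset and hyperparameters by cross-validated AUC
#'
#' Each positive training subset is combined with the full negative
#' training arm and evaluated over the hyperparameter grid by stratified
#' k-fold cross-validation (25 folds by default; reduced with a warning
#' when the smaller class has fewer samples than folds). The cell with the
#' highest mean validation AUC wins; ties break to the smallest subset
#' index, then smallest cost, then smallest kernel scale.
#'
#' @param subsets List of positive-sample tibbles from
#'   [subdivide_positives()].
#' @param train_negatives Tibble of negative training samples.
#' @param grid Hyperparameter grid from [svm_grid()].
#' @param folds Number of cross-validation folds.
#' @param seed Optional seed for fold assignment.
#' @return List with class `model_selection`: `chosen_subset`, `cost`,
#'   `gamma` (as given) , `gamma_value` (resolved), `cv` (per-cell mean
#'   AUC table), `folds_used`.
#' @export
select_model <- function(subsets, train_negatives, grid = svm_grid(),
                         folds = 25, seed = NULL) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  impl <- function() {
    cells <- list()
    for (si in seq_along(subsets)) {
      dat <- dplyr::bind_rows(subsets[[si]], train_negatives)
      counts <- table(dat$label)
      k <- min(folds, min(counts))
      if (k < folds) {
        warning("reducing folds from ", folds, " to ", k,
                " (smallest class has ", min(counts), " samples)")
      }
      if (k < 2) stop("cannot cross-validate with fewer than 2 folds")
      fold_id <- integer(nrow(dat))
      for (cl in levels(dat$label)) {
        idx <- which(dat$label == cl)
        fold_id[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      for (gi in seq_len(nrow(grid))) {
        aucs <- numeric(0)
        accs <- numeric(0)
        for (f in seq_len(k)) {
          tr <- dat[fold_id != f, , drop = FALSE]
          va <- dat[fold_id == f, , drop = FALSE]
          if (length(unique(va$label)) < 2 ||
              length(unique(tr$label)) < 2) next
          fit <- fit_svm(tr, grid$cost[gi], grid$gamma[gi])
          aucs <- c(aucs, auc_from_scores(decision_scores(fit, va),
                                          va$label))
          accs <- c(accs, mean(stats::predict(fit, sample_matrix(va)) ==
                                 va$label))
        }
        cells[[length(cells) + 1L]] <- tibble::tibble(
          subset = si, cost = grid$cost[gi], gamma = grid$gamma[gi],
          mean_auc = mean(aucs), mean_acc = mean(accs),
          n_folds = length(aucs))
      }
    }
    cv <- dplyr::bind_rows(cells)
    best_auc <- max(cv$mean_auc)
    cand <- cv[cv$mean_auc >= best_auc - 1e-12, , drop = FALSE]
    # AUC is rank-based and ties at 1 on separable data, where the most
    # regularized grid cells can still degenerate to one-class prediction;
    # mean CV accuracy breaks AUC ties before the deterministic ordering.
    best_acc <- max(cand$mean_acc)
    cand <- cand[cand$mean_acc >= best_acc - 1e-12, , drop = FALSE]
    gval <- vapply(cand$gamma, resolve_gamma, numeric(1),
                   n_features = length(delta_feature_names()))
    cand <- cand[order(cand$subset, cand$cost, gval), , drop = FALSE]
    sel <- cand[1, ]
    structure(list(chosen_subset = sel$subset, cost = sel$cost,
                   gamma = sel$gamma,
                   gamma_value = resolve_gamma(sel$gamma,
                                               length(delta_feature_names())),
                   cv = cv, folds_used = folds),
              class = "model_selection")
  }
  if (is.null(seed)) impl() else withr::with_seed(seed, impl())
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> subset %d, cost %g, gamma %s (mean CV AUC %.3f)\n",
              x$chosen_subset, x$cost, x$gamma,
              max(x$cv$mean_auc)))
  invisible(x)
}

#' Fit the final contact-level classifier
#'
#' Retrains the RBF-kernel classifier on the selected positive subset
#' combined with the negative training arm.
#'
#' @param selection A `model_selection` from [select_model()].
#' @param subsets,train_negatives As passed to [select_model()].
#' @return A fitted `svm` model.
#' @export
fit_final_model <- function(selection, subsets, train_negatives) {
  dat <- dplyr::bind_rows(subsets[[selection$chosen_subset]],
                          train_negatives)
  fit_svm(dat, selection$cost, selection$gamma)
}

#' Sensor-level evaluation on the held-out test set
#'
#' @param model Fitted classifier.
#' @param test Test-sample tibble (both classes present).
#' @return Named list of metrics (accuracy, precision, recall, f1, auc).
#' @export
evaluate_sensor_level <- function(model, test) {
  if (length(unique(test$label)) < 2) {
    stop("test set contains a single class; AUC undefined")
  }
  pred <- stats::predict(model, sample_matrix(test))
  classification_metrics(test$label, pred,
                         scores = decision_scores(model, test))
}

#' Response possibility of one patient
#'
#' The intra-individual fraction of a patient's (non-TC) contacts whose
#' delta-feature vector the classifier labels positive.
#'
#' @param model Fitted classifier.
#' @param patient_samples Delta samples of a single patient (>= 1 row).
#' @return Proportion in \[0, 1\].
#' @export
response_possibility <- function(model, patient_samples) {
  if (!nrow(patient_samples)) stop("patient has no delta samples")
  pred <- stats::predict(model, sample_matrix(patient_samples))
  mean(pred == "positive")
}

#' Individual-level decision rule
#'
#' A patient is predicted a responder when their response possibility
#' strictly exceeds the threshold ("over 50%"); a possibility of exactly
#' the threshold yields `non_responder`.
#'
#' @param possibility Numeric vector of response possibilities in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return Character vector of `"responder"` / `"non_responder"`.
#' @export
#' @examples
#' decide_outcome(c(0.963, 0.05, 0.5))
decide_outcome <- function(possibility, threshold = 0.5) {
  ifelse(possibility > threshold, "responder", "non_responder")
}

#' Individual-level outcome prediction
#'
#' Computes each patient's response possibility over all of their delta
#' samples and predicts `responder` when it strictly exceeds the
#' threshold (a possibility of exactly 0.5 is a non-responder).
#'
#' @param model Fitted classifier.
#' @param samples Delta samples of all patients (train and test; the
#'   possibility is defined over every non-TC contact of the patient).
#' @param threshold Decision threshold on the possibility (default 0.5).
#' @return Tibble with `patient_id`, `n_contacts`, `response_possibility`,
#'   `predicted_outcome`.
#' @export
predict_individuals <- function(model, samples, threshold = 0.5) {
  pids <- unique(samples$patient_id)
  poss <- vapply(pids, function(p) {
    response_possibility(model, samples[samples$patient_id == p, ,
                                        drop = FALSE])
  }, numeric(1))
  tibble::tibble(
    patient_id = pids,
    n_contacts = as.integer(table(samples$patient_id)[pids]),
    response_possibility = unname(poss),
    predicted_outcome = decide_outcome(unname(poss), threshold))
}

#' Run the full two-level outcome prediction procedure
#'
#' Splits the delta samples (class-stratified), partitions the training
#' positives into balancing subsets, selects subset and hyperparameters by
#' cross-validated AUC, retrains on the winning combination, and reports
#' sensor-level test metrics plus per-patient response possibilities and
#' predicted outcomes.
#'
#' @param samples Delta samples from [build_delta_samples()].
#' @param plan A [split_plan()].
#' @param grid Hyperparameter grid.
#' @param folds Cross-validation folds.
#' @return List with class `prediction_report`: `sensor_metrics`,
#'   `patients`, `selection`, `model`, `split`, `plan`.
#' @export
run_outcome_prediction <- function(samples, plan = split_plan(),
                                   grid = svm_grid(), folds = 25) {
  withr::with_seed(plan$seed, {
    split <- split_train_test(samples, test_fraction = plan$test_fraction)
    train_pos <- split$train[split$train$label == "positive", , drop = FALSE]
    train_neg <- split$train[split$train$label == "negative", , drop = FALSE]
    subsets <- subdivide_positives(train_pos, k = plan$subsets_k)
    selection <- select_model(subsets, train_neg, grid = grid, folds = folds)
    model <- fit_final_model(selection, subsets, train_neg)
    metrics <- evaluate_sensor_level(model, split$test)
    patients <- predict_individuals(model, samples)
    structure(list(sensor_metrics = metrics, patients = patients,
                   selection = selection, model = model, split = split,
                   plan = plan),
              class = "prediction_report")
  })
}

#' @export
print.prediction_report <- function(x, ...) {
  m <- x$sensor_metrics
  cat("<prediction_report>\n")
  cat(sprintf("  sensor level (test): accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f, AUC %.3f\n",
              m$accuracy, m$precision, m$recall, m$f1, m$auc))
  cat(sprintf("  individual level: %d/%d predicted responder\n",
              sum(x$patients$predicted_outcome == "responder"),
              nrow(x$patients)))
  invisible(x)
}
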