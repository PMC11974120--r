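fake_contact_means <- function() {
  grid <- tidyr::expand_grid(
    patient_id = c("P01", "P02"),
    channel_name = c("A1", "A2", "A3"),
    period = c("pre", "post"),
    band = band_names())
  grid$ll <- 1
  grid$apen <- 1
  grid$ll[grid$period == "pre" & grid$band == "filtered" &
            grid$channel_name == "A2"] <- 1.0
  grid$ll[grid$period == "post" & grid$band == "filtered" &
            grid$channel_name == "A2"] <- 0.4
  # TC contact A1 has no post rows
  grid <- grid[!(grid$channel_name == "A1" & grid$period == "post"), ]
  attr(grid, "normalized") <- TRUE
  contacts <- tidyr::expand_grid(patient_id = c("P01", "P02"),
                                 channel_name = c("A1", "A2", "A3"))
  contacts$electrode <- "A"
  contacts$contact_index <- rep(1:3, 2)
  contacts$is_tc <- contacts$channel_name == "A1"
  outcomes <- tibble::tibble(patient_id = c("P01", "P02"),
                             outcome = c("responder", "non_responder"))
  list(cm = grid, contacts = contacts, outcomes = outcomes)
}

test_that("delta samples are pre-minus-post vectors of non-TC contacts", {
  fx <- fake_contact_means()
  ds <- build_delta_samples(fx$cm, fx$contacts, fx$outcomes)
  expect_equal(nrow(ds), 4)  # 2 patients x 2 non-TC contacts
  expect_false("A1" %in% ds$channel_name)
  expect_named(ds, c("patient_id", "channel_name", delta_feature_names(),
                     "label"))
  expect_equal(ds$ll_filtered[ds$patient_id == "P01" &
                                ds$channel_name == "A2"], 0.6)
  expect_equal(ds$apen_low[ds$channel_name == "A3"], c(0, 0))
  expect_equal(as.character(ds$label[ds$patient_id == "P01"]),
               c("positive", "positive"))
  expect_equal(as.character(ds$label[ds$patient_id == "P02"]),
               c("negative", "negative"))
})

fake_samples <- function(n_pos, n_neg, sd = 1, gap = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    feats <- matrix(rnorm(n * 8, sd = sd), n, 8)
    feats[seq_len(n_pos), ] <- feats[seq_len(n_pos), ] + gap
    out <- tibble::as_tibble(as.data.frame(feats))
    names(out) <- delta_feature_names()
    out$patient_id <- rep(c("P01", "P02"), length.out = n)
    out$channel_name <- paste0("C", seq_len(n))
    out$label <- factor(rep(c("positive", "negative"), c(n_pos, n_neg)),
                        levels = c("negative", "positive"))
    out[, c("patient_id", "channel_name", delta_feature_names(), "label")]
  })
}

test_that("the class-stratified split reproduces the printed counts", {
  samples <- fake_samples(834, 163)
  sp <- split_train_test(samples, test_fraction = 1 / 6, seed = 1)
  expect_equal(sum(sp$test$label == "positive"), 139)
  expect_equal(sum(sp$test$label == "negative"), 27)
  expect_equal(sum(sp$train$label == "positive"), 695)
  expect_equal(sum(sp$train$label == "negative"), 136)
  expect_equal(nrow(sp$train) + nrow(sp$test), 997)
  # no sample in both partitions
  expect_length(intersect(sp$train$channel_name, sp$test$channel_name), 0)
  # deterministic under seed
  sp2 <- split_train_test(samples, test_fraction = 1 / 6, seed = 1)
  expect_identical(sp, sp2)

  even <- fake_samples(10, 10)
  spe <- split_train_test(even, test_fraction = 0.5, seed = 2)
  expect_equal(sum(spe$test$label == "positive"), 5)
  expect_equal(sum(spe$test$label == "negative"), 5)

  expect_error(split_train_test(fake_samples(5, 0)), "both classes")
})

test_that("positive subsets form a near-equal random partition", {
  pos <- fake_samples(695, 5)
  pos <- pos[pos$label == "positive", ]
  subs <- subdivide_positives(pos, k = 5, seed = 3)
  expect_equal(unname(vapply(subs, nrow, integer(1))), rep(139L, 5))
  expect_setequal(unlist(lapply(subs, function(s) s$channel_name)),
                  pos$channel_name)

  small <- fake_samples(7, 2)
  small <- small[small$label == "positive", ]
  subs2 <- subdivide_positives(small, k = 5, seed = 1)
  expect_equal(sort(unname(vapply(subs2, nrow, integer(1)))),
               c(1L, 1L, 1L, 2L, 2L))

  expect_identical(subdivide_positives(small, k = 1, seed = 1)[[1]], small)
  expect_error(subdivide_positives(small[1:3, ], k = 5), "at least k")
})

test_that("model selection maximizes CV AUC with deterministic tie-breaks", {
  # widely separated classes: every cell reaches AUC 1
  samples <- fake_samples(50, 20, sd = 0.3, gap = 6, seed = 4)
  pos <- samples[samples$label == "positive", ]
  neg <- samples[samples$label == "negative", ]
  subs <- subdivide_positives(pos, k = 2, seed = 5)
  sel <- suppressWarnings(
    select_model(subs, neg, folds = 5, seed = 6))
  expect_equal(max(sel$cv$mean_auc), 1)
  expect_true(all(sel$cv$mean_auc == 1))
  sel2 <- suppressWarnings(select_model(subs, neg, folds = 5, seed = 6))
  expect_identical(sel[c("chosen_subset", "cost", "gamma")],
                   sel2[c("chosen_subset", "cost", "gamma")])
  # the chosen cell attains the maximum
  chosen <- sel$cv[sel$cv$subset == sel$chosen_subset &
                     sel$cv$cost == sel$cost & sel$cv$gamma == sel$gamma, ]
  expect_equal(chosen$mean_auc, max(sel$cv$mean_auc))
  expect_error(select_model(subs, neg, grid = svm_grid(cost = numeric(0),
                                                       gamma = numeric(0))),
               "empty")
})

test_that("shuffled labels drive cross-validated AUC to chance", {
  set.seed(8)
  aucs <- numeric(4)
  for (i in seq_len(4)) {
    samples <- fake_samples(40, 20, sd = 1, gap = 0, seed = 100 + i)
    pos <- samples[samples$label == "positive", ]
    neg <- samples[samples$label == "negative", ]
    sel <- suppressWarnings(
      select_model(list(pos), neg, grid = svm_grid(cost = 1, gamma = 0.1),
                   folds = 5, seed = i))
    aucs[i] <- max(sel$cv$mean_auc)
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})

test_that("classification metrics match hand arithmetic", {
  truth <- c(rep("positive", 4), rep("negative", 6))
  pred <- c("positive", "positive", "positive", "negative",
            "positive", rep("negative", 5))
  # TP 3, FP 1, FN 1, TN 5
  m <- classification_metrics(truth, pred)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)

  m2 <- classification_metrics(truth, truth, scores = c(rep(1, 4), rep(0, 6)))
  expect_equal(m2$accuracy, 1)
  expect_equal(m2$auc, 1)
})

test_that("AUC equals the scaled Mann-Whitney statistic", {
  set.seed(10)
  for (i in 1:8) {
    np <- sample(5:30, 1)
    nn <- sample(5:30, 1)
    scores <- c(rnorm(np, 0.5), rnorm(nn))
    if (i %% 2 == 0) scores <- round(scores, 1)  # induce ties
    labels <- rep(c("positive", "negative"), c(np, nn))
    u <- suppressWarnings(
      stats::wilcox.test(scores[seq_len(np)],
                         scores[np + seq_len(nn)])$statistic)
    expect_equal(auc_from_scores(scores, labels), unname(u) / (np * nn))
  }
  expect_error(auc_from_scores(1:3, rep("positive", 3)), "one class")
})

test_that("the strict decision rule reproduces the worked example", {
  poss <- c(0.963, 0.857, 0.143, 0.96, 0.696, 1, 0.615, 1, 0.05, 0.875)
  dec <- decide_outcome(poss)
  expect_equal(sum(dec == "responder"), 8)
  expect_equal(sum(dec == "non_responder"), 2)
  expect_equal(dec[c(3, 9)], c("non_responder", "non_responder"))
  expect_equal(decide_outcome(0.5), "non_responder")
  expect_equal(decide_outcome(0.5 + 1e-9), "responder")
})

test_that("response possibility is the fraction of positive contacts", {
  samples <- fake_samples(40, 20, sd = 0.3, gap = 6, seed = 11)
  pos <- samples[samples$label == "positive", ]
  neg <- samples[samples$label == "negative", ]
  model <- suppressWarnings(
    fit_final_model(select_model(list(pos), neg,
                                 grid = svm_grid(cost = 10, gamma = 0.1),
                                 folds = 5, seed = 1),
                    list(pos), neg))
  one_pos <- pos[1:10, ]
  expect_equal(response_possibility(model, one_pos), 1)
  mixed <- dplyr::bind_rows(pos[1:7, ], neg[1:3, ])
  expect_equal(response_possibility(model, mixed), 0.7)
  expect_error(response_possibility(model, pos[0, ]), "no delta samples")
  ind <- predict_individuals(model, samples)
  expect_true(all(ind$response_possibility >= 0 &
                    ind$response_possibility <= 1))
  expect_equal(ind$predicted_outcome,
               decide_outcome(ind$response_possibility))
})

test_that("the full prediction procedure is reproducible and accurate on the reference cohort", {
  an <- ref_analysis()
  coh <- ref_cohort()
  rep1 <- suppressWarnings(
    run_outcome_prediction(an$delta, plan = split_plan(seed = 5)))
  rep2 <- suppressWarnings(
    run_outcome_prediction(an$delta, plan = split_plan(seed = 5)))
  expect_identical(rep1$patients, rep2$patients)
  expect_identical(rep1$sensor_metrics, rep2$sensor_metrics)
  expect_identical(rep1$selection$cv, rep2$selection$cv)

  pat <- dplyr::left_join(rep1$patients, coh$outcomes, by = "patient_id")
  expect_equal(pat$predicted_outcome, pat$outcome)
  expect_gte(rep1$sensor_metrics$auc, 0.9)
  expect_gte(max(rep1$selection$cv$mean_auc), 0.9)
})
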