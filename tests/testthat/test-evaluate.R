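# Evaluation protocol: metrics, cross-validation machinery, feature
# selection and ablation plumbing.

test_that("AUROC handles separation, ties, and enumerated pairs", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # two case-control pairs: one concordant, one discordant
  expect_equal(auroc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), class = "cicuboost_metric_error")
})

test_that("AUROC equals the O(n^2) pair-enumeration oracle on random sets", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(5:120, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(auroc(scores, labels), auroc_pairs(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("predictive values reproduce Bayes-theorem algebra and limits", {
  pv <- predictive_values(0.9, 0.65, 1 / 6)
  expect_equal(pv$ppv, 0.9 / 6 / (0.9 / 6 + 0.35 * 5 / 6), tolerance = 1e-12)
  # no positives exist -> NPV = 1
  expect_equal(predictive_values(0.9, 0.65, 0)$npv, 1)
  # uninformative test (sens = 1 - spec): PPV -> prevalence, NPV -> 1 - prev
  for (p in c(0.1, 0.3, 0.7)) {
    pv <- predictive_values(0.4, 0.6, p)
    expect_equal(pv$ppv, p, tolerance = 1e-12)
    expect_equal(pv$npv, 1 - p, tolerance = 1e-12)
  }
  expect_error(predictive_values(1.2, 0.5, 0.5),
               class = "cicuboost_validation_error")
})

test_that("confusion summaries satisfy the rate identities", {
  set.seed(14)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.3)
  cm <- confusion_summary(scores, labels, 0.5)
  expect_identical(cm$TP + cm$FN, sum(labels == 1))
  expect_identical(cm$TN + cm$FP, sum(labels == 0))
  expect_equal(cm$sensitivity, cm$TP / (cm$TP + cm$FN))
  expect_equal(cm$specificity, cm$TN / (cm$TN + cm$FP))
})

test_that("fold assignment is stratified and demands enough cases", {
  set.seed(15)
  y <- c(rep(1, 10), rep(0, 40))
  f <- cicuboost:::stratified_folds(y, 5)
  for (k in 1:5) {
    expect_identical(sum(y == 1 & f == k), 2L)
    expect_identical(sum(y == 0 & f == k), 8L)
  }
  expect_error(cicuboost:::stratified_folds(c(1, 1, 0, 0, 0, 0, 0), 5),
               class = "cicuboost_validation_error")
})

test_that("the experiment protocol is deterministic given cohort and seed", {
  coh <- shared_cohort()
  e1 <- run_experiment(coh, lead_hours = c(13, 1), n_replicates = 1,
                       baselines = FALSE, seed = 5)
  e2 <- run_experiment(coh, lead_hours = c(13, 1), n_replicates = 1,
                       baselines = FALSE, seed = 5)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  e3 <- run_experiment(coh, lead_hours = c(13, 1), n_replicates = 1,
                       baselines = FALSE, seed = 6)
  expect_false(identical(as.data.frame(e1)$auroc, as.data.frame(e3)$auroc))
})

test_that("nothing measured on held-out subjects influences the fitted
           model (no leakage)", {
  coh <- shared_cohort()
  labels <- cicuboost:::subject_labels(coh)
  ids <- names(labels)
  test_ids <- c(ids[labels == 1][1:3], ids[labels == 0][1:9])
  train <- cicuboost:::cohort_subset(coh, setdiff(ids, test_ids))
  fit_once <- function(cohort_train) {
    norm <- baseline_normalize(cohort_train)
    scheme <- fit_discretization(norm)
    store <- encode_predicates(norm, scheme)
    fit_stacked(store)
  }
  f1 <- fit_once(train)
  # perturb the held-out subjects wildly; the training-side fit is unmoved
  pert <- coh
  sel <- pert$subject_id %in% test_ids
  pert$value[sel] <- pert$value[sel] * 10 + 100
  f2 <- fit_once(cicuboost:::cohort_subset(pert, setdiff(ids, test_ids)))
  p1 <- file.path(tempdir(), "m1.json"); p2 <- file.path(tempdir(), "m2.json")
  write_model(f1, p1); write_model(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
  unlink(c(p1, p2))
})

test_that("lead-time summaries aggregate fold AUROCs as mean and
           within-replicate SD", {
  df <- data.frame(model = "stacked_fgb",
                   replicate = rep(1:2, each = 2),
                   fold = rep(1:2, 2), lead_h = 1,
                   auroc = c(0.6, 0.8, 0.5, 0.9))
  ev <- structure(df, class = c("lead_time_eval", "data.frame"))
  s <- summary(ev)
  expect_equal(s$mean_auroc, 0.7)
  expect_equal(s$sd_auroc, mean(c(sd(c(0.6, 0.8)), sd(c(0.5, 0.9)))))
})

test_that("feature selection clips k with a warning and returns every
           feature at k = total", {
  coh <- shared_cohort()
  expect_warning(sel <- select_features(coh, k = 50), "clipped")
  expect_setequal(sel, intersect(cicu_features(), unique(coh$feature)))
})

test_that("the default ablation grid carries the seven reported feature
           groups and a whole-vocabulary group reproduces the headline run", {
  groups <- ablation_feature_groups()
  expect_length(groups, 7)
  expect_setequal(groups[["HR+DBP+VIS+urine_output"]],
                  c("HR", "DBP", "VIS", "urine_output"))
  coh <- shared_cohort()
  ev_all <- run_experiment(coh, lead_hours = 1, n_replicates = 1,
                           baselines = FALSE, seed = 8)
  ab <- ablation(coh, groups = list(all = cicu_features()),
                 lead_hours = 1, n_replicates = 1, seed = 8)
  expect_equal(ab$mean_auroc, summary(ev_all)$mean_auroc, tolerance = 1e-12)
  expect_error(ablation(coh, groups = list(bad = c("HR", "pH"))),
               class = "cicuboost_vocab_error")
})
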