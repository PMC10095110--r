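# Forward imputation, baseline normalization, discretization, and the
# predicate encoding.

test_that("forward imputation carries the latest-not-after value", {
  facts <- data.frame(feature = "HR", time_h = 1, value = 7.4)
  expect_equal(forward_impute(facts, "HR", 3), 7.4)
  expect_true(is.na(forward_impute(facts, "HR", 0.5)))
  facts2 <- data.frame(feature = "HR", time_h = c(1, 2), value = c(100, 110))
  expect_equal(forward_impute(facts2, "HR", 2), 110)
  expect_error(forward_impute(facts, "pH", 1), class = "cicuboost_vocab_error")
  expect_error(forward_impute(facts, "HR", -1),
               class = "cicuboost_validation_error")
})

test_that("baseline normalization subtracts the first-4-h mean for the five
           normalized channels only", {
  coh <- make_cohort(
    subject_id = rep("s1", 6),
    label = "control",
    time_h = c(0, 2, 10, 0, 1, 12),
    feature = c("HR", "HR", "HR", "anion_gap", "anion_gap", "anion_gap"),
    value = c(100, 110, 120, 8, 9, 10),
    window_hours = 48)
  norm <- baseline_normalize(coh)
  hr <- norm$value[norm$feature == "HR"]
  expect_equal(hr, c(-5, 5, 15))          # baseline mean 105
  expect_equal(norm$value[norm$feature == "anion_gap"], c(8, 9, 10))
})

test_that("constant series normalizes to zero; re-normalization shifts by the
           new baseline mean", {
  coh <- make_cohort("s1", "control", c(0, 1, 2, 20), "HR",
                     c(120, 120, 120, 120), window_hours = 48)
  norm <- baseline_normalize(coh)
  expect_true(all(norm$value == 0))
  # algebraic identity: normalizing twice shifts by the normalized baseline
  # mean (zero here), so it is idempotent exactly when that mean is zero
  norm2 <- baseline_normalize(norm)
  expect_equal(norm2$value, norm$value)
})

test_that("subjects lacking a baseline are flagged and passed through", {
  coh <- make_cohort("s1", "control", c(10, 12), "DBP", c(50, 52),
                     window_hours = 48)
  norm <- baseline_normalize(coh)
  expect_equal(norm$value, c(50, 52))
  flagged <- attr(norm, "unnormalized")
  expect_identical(flagged$subject_id, "s1")
  expect_identical(flagged$feature, "DBP")
})

test_that("tertile discretization matches brute-force quantiles", {
  coh <- make_cohort(paste0("s", 1:9), "control", rep(1, 9), "HR", 1:9,
                     window_hours = 48)
  scheme <- fit_discretization(coh, "HR")
  expect_equal(scheme$cuts$HR, unname(quantile(1:9, c(1 / 3, 2 / 3))))
  expect_identical(cicuboost:::assign_bins(scheme, "HR", c(2, 5, 8)),
                   c("low", "mid", "high"))
  # values outside the training range still map to a bin
  expect_identical(cicuboost:::assign_bins(scheme, "HR", -100), "low")
  expect_identical(cicuboost:::assign_bins(scheme, "HR", 1e6), "high")
})

test_that("degenerate features fall back to a single bin with a warning", {
  coh <- make_cohort(paste0("s", 1:5), "control", rep(1, 5), "FiO2",
                     rep(0.21, 5), window_hours = 48)
  expect_warning(scheme <- fit_discretization(coh, "FiO2"),
                 "single bin")
  expect_null(scheme$cuts$FiO2)
  expect_identical(cicuboost:::assign_bins(scheme, "FiO2", c(0.1, 0.9)),
                   c("mid", "mid"))
})

test_that("zero-inflated features keep informative bins", {
  coh <- make_cohort(paste0("s", 1:10), "control", rep(1, 10), "VIS",
                     c(rep(0, 7), 2.5, 5, 10), window_hours = 48)
  scheme <- fit_discretization(coh, "VIS")
  expect_identical(cicuboost:::assign_bins(scheme, "VIS", c(0, 2.5, 10)),
                   c("low", "mid", "high"))
})

test_that("predicate encoding emits 16 facts per fully observed feature,
           4 per tranche, and preserves missingness", {
  coh <- make_cohort(
    subject_id = rep("s1", 49),
    label = "arrest",
    time_h = 0:48, feature = "HR", value = rnorm(49, 120, 5),
    window_hours = 48)
  scheme <- fit_discretization(coh, "HR")
  store <- encode_predicates(coh, scheme)
  expect_identical(nrow(store$facts), 16L)
  expect_identical(as.integer(table(store$facts$tranche)), rep(4L, 4))
  expect_setequal(store$facts$offset, 1:16)
  # no anion gap observations -> no anion gap facts
  scheme2 <- suppressWarnings(fit_discretization(coh, c("HR", "anion_gap")))
  store2 <- encode_predicates(coh, scheme2)
  expect_identical(sum(store2$facts$feature == "anion_gap"), 0L)
})

test_that("a single lab draw carries forward but never backward", {
  # anchor 48; a draw at hour 38 = offset 10
  coh <- make_cohort(
    subject_id = c(rep("s1", 9), "s1"),
    label = "arrest",
    time_h = c(1:9, 38), feature = c(rep("HR", 9), "anion_gap"),
    value = c(rnorm(9, 120, 10), 12),
    window_hours = 48)
  scheme <- suppressWarnings(fit_discretization(coh, c("HR", "anion_gap")))
  ag <- encode_predicates(coh, scheme)$facts
  ag <- ag[ag$feature == "anion_gap", ]
  expect_setequal(ag$offset, 1:10)
})

test_that("every emitted fact is reachable from a raw observation by
           carry-forward (nothing fabricated)", {
  coh <- shared_cohort()
  norm <- baseline_normalize(coh)
  scheme <- fit_discretization(norm)
  store <- encode_predicates(norm, scheme)
  anchors <- cicuboost:::subject_anchors(norm)
  set.seed(2)
  some <- store$facts[sample(nrow(store$facts), 200), ]
  for (i in seq_len(nrow(some))) {
    f <- some[i, ]
    sub <- norm[norm$subject_id == f$subject_id & norm$feature == f$feature, ]
    # the encoding floors timestamps onto the hourly grid, so the fact at
    # offset o summarizes carry-forward as of the end of that charting hour
    v <- forward_impute(sub, f$feature,
                        anchors[[f$subject_id]] - f$offset + 1 - 1e-9)
    expect_false(is.na(v))
    expect_identical(cicuboost:::assign_bins(scheme, f$feature, v), f$bin)
  }
})

test_that("predicate stores export as flat CSV with a JSON scheme sidecar", {
  coh <- shared_cohort()
  norm <- baseline_normalize(coh)
  store <- encode_predicates(norm, fit_discretization(norm))
  path <- file.path(tempdir(), "facts.csv")
  write_predicates(store, path)
  back <- read.csv(path)
  expect_identical(nrow(back), nrow(store$facts))
  expect_true(all(c("subject_id", "feature", "tranche", "offset", "bin",
                    "label") %in% names(back)))
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_identical(side$tranche_hours, 4L)
  expect_true("HR" %in% names(side$cuts))
  unlink(c(path, sub("\\.csv$", ".json", path)))
})

test_that("tranche length must divide the modelling window", {
  coh <- shared_cohort()
  scheme <- fit_discretization(baseline_normalize(coh))
  expect_error(encode_predicates(coh, scheme, tranche_hours = 5),
               class = "cicuboost_config_error")
})
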