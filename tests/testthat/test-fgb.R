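# The boosting engine: gradients, tree induction, and the equivalence with
# a hand-coded propositional oracle.

test_that("functional gradient is label minus sigmoid(psi)", {
  expect_equal(functional_gradient(1, 0), 0.5)
  expect_equal(functional_gradient(0, 0), -0.5)
  expect_equal(functional_gradient(0, 50), -1, tolerance = 1e-12)
  expect_equal(functional_gradient(1, 50), 0, tolerance = 1e-12)
})

test_that("depth-0 trees are stumps at the mean gradient", {
  M <- matrix(c(TRUE, FALSE, TRUE, FALSE), 4, 1)
  tr <- fit_tree(M, c(0.5, -0.5, 0.3, -0.3), candidates = 1L, depth = 0)
  expect_null(tr$test)
  expect_equal(tr$value, 0)
})

test_that("a separating test is found and zeroes the training SSE", {
  M <- matrix(c(TRUE, FALSE), 2, 1)
  tr <- fit_tree(M, c(0.5, -0.5), candidates = 1L, depth = 2, min_leaf = 1)
  expect_identical(tr$test, 1L)
  expect_equal(tr$left$value, 0.5)
  expect_equal(tr$right$value, -0.5)
})

test_that("equal gradients give a stump regardless of candidates", {
  set.seed(3)
  M <- matrix(sample(c(TRUE, FALSE), 40, replace = TRUE), 8, 5)
  tr <- fit_tree(M, rep(0.25, 8), candidates = 1:5, depth = 3, min_leaf = 1)
  expect_null(tr$test)
  expect_equal(tr$value, 0.25)
})

test_that("one balanced stump leaves predictions at one half; zero shrinkage
           freezes them at sigmoid(psi0)", {
  pattern <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 1,
                    dimnames = list(paste0("s", 1:4), "HR"))
  labels <- setNames(c(1L, 0L, 1L, 0L), paste0("s", 1:4))
  store <- single_tranche_store(pattern, labels)
  m <- boost(store, n_trees = 1, depth = 0, shrinkage = 1)
  expect_equal(unname(predict_proba(m, store)), rep(0.5, 4))
  m0 <- boost(store, n_trees = 5, depth = 2, min_leaf = 1, shrinkage = 0)
  expect_equal(unname(predict_proba(m0, store)), rep(0.5, 4))
})

test_that("training log-loss decreases with more trees on separable data", {
  pattern <- matrix(c(rep(TRUE, 6), rep(FALSE, 6)), 12, 1,
                    dimnames = list(paste0("s", 1:12), "DBP"))
  labels <- setNames(c(rep(1L, 6), rep(0L, 6)), paste0("s", 1:12))
  store <- single_tranche_store(pattern, labels)
  m <- boost(store, n_trees = 10, depth = 2, min_leaf = 2, shrinkage = 1)
  y <- labels
  ll <- vapply(c(1, 5, 10), function(k) {
    p <- predict_proba(m, store, trees = m$trees[seq_len(k)])
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }, numeric(1))
  expect_true(all(diff(ll) < 0))
})

test_that("training log-loss is non-increasing tree by tree on a noisy store", {
  set.seed(8)
  pattern <- matrix(runif(120) < 0.5, 20, 6,
                    dimnames = list(paste0("s", 1:20), paste0("f", 1:6)))
  colnames(pattern) <- c("HR", "DBP", "SpO2", "VIS", "FiO2", "ETCO2")
  labels <- setNames(rbinom(20, 1, 0.5 + 0.3 * (pattern[, 1] - 0.5)),
                     rownames(pattern))
  if (length(unique(labels)) < 2) labels[1] <- 1 - labels[1]
  store <- single_tranche_store(pattern, labels)
  m <- boost(store, n_trees = 8, depth = 2, min_leaf = 3, shrinkage = 0.5)
  ll <- vapply(0:8, function(k) {
    p <- predict_proba(m, store, trees = m$trees[seq_len(k)])
    -mean(labels * log(p) + (1 - labels) * log(1 - p))
  }, numeric(1))
  expect_true(all(diff(ll) <= 1e-12))
})

test_that("single-class labels return the psi0-only model with a warning", {
  pattern <- matrix(TRUE, 3, 1, dimnames = list(paste0("s", 1:3), "HR"))
  labels <- setNames(rep(1L, 3), paste0("s", 1:3))
  store <- single_tranche_store(pattern, labels)
  expect_warning(m <- boost(store, n_trees = 3), "single-class")
  expect_length(m$trees, 0)
  expect_equal(unname(predict_proba(m, store)), rep(0.5, 3))
})

test_that("subjects with no facts are scored through all-FALSE paths and
           probabilities stay inside (0,1)", {
  pattern <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                    4, 2, dimnames = list(paste0("s", 1:4), c("HR", "DBP")))
  labels <- setNames(c(1L, 1L, 0L, 0L), paste0("s", 1:4))
  store <- single_tranche_store(pattern, labels)
  m <- boost(store, n_trees = 5, depth = 2, min_leaf = 1)
  # new store: one subject with zero facts
  empty <- make_store(store$facts[0, ], setNames(0L, "ghost"),
                      features = c("HR", "DBP"))
  p <- predict_proba(m, empty)
  expect_length(p, 1)
  expect_true(p > 0 && p < 1)
  p_all <- predict_proba(m, store)
  expect_true(all(p_all > 0 & p_all < 1))
})

test_that("subject order does not matter (set semantics)", {
  coh <- shared_cohort()
  norm <- baseline_normalize(coh)
  scheme <- fit_discretization(norm)
  store <- encode_predicates(norm, scheme)
  perm <- rev(seq_along(store$subjects))
  store_p <- store
  store_p$subjects <- store$subjects[perm]
  store_p$labels <- store$labels[perm]
  store_p$facts <- store$facts[rev(seq_len(nrow(store$facts))), ]
  m1 <- boost(store, n_trees = 5)
  m2 <- boost(store_p, n_trees = 5)
  p1 <- predict_proba(m1, store)
  p2 <- predict_proba(m2, store_p)
  expect_equal(p1[sort(names(p1))], p2[sort(names(p2))], tolerance = 1e-12)
})

test_that("on single-tranche complete data the relational engine matches the
           hand-coded propositional oracle exactly", {
  set.seed(11)
  for (rep in 1:3) {
    n <- 30
    pattern <- matrix(runif(n * 4) < 0.5, n, 4,
                      dimnames = list(paste0("s", 1:n),
                                      c("DBP", "HR", "SpO2", "VIS")))
    labels <- setNames(rbinom(n, 1, plogis(2 * pattern[, 1] - 1 +
                                             0.5 * pattern[, 2])),
                       rownames(pattern))
    if (length(unique(labels)) < 2) labels[1] <- 1 - labels[1]
    store <- single_tranche_store(pattern, labels)
    m <- boost(store, n_trees = 6, depth = 2, min_leaf = 3, shrinkage = 0.5)
    p_rel <- predict_proba(m, store)
    # oracle columns: the "<feature> low exists" indicators, same order the
    # engine enumerates features
    X <- pattern[, sort(colnames(pattern))]
    p_prop <- prop_boost_oracle(X, labels, n_trees = 6, depth = 2,
                                min_leaf = 3, shrinkage = 0.5)
    expect_equal(unname(p_rel), p_prop, tolerance = 1e-12)
  }
})
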