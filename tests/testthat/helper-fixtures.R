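# Shared fixtures and independent oracles.

# Build a cicu_cohort directly from vectors (bypasses the generator).
make_cohort <- function(subject_id, label, time_h, feature, value,
                        window_hours = NULL) {
  df <- data.frame(subject_id = subject_id, label = label, time_h = time_h,
                   feature = feature, value = value, stringsAsFactors = FALSE)
  cicuboost:::as_cicu_cohort(df, window_hours = window_hours)
}

# Build a predicate_store directly from a facts table (subject_id, feature,
# tranche, offset, bin) — used to drive the boosting engine with hand-made
# relational data.
make_store <- function(facts, labels, features = unique(facts$feature),
                       tranche_hours = 4, n_tranches = 4) {
  scheme <- structure(list(cuts = stats::setNames(
    rep(list(c(-1, 1)), length(features)), features),
    features = features), class = "discretization_scheme")
  structure(list(facts = facts, labels = labels, subjects = names(labels),
                 tranche_hours = tranche_hours, n_tranches = n_tranches,
                 window_hours = tranche_hours * n_tranches, scheme = scheme),
            class = "predicate_store")
}

# Facts giving every subject one fact per (feature, bin-pattern) in tranche 1
# only, from a binary pattern matrix: pattern[i, j] == TRUE emits a "low"
# fact for feature j, FALSE emits nothing (the existential test is FALSE).
single_tranche_store <- function(pattern, labels) {
  features <- colnames(pattern)
  rows <- which(pattern, arr.ind = TRUE)
  facts <- data.frame(subject_id = rownames(pattern)[rows[, 1]],
                      feature = features[rows[, 2]],
                      tranche = 1L, offset = 16L, bin = "low",
                      stringsAsFactors = FALSE)
  make_store(facts, labels, features = features)
}

# O(n^2) pair-enumeration AUROC oracle (ties counted one half).
auroc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Hand-coded propositional gradient boosting on a binary feature matrix:
# independent of the package's tree code (explicit loops, direct SSE).
prop_boost_oracle <- function(X, y, n_trees, depth, min_leaf, shrinkage,
                              psi0 = 0) {
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  grow <- function(idx, g, d) {
    if (d == 0 || length(idx) < 2 * min_leaf) return(list(value = mean(g[idx])))
    best_j <- 0L; best_gain <- 1e-12
    parent <- sse(g[idx])
    for (j in seq_len(ncol(X))) {
      a <- idx[X[idx, j]]; b <- idx[!X[idx, j]]
      if (length(a) < min_leaf || length(b) < min_leaf) next
      gain <- parent - sse(g[a]) - sse(g[b])
      if (gain > best_gain + 1e-15) { best_gain <- gain; best_j <- j }
    }
    if (best_j == 0L) return(list(value = mean(g[idx])))
    list(j = best_j,
         left = grow(idx[X[idx, best_j]], g, d - 1),
         right = grow(idx[!X[idx, best_j]], g, d - 1))
  }
  pred1 <- function(node, i) {
    while (is.null(node$value)) node <- if (X[i, node$j]) node$left else node$right
    node$value
  }
  psi <- rep(psi0, nrow(X))
  for (t in seq_len(n_trees)) {
    g <- y - 1 / (1 + exp(-psi))
    tree <- grow(seq_len(nrow(X)), g, depth)
    psi <- psi + shrinkage * vapply(seq_len(nrow(X)), function(i)
      pred1(tree, i), numeric(1))
  }
  1 / (1 + exp(-psi))
}

# Small default-structure cohort shared by several slow-ish tests.
shared_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- generate_cohort(cohort_config(15, 45, seed = 404))
    coh
  }
})
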