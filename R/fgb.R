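# Functional gradient boosting of relational regression trees. Node tests
# are existential: TRUE iff the subject has some fact matching a
# (feature, tranche-or-any, bin) pattern, so a subject with no matching
# facts simply takes the FALSE branch — missingness is an outcome, not an
# error. The engine works on a subjects x tests boolean incidence matrix.

#' Pointwise functional gradient of the Bernoulli log-likelihood
#'
#' The stage-wise learner fits each new regression tree to these per-example
#' gradients evaluated at the current model: `label - sigmoid(psi)`.
#'
#' @param label 0/1 outcome.
#' @param psi Current additive model value (log-odds scale).
#' @return The gradient, in (-1, 1).
#' @export
functional_gradient <- function(label, psi) label - sigmoid(psi)

# Candidate test grammar: feature x tranche x bin, plus tranche-free ("any")
# tests such as "DBP was low at some point". Rows are in the canonical
# lexicographic order used for deterministic tie-breaking.
candidate_tests <- function(features, n_tranches = 4) {
  features <- sort(features)
  tranches <- c(as.character(seq_len(n_tranches)), "any")
  g <- expand.grid(bin = bin_levels(), tranche = tranches, feature = features,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[order(g$feature, g$tranche, match(g$bin, bin_levels())),
         c("feature", "tranche", "bin")]
  rownames(g) <- NULL
  g$id <- seq_len(nrow(g))
  g
}

test_key <- function(feature, tranche, bin) paste(feature, tranche, bin, sep = "|")

# Boolean incidence matrix: subjects x candidate tests, built from the facts
# of tranches 1..max_tranche only (fitting block k must not see later data).
test_matrix <- function(store, tests, subjects = store$subjects,
                        max_tranche = store$n_tranches) {
  f <- store$facts[store$facts$tranche <= max_tranche, , drop = FALSE]
  M <- matrix(FALSE, nrow = length(subjects), ncol = nrow(tests),
              dimnames = list(subjects, NULL))
  if (nrow(f)) {
    keys <- test_key(tests$feature, tests$tranche, tests$bin)
    i <- match(f$subject_id, subjects)
    keep <- !is.na(i)
    f <- f[keep, , drop = FALSE]; i <- i[keep]
    j_spec <- match(test_key(f$feature, f$tranche, f$bin), keys)
    j_any <- match(test_key(f$feature, "any", f$bin), keys)
    idx <- cbind(c(i, i), c(j_spec, j_any))
    idx <- idx[!is.na(idx[, 2]), , drop = FALSE]
    M[idx] <- TRUE
  }
  M
}

#' Fit one relational regression tree to pointwise gradients
#'
#' Greedy top-down induction: at each node the existential test maximizing
#' the squared-error reduction of the gradients is chosen (ties broken by
#' the canonical lexicographic test order); leaves hold the mean gradient of
#' the subjects reaching them. Growth stops at `depth`, when a split would
#' leave fewer than `min_leaf` subjects on a side, or at zero gain.
#'
#' @param M Subjects x tests boolean matrix (see the predicate encoding).
#' @param gradients Per-subject functional gradients.
#' @param candidates Integer ids of the admissible test columns.
#' @param depth Maximum depth (0 = single leaf).
#' @param min_leaf Minimum subjects per leaf.
#' @return A nested-list tree: interior nodes `list(test, left, right)`
#'   (left = test TRUE), leaves `list(value)`.
#' @export
fit_tree <- function(M, gradients, candidates, depth = 3, min_leaf = 5) {
  grow <- function(idx, d) {
    g <- gradients[idx]
    leaf <- list(value = mean(g))
    n <- length(idx)
    if (d <= 0 || n < 2 * min_leaf || length(candidates) == 0) return(leaf)
    S <- sum(g)
    Msub <- M[idx, candidates, drop = FALSE]
    n1 <- colSums(Msub)
    S1 <- as.vector(crossprod(Msub, g))
    valid <- n1 >= min_leaf & (n - n1) >= min_leaf
    if (!any(valid)) return(leaf)
    gain <- rep(-Inf, length(candidates))
    gain[valid] <- S1[valid]^2 / n1[valid] +
      (S - S1[valid])^2 / (n - n1[valid]) - S^2 / n
    best <- which.max(gain)   # first max = lexicographic tie-break
    if (gain[best] <= 1e-12) return(leaf)
    j <- candidates[best]
    go <- M[idx, j]
    list(test = j,
         left = grow(idx[go], d - 1),
         right = grow(idx[!go], d - 1))
  }
  grow(seq_len(nrow(M)), depth)
}

# Leaf value for every subject (rows of M) under one tree.
predict_tree <- function(tree, M) {
  out <- numeric(nrow(M))
  walk <- function(node, idx) {
    if (is.null(node$test)) { out[idx] <<- node$value; return(invisible()) }
    go <- M[idx, node$test]
    if (any(go)) walk(node$left, idx[go])
    if (any(!go)) walk(node$right, idx[!go])
  }
  if (nrow(M)) walk(tree, seq_len(nrow(M)))
  out
}

#' Boost relational regression trees on a predicate store
#'
#' Stage-wise functional gradient boosting: starting from the constant model
#' `psi0`, repeatedly computes per-subject gradients, fits a regression tree
#' to them, and adds `shrinkage` times its leaf values to the model. The
#' fitted probability is `sigmoid(psi0 + shrinkage * sum of leaf values)`.
#'
#' @param store A `predicate_store` from [encode_predicates()].
#' @param n_trees Number of trees (>= 1).
#' @param depth,min_leaf Tree growth controls (see [fit_tree()]).
#' @param shrinkage Learning rate on each tree's contribution.
#' @param psi0 Initial potential (log-odds); 0 by default since training
#'   classes are near-balanced after control subsampling.
#' @param max_tranche Restrict facts and candidate tests to tranches
#'   `1..max_tranche`.
#' @return An object of class `boosted_fgb`.
#' @export
boost <- function(store, n_trees, depth = 2, min_leaf = 8, shrinkage = 0.5,
                  psi0 = 0, max_tranche = store$n_tranches) {
  if (n_trees < 1) stop_config("n_trees must be >= 1")
  y <- store$labels
  tests <- candidate_tests(store$scheme$features, store$n_tranches)
  model <- list(trees = list(), tests = tests, psi0 = psi0,
                shrinkage = shrinkage, tranche_hours = store$tranche_hours,
                n_tranches = store$n_tranches, scheme = store$scheme)
  class(model) <- "boosted_fgb"
  if (length(unique(y)) < 2) {
    warning("single-class labels: returning the psi0-only model", call. = FALSE)
    return(model)
  }
  M <- test_matrix(store, tests, max_tranche = max_tranche)
  cand <- tests$id[tests$tranche %in% c(as.character(seq_len(max_tranche)), "any")]
  psi <- rep(psi0, length(y))
  for (k in seq_len(n_trees)) {
    g <- functional_gradient(y, psi)
    tr <- fit_tree(M, g, cand, depth = depth, min_leaf = min_leaf)
    psi <- psi + shrinkage * predict_tree(tr, M)
    model$trees[[k]] <- tr
  }
  model
}

#' Predict from a boosted model
#'
#' `predict_psi` returns the additive potential
#' `psi0 + shrinkage * sum of leaf values`; `predict_proba` its sigmoid.
#' Subjects with no facts are valid inputs: every existential test is FALSE
#' and they are routed down all-FALSE paths.
#'
#' @param model A `boosted_fgb`.
#' @param store A `predicate_store` holding the subjects to score.
#' @param trees Optional subset of trees to use (default all).
#' @return Named numeric vector (per subject).
#' @export
predict_psi <- function(model, store, trees = model$trees) {
  M <- test_matrix(store, model$tests)
  psi <- rep(model$psi0, length(store$subjects))
  for (tr in trees) psi <- psi + model$shrinkage * predict_tree(tr, M)
  stats::setNames(psi, store$subjects)
}

#' @rdname predict_psi
#' @export
predict_proba <- function(model, store, trees = model$trees) {
  sigmoid(predict_psi(model, store, trees))
}

#' @export
print.boosted_fgb <- function(x, ...) {
  cat(sprintf("Boosted relational regression trees: %d trees, psi0 = %g, shrinkage = %g\n",
              length(x$trees), x$psi0, x$shrinkage))
  invisible(x)
}

# Training log-loss of a boosted model on its own store (used by tests and
# summaries; lower is better).
log_loss <- function(p, y) -mean(y * log(p) + (1 - y) * log(1 - p))
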