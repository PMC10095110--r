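# Tranche-wise stacking with anytime querying: the model grows in blocks of
# trees, one block per 4-h tranche, each block fitted with access only to
# the tranches observed so far, so any prefix of blocks is itself a valid
# model for the corresponding data prefix.

#' Fit a temporally stacked boosted model on an encoded store
#'
#' For tranche k = 1..4 (farthest-to-nearest the anchor), boosting continues
#' from the current potential with candidate tests and facts restricted to
#' tranches 1..k, appending `trees_per_tranche` trees per block; earlier
#' blocks are never refit. With the default 5 trees per tranche the
#' cumulative model sizes are 5, 10, 15 and 20 trees. Block k's trees carry
#' their temporal horizon with them: their any-tranche tests quantify over
#' tranches 1..k at fitting time and forever after, so data arriving in
#' later tranches never alters an earlier block's contribution — gradients
#' carry across blocks as one continuous boosting run, and any prefix of
#' blocks is exactly the model that training stopped there would have given.
#'
#' @param store A `predicate_store` spanning the 16-h modelling window.
#' @param trees_per_tranche Trees per 4-h block (default 5).
#' @param depth,min_leaf,shrinkage,psi0 Boosting controls as in [boost()].
#' @return An object of class `stacked_fgb_fit` with `blocks` (a list of
#'   tree lists), the candidate-test table, and the discretization scheme.
#' @export
fit_stacked <- function(store, trees_per_tranche = 5, depth = 2,
                        min_leaf = 8, shrinkage = 0.5, psi0 = 0) {
  if (!inherits(store, "predicate_store"))
    stop_validation("store must be a predicate_store")
  if (store$window_hours < store$tranche_hours)
    stop_config("the modelling window must span at least one tranche (>= 4 h of data)")
  if (trees_per_tranche < 1) stop_config("trees_per_tranche must be >= 1")
  y <- store$labels
  tests <- candidate_tests(store$scheme$features, store$n_tranches)
  fit <- list(blocks = vector("list", store$n_tranches), tests = tests,
              psi0 = psi0, shrinkage = shrinkage,
              trees_per_tranche = as.integer(trees_per_tranche),
              tranche_hours = store$tranche_hours,
              n_tranches = store$n_tranches,
              window_hours = store$window_hours,
              scheme = store$scheme)
  class(fit) <- "stacked_fgb_fit"
  single_class <- length(unique(y)) < 2
  if (single_class)
    warning("single-class labels: returning the psi0-only model", call. = FALSE)
  psi <- rep(psi0, length(y))
  for (k in seq_len(store$n_tranches)) {
    if (single_class) { fit$blocks[[k]] <- list(); next }
    Mk <- test_matrix(store, tests, max_tranche = k)
    cand <- tests$id[tests$tranche %in% c(as.character(seq_len(k)), "any")]
    blk <- vector("list", trees_per_tranche)
    for (t in seq_len(trees_per_tranche)) {
      g <- functional_gradient(y, psi)
      tr <- fit_tree(Mk, g, cand, depth = depth, min_leaf = min_leaf)
      psi <- psi + shrinkage * predict_tree(tr, Mk)
      blk[[t]] <- tr
    }
    fit$blocks[[k]] <- blk
  }
  fit
}

# Number of complete tranches available when querying lead_h hours before
# the anchor; offsets >= lead_h are observable, tranche k needs offset
# 16 - 4k + 1 .. 16 - 4(k-1).
tranches_available <- function(fit, lead_h) {
  k <- floor((fit$window_hours + 1 - lead_h) / fit$tranche_hours)
  min(fit$n_tranches, k)
}

#' Query a stacked model at a given lead time
#'
#' Scores subjects using only the data that would exist `lead_h` hours
#' before the anchor: facts at hour offsets below `lead_h` are discarded and
#' only the first k blocks of trees are summed, where k is the number of
#' complete 4-h tranches available (lead 13 -> 1 block of 5 trees, 9 -> 10
#' trees, 5 -> 15, 1 -> 20; non-boundary leads floor to the last complete
#' tranche). Requires at least one complete tranche (>= 4 h of data).
#'
#' @param fit A `stacked_fgb_fit`.
#' @param store A `predicate_store` of the subjects to score (full-window
#'   encoding; the truncation to the lead is applied here).
#' @param lead_h Hours before the anchor, in `[0, 13]`.
#' @return Named vector of arrest probabilities, strictly in (0, 1).
#' @export
query_anytime <- function(fit, store, lead_h) {
  if (lead_h < 0) stop_validation("lead_h must be nonnegative")
  k <- tranches_available(fit, lead_h)
  if (k < 1)
    stop_validation("cannot query at lead ", lead_h,
                    " h: at least 4 h of data (one complete tranche) is required")
  avail <- truncate_store(store, lead_h)
  psi <- rep(fit$psi0, length(avail$subjects))
  for (j in seq_len(k)) {
    # block j's tests keep their fitting-time horizon (tranches 1..j)
    Mj <- test_matrix(avail, fit$tests, max_tranche = j)
    for (tr in fit$blocks[[j]]) psi <- psi + fit$shrinkage * predict_tree(tr, Mj)
  }
  stats::setNames(sigmoid(psi), avail$subjects)
}

#' @export
print.stacked_fgb_fit <- function(x, ...) {
  nb <- lengths(x$blocks)
  cat(sprintf("Stacked boosted relational trees: %d blocks (%s trees; cumulative %s)\n",
              length(nb), paste(nb, collapse = "/"),
              paste(cumsum(nb), collapse = ", ")))
  invisible(x)
}

#' Fit the full anytime arrest-risk model to a cohort
#'
#' The one-call modelling interface: baseline-normalizes the cohort, fits
#' the tertile discretization, encodes the 16-h window before each subject's
#' anchor as ground predicates, and fits the tranche-stacked boosted model.
#'
#' @param cohort A `cicu_cohort` (long-format measurements with labels).
#' @param trees_per_tranche,depth,min_leaf,shrinkage,psi0 Model controls;
#'   see [fit_stacked()].
#' @param features Feature subset to model (default: the full vocabulary
#'   present in the cohort).
#' @param tranche_hours,window_hours Temporal geometry (defaults 4 and 16).
#' @return An object of class `stacked_fgb` with `print`, `summary` and
#'   `predict` methods.
#' @examples
#' coh <- generate_cohort(cohort_config(12, 24, seed = 7))
#' fit <- stacked_fgb(coh)
#' p1 <- predict(fit, coh, lead_h = 1)   # risk 1 h before the anchor
#' @export
stacked_fgb <- function(cohort, trees_per_tranche = 5, depth = 2,
                        min_leaf = 8, shrinkage = 0.5, psi0 = 0,
                        features = NULL, tranche_hours = 4,
                        window_hours = 16) {
  cl <- match.call()
  norm <- baseline_normalize(cohort)
  features <- features %||% intersect(cicu_features(), unique(cohort$feature))
  check_features(features)
  scheme <- fit_discretization(norm, features)
  store <- encode_predicates(norm, scheme, tranche_hours, window_hours)
  fit <- fit_stacked(store, trees_per_tranche = trees_per_tranche,
                     depth = depth, min_leaf = min_leaf,
                     shrinkage = shrinkage, psi0 = psi0)
  structure(list(fit = fit, scheme = scheme, features = features,
                 n_subjects = length(store$subjects),
                 n_arrest = sum(store$labels == 1),
                 train_probs = query_anytime(fit, store, 0),
                 labels = store$labels,
                 call = cl),
            class = "stacked_fgb")
}

#' @export
print.stacked_fgb <- function(x, ...) {
  cat("Anytime arrest-risk model (stacked functional gradient boosting)\n")
  cat(sprintf("  trained on %d subjects (%d arrest, %d control)\n",
              x$n_subjects, x$n_arrest, x$n_subjects - x$n_arrest))
  print(x$fit)
  invisible(x)
}

#' @export
summary.stacked_fgb <- function(object, ...) {
  p <- object$train_probs
  y <- object$labels[names(p)]
  cat("Anytime arrest-risk model (stacked functional gradient boosting)\n")
  cat(sprintf("  subjects: %d (%d arrest) | features: %s\n",
              object$n_subjects, object$n_arrest,
              paste(object$features, collapse = ", ")))
  nb <- lengths(object$fit$blocks)
  cat(sprintf("  blocks: %s trees (cumulative %s), depth <= %s\n",
              paste(nb, collapse = "/"), paste(cumsum(nb), collapse = ", "),
              "3"))
  cat(sprintf("  training AUROC (lead 0): %.3f | log-loss: %.3f\n",
              auroc(p, y), log_loss(p, y)))
  invisible(object)
}

#' Predict arrest risk for new subjects at a lead time
#'
#' @param object A fitted [stacked_fgb()] model.
#' @param newdata A `cicu_cohort` of subjects to score.
#' @param lead_h Hours before the anchor at which to query (default 1).
#' @param ... Unused.
#' @return Named vector of arrest probabilities.
#' @export
predict.stacked_fgb <- function(object, newdata, lead_h = 1, ...) {
  norm <- baseline_normalize(newdata)
  store <- encode_predicates(norm, object$scheme,
                             object$fit$tranche_hours,
                             object$fit$window_hours)
  query_anytime(object$fit, store, lead_h)
}
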