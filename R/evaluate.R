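# Evaluation protocol: AUROC, predictive-value algebra, confusion summaries,
# control-subsampled replicates of subject-level 5-fold cross-validation with
# AUROC by lead time, gradient-boosted feature selection, and the
# feature-group ablation grid.

#' Area under the ROC curve
#'
#' Probability that a randomly chosen case outranks a randomly chosen
#' control, with ties counted one half (the normalized Mann-Whitney
#' statistic, computed from midranks).
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels 0/1 or "arrest"/"control" labels; both classes required.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_label(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop_metric("AUROC is undefined with a single class")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Positive and negative predictive value from sensitivity, specificity
#' and prevalence
#'
#' \deqn{PPV = \frac{se\,p}{se\,p + (1-sp)(1-p)}, \quad
#'       NPV = \frac{sp\,(1-p)}{sp\,(1-p) + (1-se)\,p}}
#' Degenerate denominators (e.g. prevalence 0 with sensitivity 1) are
#' resolved by their limits and flagged.
#'
#' @param sensitivity,specificity,prevalence Values in `[0, 1]`.
#' @return List with `ppv`, `npv` and a `degenerate` flag.
#' @examples
#' predictive_values(0.90, 0.65, 1 / 6)$npv   # ~0.970
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  args <- c(sensitivity = sensitivity, specificity = specificity,
            prevalence = prevalence)
  if (any(args < 0 | args > 1))
    stop_validation("sensitivity, specificity and prevalence must lie in [0, 1]")
  p <- prevalence
  num_p <- sensitivity * p
  den_p <- num_p + (1 - specificity) * (1 - p)
  num_n <- specificity * (1 - p)
  den_n <- num_n + (1 - sensitivity) * p
  degenerate <- den_p == 0 || den_n == 0
  # limits: with no positives flagged, PPV -> prevalence-at-threshold is
  # undefined; report 0/1 edge values (no positives exist -> NPV = 1 etc.)
  ppv <- if (den_p == 0) 0 else num_p / den_p
  npv <- if (den_n == 0) 1 else num_n / den_n
  list(ppv = ppv, npv = npv, degenerate = degenerate)
}

#' Confusion-matrix summary at a score threshold
#'
#' @param scores Numeric scores.
#' @param labels 0/1 or "arrest"/"control".
#' @param threshold Scores `>= threshold` are called positive.
#' @return List of class `confusion_summary` with the counts and rates.
#' @export
confusion_summary <- function(scores, labels, threshold) {
  y <- as_binary_label(labels)
  pos <- scores >= threshold
  tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
  fn <- sum(!pos & y == 1); tn <- sum(!pos & y == 0)
  structure(list(threshold = threshold, TP = tp, FP = fp, TN = tn, FN = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Confusion at threshold %.3f: TP %d  FP %d  TN %d  FN %d\n",
              x$threshold, x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

# Youden-optimal (sens + spec - 1 maximizing) threshold over observed scores.
youden_threshold <- function(scores, labels) {
  y <- as_binary_label(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(th) {
    pos <- scores >= th
    sens <- sum(pos & y == 1) / sum(y == 1)
    spec <- sum(!pos & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

# Subject-level stratified fold assignment: permute within class, deal
# round-robin so every fold holds both classes.
stratified_folds <- function(labels, n_folds) {
  y <- as_binary_label(labels)
  if (min(table(y)) < n_folds)
    stop_validation("need at least ", n_folds,
                    " subjects per class for ", n_folds, "-fold CV ",
                    "(have ", min(table(y)), ")")
  fold <- integer(length(y))
  for (cls in c(0, 1)) {
    i <- which(y == cls)
    fold[sample(i)] <- rep_len(seq_len(n_folds), length(i))
  }
  fold
}

#' Run the cross-validated lead-time evaluation protocol
#'
#' For each of `n_replicates` replicates (each with its own derived seed):
#' assign subjects to `n_folds` stratified folds; per fold, subsample the
#' training controls to `subsample_ratio` controls per case (the held-out
#' fold is scored unsubsampled, at its natural imbalance), fit the
#' discretization and the stacked boosted model on training subjects only,
#' and score the held-out subjects at every lead hour. Optionally fits the
#' Gaussian naive Bayes and the hourly logistic baselines on identical
#' folds. Identical cohort + seed gives identical results.
#'
#' @param cohort A `cicu_cohort`.
#' @param lead_hours Lead hours to score (default the hourly grid 13..1).
#' @param n_replicates,n_folds Protocol sizes (defaults 5 and 5).
#' @param subsample_ratio Training controls per training case (default 1).
#' @param trees_per_tranche,depth,min_leaf,shrinkage,psi0 Model controls.
#' @param features Restrict the predicate vocabulary to this subset.
#' @param baselines Also run the GNB and logistic comparators (default TRUE).
#' @param seed Master seed; every source of randomness derives from it.
#' @return A `lead_time_eval`: long data.frame of fold-level AUROCs
#'   (`model`, `replicate`, `fold`, `lead_h`, `auroc`) with a summary and a
#'   representative lead-1 confusion matrix as attributes.
#' @export
run_experiment <- function(cohort, lead_hours = 13:1, n_replicates = 5,
                           n_folds = 5, subsample_ratio = 1,
                           trees_per_tranche = 5, depth = 2, min_leaf = 8,
                           shrinkage = 0.5, psi0 = 0, features = NULL,
                           baselines = TRUE, seed = 1) {
  features <- features %||% intersect(cicu_features(), unique(cohort$feature))
  check_features(features)
  labels <- subject_labels(cohort)
  ids <- names(labels)
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_replicates))
  norm <- baseline_normalize(cohort)
  rows_all <- if (baselines) hourly_feature_rows(norm, lead_hours) else NULL

  out <- list()
  confusion <- NULL
  for (r in seq_len(n_replicates)) {
    res <- with_seed(rep_seeds[r], {
      fold <- stratified_folds(labels, n_folds)
      fold_res <- list()
      for (k in seq_len(n_folds)) {
        test_ids <- ids[fold == k]
        train_ids <- ids[fold != k]
        tr_cases <- train_ids[labels[train_ids] == 1]
        tr_ctrls <- train_ids[labels[train_ids] == 0]
        n_keep <- min(length(tr_ctrls),
                      ceiling(subsample_ratio * length(tr_cases)))
        tr_ids <- c(tr_cases, sample(tr_ctrls, n_keep))
        train_norm <- cohort_subset(norm, tr_ids)
        test_norm <- cohort_subset(norm, test_ids)

        scheme <- fit_discretization(train_norm, features)
        store_tr <- encode_predicates(train_norm, scheme)
        fit <- fit_stacked(store_tr, trees_per_tranche = trees_per_tranche,
                           depth = depth, min_leaf = min_leaf,
                           shrinkage = shrinkage, psi0 = psi0)
        store_te <- encode_predicates(test_norm, scheme)
        y_te <- labels[test_ids]

        recs <- lapply(lead_hours, function(h) {
          p <- query_anytime(fit, store_te, h)
          rec <- data.frame(model = "stacked_fgb", replicate = r, fold = k,
                            lead_h = h, auroc = auroc(p[test_ids], y_te))
          if (baselines) {
            feat_cols <- intersect(features, names(rows_all))
            tr_rows <- rows_all[rows_all$subject_id %in% tr_ids &
                                  rows_all$lead_h == h, ]
            te_rows <- rows_all[rows_all$subject_id %in% test_ids &
                                  rows_all$lead_h == h, ]
            gnb <- fit_gnb(tr_rows[feat_cols], tr_rows$label)
            pg <- predict_gnb(gnb, te_rows[feat_cols])
            rec <- rbind(rec, data.frame(
              model = "gnb", replicate = r, fold = k, lead_h = h,
              auroc = auroc(pg, labels[te_rows$subject_id])))
            if (all(logistic_predictors() %in% names(rows_all))) {
              lg <- fit_hourly_logistic(tr_rows, h)
              pl <- predict_hourly_logistic(lg, te_rows, h)
              rec <- rbind(rec, data.frame(
                model = "logistic", replicate = r, fold = k, lead_h = h,
                auroc = auroc(pl, labels[te_rows$subject_id])))
            }
          }
          rec
        })
        # representative operating point: training Youden threshold at the
        # shortest lead, accumulated over folds of the first replicate
        if (r == 1) {
          h1 <- min(lead_hours)
          p_tr <- query_anytime(fit, store_tr, h1)
          th <- youden_threshold(p_tr, store_tr$labels)
          p_te <- query_anytime(fit, store_te, h1)
          cm <- confusion_summary(p_te[test_ids], y_te, th)
          confusion <- if (is.null(confusion)) cm else {
            acc <- confusion
            for (f in c("TP", "FP", "TN", "FN")) acc[[f]] <- acc[[f]] + cm[[f]]
            acc
          }
        }
        fold_res[[k]] <- do.call(rbind, recs)
      }
      do.call(rbind, fold_res)
    })
    out[[r]] <- res
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  if (!is.null(confusion)) {
    confusion$sensitivity <- confusion$TP / (confusion$TP + confusion$FN)
    confusion$specificity <- confusion$TN / (confusion$TN + confusion$FP)
    confusion$ppv <- confusion$TP / (confusion$TP + confusion$FP)
    confusion$npv <- confusion$TN / (confusion$TN + confusion$FN)
  }
  structure(df, class = c("lead_time_eval", "data.frame"),
            seed = seed, rep_seeds = rep_seeds, confusion = confusion,
            features = features)
}

#' Summarize a lead-time evaluation
#'
#' Mean AUROC per model and lead hour, with the dispersion computed as the
#' SD across folds within each replicate, averaged over replicates.
#'
#' @param object A `lead_time_eval`.
#' @param ... Unused.
#' @return Data.frame with `model`, `lead_h`, `mean_auroc`, `sd_auroc`.
#' @export
summary.lead_time_eval <- function(object, ...) {
  df <- as.data.frame(object)
  agg <- do.call(rbind, lapply(split(df, df[c("model", "lead_h")], drop = TRUE),
    function(g) {
      per_rep_sd <- tapply(g$auroc, g$replicate, stats::sd)
      data.frame(model = g$model[1], lead_h = g$lead_h[1],
                 mean_auroc = mean(g$auroc),
                 sd_auroc = mean(per_rep_sd, na.rm = TRUE))
    }))
  agg <- agg[order(agg$model, -agg$lead_h), ]
  rownames(agg) <- NULL
  agg
}

#' @export
print.lead_time_eval <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Lead-time evaluation: %d replicate(s) x %d fold(s)\n",
              length(unique(x$replicate)), length(unique(x$fold))))
  s$mean_auroc <- round(s$mean_auroc, 3)
  s$sd_auroc <- round(s$sd_auroc, 3)
  print(as.data.frame(s), row.names = FALSE)
  invisible(x)
}

#' Plot AUROC against hours to the event
#'
#' @param x A `lead_time_eval`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lead_time_eval <- function(x, ...) {
  s <- summary(x)
  models <- unique(s$model)
  cols <- stats::setNames(c("firebrick", "steelblue", "darkgreen")[
    seq_along(models)], models)
  graphics::plot(NA, xlim = rev(range(s$lead_h)),
                 ylim = c(min(0.4, min(s$mean_auroc - s$sd_auroc)), 1),
                 xlab = "Hours until event", ylab = "AUROC", ...)
  graphics::abline(h = 0.5, lty = 3, col = "grey")
  for (m in models) {
    g <- s[s$model == m, ]
    g <- g[order(-g$lead_h), ]
    graphics::lines(g$lead_h, g$mean_auroc, col = cols[m], lwd = 2)
    graphics::arrows(g$lead_h, g$mean_auroc - g$sd_auroc,
                     g$lead_h, g$mean_auroc + g$sd_auroc,
                     angle = 90, code = 3, length = 0.03, col = cols[m])
  }
  graphics::legend("topright", legend = models, col = cols[models], lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Rank features by propositional gradient-boosting importance
#'
#' Flattens the cohort to one row per subject (per-tranche means of each
#' feature over the 16-h window, after baseline normalization; missing stays
#' missing), fits a gradient-boosted tree classifier, and ranks the base
#' features by total split gain. Ties and never-used features are ordered
#' lexicographically.
#'
#' @param cohort A `cicu_cohort`.
#' @param k Number of top features to return (default 11; clipped with a
#'   warning if it exceeds the number available).
#' @param nrounds,max_depth,eta Booster controls.
#' @param seed Seed for the booster.
#' @return Character vector of the top-`k` feature names, best first.
#' @export
select_features <- function(cohort, k = 11, nrounds = 50, max_depth = 3,
                            eta = 0.3, seed = 1) {
  features <- intersect(cicu_features(), unique(cohort$feature))
  if (k > length(features)) {
    warning("k exceeds the ", length(features), " available features; clipped",
            call. = FALSE)
    k <- length(features)
  }
  norm <- baseline_normalize(cohort)
  anchors <- subject_anchors(norm)
  labels <- subject_labels(norm)
  ids <- names(labels)
  n_tranches <- 4L; tranche_hours <- 4
  X <- matrix(NA_real_, length(ids), length(features) * n_tranches,
              dimnames = list(ids, paste0(rep(features, each = n_tranches),
                                          ".t", rep(seq_len(n_tranches),
                                                    length(features)))))
  A <- anchors[norm$subject_id]
  off <- A - norm$time_h
  in_win <- off > 0 & off <= n_tranches * tranche_hours
  d <- norm[in_win, ]
  tranche <- n_tranches - ceiling(off[in_win] / tranche_hours) + 1L
  key <- paste0(d$feature, ".t", tranche)
  means <- tapply(d$value, list(d$subject_id, key), mean)
  X[rownames(means), colnames(means)] <- means
  X <- X[, colnames(X) %in% paste0(rep(features, each = n_tranches), ".t",
                                   rep(1:n_tranches, length(features))),
         drop = FALSE]
  dtrain <- xgboost::xgb.DMatrix(X, label = labels[ids], missing = NA)
  bst <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0))
  imp <- xgboost::xgb.importance(model = bst)
  gain <- stats::setNames(rep(0, length(features)), features)
  if (!is.null(imp) && nrow(imp)) {
    base_feat <- sub("\\.t[0-9]+$", "", imp$Feature)
    g <- tapply(imp$Gain, base_feat, sum)
    gain[names(g)] <- g
  }
  ranked <- features[order(-gain[features], features)]
  ranked[seq_len(k)]
}

#' Standard feature groupings for the ablation
#'
#' The feature subsets used for the group-wise ablation of model
#' performance: gas-exchange/metabolic markers, hemodynamic-oximetry
#' combinations with and without VIS, and a hemodynamics + urine-output
#' group.
#'
#' @return Named list of character vectors.
#' @export
ablation_feature_groups <- function() {
  list(
    "SpO2+ETCO2+anion_gap+base_excess+FiO2" =
      c("SpO2", "ETCO2", "anion_gap", "base_excess", "FiO2"),
    "HR+DBP+SpO2+rSO2c" = c("HR", "DBP", "SpO2", "rSO2c"),
    "HR+DBP+SpO2+rSO2s" = c("HR", "DBP", "SpO2", "rSO2s"),
    "HR+DBP+SpO2+rSO2c+rSO2s" = c("HR", "DBP", "SpO2", "rSO2c", "rSO2s"),
    "HR+DBP+SpO2+rSO2c+rSO2s+VIS" =
      c("HR", "DBP", "SpO2", "rSO2c", "rSO2s", "VIS"),
    "HR+DBP+SpO2+rSO2c+VIS" = c("HR", "DBP", "SpO2", "rSO2c", "VIS"),
    "HR+DBP+VIS+urine_output" = c("HR", "DBP", "VIS", "urine_output")
  )
}

#' Feature-group ablation grid
#'
#' Reruns the full evaluation protocol with the predicate vocabulary
#' restricted to each named feature group, and tabulates mean +/- SD AUROC
#' per group at the requested lead hours (the tranche boundaries 13/9/5/1 by
#' default).
#'
#' @param cohort A `cicu_cohort`.
#' @param groups Named list of feature subsets
#'   (default [ablation_feature_groups()]).
#' @param lead_hours Lead hours to report.
#' @param ... Passed to [run_experiment()] (e.g. `n_replicates`, `seed`).
#' @return Data.frame of class `fgb_ablation`: one row per group x lead hour.
#' @export
ablation <- function(cohort, groups = ablation_feature_groups(),
                     lead_hours = c(13, 9, 5, 1), ...) {
  if (!length(groups) || is.null(names(groups)))
    stop_config("groups must be a named list of feature subsets")
  for (g in groups) check_features(g, "group feature")
  res <- lapply(names(groups), function(nm) {
    ev <- run_experiment(cohort, lead_hours = lead_hours,
                         features = groups[[nm]], baselines = FALSE, ...)
    s <- summary(ev)
    s$group <- nm
    s
  })
  out <- do.call(rbind, res)[, c("group", "lead_h", "mean_auroc", "sd_auroc")]
  rownames(out) <- NULL
  class(out) <- c("fgb_ablation", "data.frame")
  out
}

#' @export
print.fgb_ablation <- function(x, ...) {
  cat("Feature-group ablation (mean +/- SD AUROC by lead hour)\n")
  wide <- stats::reshape(
    transform(as.data.frame(x),
              cell = sprintf("%.2f +/- %.2f", mean_auroc, sd_auroc),
              mean_auroc = NULL, sd_auroc = NULL),
    idvar = "group", timevar = "lead_h", direction = "wide")
  names(wide) <- sub("^cell\\.", "lead ", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
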