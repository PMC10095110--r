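# Comparator models: Gaussian naive Bayes on the forward-imputed numeric
# feature values, and the per-lead-hour multivariable logistic regression.

#' Hourly feature rows for the vector-based comparators
#'
#' One row per subject per lead hour: each feature is the mean of its
#' observations within the hour ending `lead_h` hours before the anchor,
#' forward-imputed (latest earlier observation) when that hour is empty, and
#' `NA` when nothing has ever been observed. Adds `VIS_bin` (VIS dichotomized
#' at 0, the charted VIS being zero-inflated) and the saturation-minus-
#' oximetry differences `dSpO2_rSO2c` and `dSpO2_rSO2s`.
#'
#' @param cohort A `cicu_cohort` (normalize first if the model expects
#'   change-from-baseline values).
#' @param lead_hours Lead hours to tabulate (default 13..1).
#' @return Data.frame with `subject_id`, `label`, `lead_h`, one column per
#'   feature, plus the derived columns.
#' @export
hourly_feature_rows <- function(cohort, lead_hours = 13:1) {
  anchors <- subject_anchors(cohort)
  labels <- subject_labels(cohort)
  ids <- names(anchors)
  features <- intersect(cicu_features(), unique(cohort$feature))
  rows <- expand.grid(subject_id = ids, lead_h = lead_hours,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  by_sf <- split(cohort[c("time_h", "value")],
                 list(factor(cohort$subject_id, ids),
                      factor(cohort$feature, features)), sep = "\r")
  cols <- lapply(features, function(f) rep(NA_real_, nrow(rows)))
  names(cols) <- features
  ridx_by_subj <- split(seq_len(nrow(rows)), factor(rows$subject_id, ids))
  for (i in seq_along(ids)) {
    A <- anchors[[ids[i]]]
    ridx <- ridx_by_subj[[i]]
    hs <- rows$lead_h[ridx]
    for (f in features) {
      g <- by_sf[[paste(ids[i], f, sep = "\r")]]
      if (is.null(g) || !nrow(g)) next
      o <- order(g$time_h); tt <- g$time_h[o]; vv <- g$value[o]
      cols[[f]][ridx] <- vapply(hs, function(h) {
        in_hour <- tt > A - h - 1 & tt <= A - h
        if (any(in_hour)) mean(vv[in_hour]) else {
          j <- findInterval(A - h, tt)
          if (j > 0) vv[j] else NA_real_
        }
      }, numeric(1))
    }
  }
  for (f in features) rows[[f]] <- cols[[f]]
  rows$label <- labels[rows$subject_id]
  if (!is.null(rows$VIS)) rows$VIS_bin <- as.integer(rows$VIS > 0)
  if (!is.null(rows$SpO2) && !is.null(rows$rSO2c))
    rows$dSpO2_rSO2c <- rows$SpO2 - rows$rSO2c
  if (!is.null(rows$SpO2) && !is.null(rows$rSO2s))
    rows$dSpO2_rSO2s <- rows$SpO2 - rows$rSO2s
  rows
}

#' Gaussian naive Bayes classifier
#'
#' Class-conditional independent Gaussians per feature with class priors
#' from the training frequencies. Zero-variance features have their variance
#' floored (with a warning). At prediction, a feature that is `NA` for a row
#' is skipped — the naive-Bayes factorization marginalizes it out — so a row
#' missing every feature falls back to the prior.
#'
#' @param x Numeric matrix or data.frame of features (NAs allowed).
#' @param y 0/1 labels (or "arrest"/"control").
#' @param var_floor Lower bound applied to every class-conditional variance.
#' @return An object of class `gnb`.
#' @export
fit_gnb <- function(x, y, var_floor = 1e-6) {
  x <- as.matrix(x)
  y <- as_binary_label(y)
  if (min(table(y)) < 2)
    stop_validation("need at least 2 subjects per class to fit the GNB")
  stats_for <- function(cls) {
    xs <- x[y == cls, , drop = FALSE]
    mu <- colMeans(xs, na.rm = TRUE)
    v <- apply(xs, 2, stats::var, na.rm = TRUE)
    v[is.na(v)] <- var_floor
    list(mu = mu, var = pmax(v, var_floor), floored = any(v < var_floor))
  }
  par <- list(`0` = stats_for(0), `1` = stats_for(1))
  if (par$`0`$floored || par$`1`$floored)
    warning("zero/near-zero variance feature(s) floored at ", var_floor,
            call. = FALSE)
  structure(list(classes = c(0, 1),
                 prior = c(mean(y == 0), mean(y == 1)),
                 par = par, features = colnames(x)),
            class = "gnb")
}

#' @rdname fit_gnb
#' @param model A fitted `gnb`.
#' @param newdata Matrix/data.frame with the training columns.
#' @return `predict_gnb` returns the posterior probability of class 1
#'   (arrest) per row.
#' @export
predict_gnb <- function(model, newdata) {
  x <- as.matrix(newdata)
  if (!is.null(model$features)) x <- x[, model$features, drop = FALSE]
  loglik <- function(cls) {
    p <- model$par[[as.character(cls)]]
    ll <- rep(log(model$prior[cls + 1]), nrow(x))
    for (j in seq_len(ncol(x))) {
      ok <- !is.na(x[, j])
      ll[ok] <- ll[ok] + stats::dnorm(x[ok, j], p$mu[j], sqrt(p$var[j]),
                                      log = TRUE)
    }
    ll
  }
  l0 <- loglik(0); l1 <- loglik(1)
  m <- pmax(l0, l1)
  exp(l1 - m) / (exp(l0 - m) + exp(l1 - m))
}

#' @export
print.gnb <- function(x, ...) {
  cat(sprintf("Gaussian naive Bayes: %d features, priors %.3f/%.3f (control/arrest)\n",
              length(x$par$`0`$mu), x$prior[1], x$prior[2]))
  invisible(x)
}

# Predictors of the multivariable hourly logistic model.
logistic_predictors <- function() {
  c("DBP", "HR", "VIS_bin", "dSpO2_rSO2c", "dSpO2_rSO2s")
}

#' Hourly multivariable logistic regression
#'
#' Classical (unpenalized) maximum-likelihood logistic fit at each lead hour
#' on five predictors: DBP, HR, dichotomized VIS (0 vs > 0), and the
#' SpO2 - rSO2c and SpO2 - rSO2s differences, with HR/DBP (and the
#' saturation channels feeding the differences) expressed as change from the
#' first-4-h baseline. Rows with missing predictors are dropped at fitting;
#' at prediction missing predictors take the training mean so every subject
#' is scorable. Perfect separation is reported via a convergence flag, not
#' an error.
#'
#' @param rows Output of [hourly_feature_rows()] on a baseline-normalized
#'   cohort.
#' @param lead_hours Lead hours to fit (default: all present in `rows`).
#' @return Object of class `hourly_logistic`: per-hour coefficient table,
#'   in-sample AUROC and convergence flags.
#' @export
fit_hourly_logistic <- function(rows, lead_hours = NULL) {
  lead_hours <- lead_hours %||% sort(unique(rows$lead_h), decreasing = TRUE)
  preds <- logistic_predictors()
  miss <- setdiff(preds, names(rows))
  if (length(miss))
    stop_validation("rows lack predictor column(s): ", paste(miss, collapse = ", "))
  fits <- lapply(lead_hours, function(h) {
    d <- rows[rows$lead_h == h, c("label", preds)]
    d$label <- as_binary_label(d$label)
    if (length(unique(d$label)) < 2)
      stop_validation("both classes must be present at lead hour ", h)
    cc <- stats::complete.cases(d)
    fit <- suppressWarnings(
      stats::glm(label ~ ., data = d[cc, ], family = stats::binomial()))
    p_fit <- fit$fitted.values
    separated <- !fit$converged || any(p_fit > 1 - 1e-8) || any(p_fit < 1e-8)
    means <- colMeans(d[cc, preds, drop = FALSE])
    dd <- d
    for (j in preds) dd[[j]][is.na(dd[[j]])] <- means[[j]]
    p <- stats::predict(fit, newdata = dd, type = "response")
    list(lead_h = h, coef = stats::coef(fit), converged = !separated,
         auroc = auroc(p, d$label), prob = p, means = means)
  })
  coefs <- do.call(rbind, lapply(fits, function(f) f$coef))
  structure(list(lead_hours = lead_hours, coefficients = coefs,
                 auroc = vapply(fits, `[[`, 0, "auroc"),
                 converged = vapply(fits, `[[`, TRUE, "converged"),
                 fits = fits, predictors = preds),
            class = "hourly_logistic")
}

#' @export
print.hourly_logistic <- function(x, ...) {
  cat("Hourly multivariable logistic regression\n")
  tab <- data.frame(lead_h = x$lead_hours, AUROC = round(x$auroc, 3),
                    converged = x$converged)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.hourly_logistic <- function(object, ...) object$coefficients

# Score new rows with the logistic model fitted at one lead hour.
predict_hourly_logistic <- function(model, rows, lead_h) {
  i <- match(lead_h, model$lead_hours)
  if (is.na(i)) stop_validation("no logistic fit at lead hour ", lead_h)
  f <- model$fits[[i]]
  d <- rows[rows$lead_h == lead_h, model$predictors, drop = FALSE]
  cf <- f$coef
  cf[is.na(cf)] <- 0
  X <- as.matrix(d)
  # impute missing predictors at the training means stored with the fit
  mu <- f$means[colnames(X)]; mu[is.na(mu)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  eta <- cf[1] + X %*% cf[-1]
  stats::setNames(sigmoid(drop(eta)), rows$subject_id[rows$lead_h == lead_h])
}
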