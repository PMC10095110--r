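# Preprocessing: forward imputation, first-4-h baseline normalization,
# tertile discretization, and encoding into timestamped ground predicates.

#' Forward (last-observation-carried-forward) imputation
#'
#' Returns the value of the latest observation of `feature` at or before time
#' `t` for one subject's facts; `NA` if nothing precedes the query. No
#' back-fill and no default value: missingness stays missing.
#'
#' @param facts Data.frame with columns `feature`, `time_h`, `value` (one
#'   subject's measurements; a `cicu_cohort` restricted to one subject works).
#' @param feature Feature name from the vocabulary.
#' @param t Query time in hours (>= 0).
#' @return The carried-forward value, or `NA_real_`.
#' @export
forward_impute <- function(facts, feature, t) {
  check_features(feature)
  if (t < 0) stop_validation("query time must be nonnegative")
  f <- facts[facts$feature == feature & facts$time_h <= t, , drop = FALSE]
  if (!nrow(f)) return(NA_real_)
  f$value[which.max(f$time_h)]
}

#' Baseline normalization to each subject's first four hours
#'
#' For HR, DBP, SpO2, rSO2c and rSO2s only, every value is replaced by its
#' change from the mean of that subject's observations in hours `[0, 4)`.
#' Other features pass through unchanged. Subjects with no baseline
#' observation for a feature are left unnormalized and recorded in the
#' `"unnormalized"` attribute (flag-and-pass).
#'
#' @param cohort A `cicu_cohort`.
#' @return The cohort with normalized values; attribute `"unnormalized"` is a
#'   data.frame of (subject_id, feature) pairs lacking a baseline.
#' @export
baseline_normalize <- function(cohort) {
  norm <- cohort$feature %in% normalized_features()
  key <- paste(cohort$subject_id, cohort$feature, sep = "\r")
  in_base <- cohort$time_h >= 0 & cohort$time_h < 4
  bsum <- tapply(cohort$value[norm & in_base], key[norm & in_base], mean)
  m <- bsum[key]
  adjust <- norm & !is.na(m)
  cohort$value[adjust] <- cohort$value[adjust] - m[adjust]
  # subject/feature pairs that should be normalized but have no baseline data
  all_norm_keys <- unique(key[norm])
  missing_keys <- setdiff(all_norm_keys, names(bsum))
  un <- if (length(missing_keys)) {
    parts <- strsplit(missing_keys, "\r", fixed = TRUE)
    data.frame(subject_id = vapply(parts, `[`, "", 1L),
               feature = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = character(0), feature = character(0))
  }
  attr(cohort, "unnormalized") <- un
  attr(cohort, "normalized") <- TRUE
  cohort
}

#' Fit a tertile discretization scheme
#'
#' Per feature, cut points at the empirical 1/3 and 2/3 quantiles of all
#' training observations (taken after [baseline_normalize()] where that
#' applies), defining three equal-frequency bins low/mid/high. When a point
#' mass makes the two tertiles coincide (zero-inflated VIS, typically), the
#' tie is broken at the nearest distinct observed value so the bins stay
#' informative; features with fewer than three distinct training values
#' degenerate to a single `mid` bin with a warning.
#'
#' @param cohort Training `cicu_cohort` (fit on training folds only; reuse
#'   the fitted scheme unchanged on held-out data).
#' @param features Features to include (default: every feature present).
#' @return An object of class `discretization_scheme`: per-feature cut points.
#' @export
fit_discretization <- function(cohort, features = NULL) {
  features <- features %||% intersect(cicu_features(), unique(cohort$feature))
  check_features(features)
  cuts <- lapply(features, function(f) {
    x <- cohort$value[cohort$feature == f]
    if (length(unique(x)) < 3) {
      warning("feature '", f, "' has < 3 distinct training values; ",
              "using a single bin", call. = FALSE)
      return(NULL)
    }
    q <- unname(stats::quantile(x, c(1 / 3, 2 / 3), type = 7))
    if (q[1] >= q[2]) {
      # point mass at the tertiles (e.g. zero-inflated VIS): break the tie at
      # the nearest distinct observed value so the bins stay informative
      uq <- sort(unique(x))
      above <- uq[uq > q[1]]
      below <- uq[uq < q[1]]
      if (length(above)) q <- c(q[1], above[1])
      else if (length(below)) q <- c(below[length(below)], q[1])
      else return(NULL)  # unreachable: >= 3 distinct values guaranteed above
    }
    q
  })
  names(cuts) <- features
  structure(list(cuts = cuts, features = features),
            class = "discretization_scheme")
}

#' @export
print.discretization_scheme <- function(x, ...) {
  cat("Tertile discretization scheme (3 bins: low/mid/high)\n")
  for (f in x$features) {
    q <- x$cuts[[f]]
    if (is.null(q)) cat(sprintf("  %-13s single bin (degenerate)\n", f))
    else cat(sprintf("  %-13s cuts at %.4g, %.4g\n", f, q[1], q[2]))
  }
  invisible(x)
}

# Map values of one feature to bins under a fitted scheme. The bins
# partition the real line: value <= cut1 -> low, <= cut2 -> mid, else high.
assign_bins <- function(scheme, feature, values) {
  if (!feature %in% scheme$features)
    stop_vocab("feature '", feature, "' is not in the fitted scheme")
  q <- scheme$cuts[[feature]]
  if (is.null(q)) return(rep("mid", length(values)))
  ifelse(values <= q[1], "low", ifelse(values <= q[2], "mid", "high"))
}

#' Encode a cohort as tranche-indexed ground predicates
#'
#' For each subject, each feature and each hour offset 1..16 counted back
#' from the subject's anchor (arrest time for cases, window end for
#' controls), emits a ground fact
#' `measured(subject, feature, tranche, offset, bin)` using the
#' forward-imputed value at that hour, binned under `scheme`. Hours with no
#' preceding observation emit no fact: missingness is preserved, never
#' fabricated. Offsets map to tranches of `tranche_hours` each, tranche 1
#' farthest from the anchor (offsets 16..13) through tranche 4 nearest
#' (offsets 4..1). Sub-hour timestamps are floored onto the hourly grid.
#'
#' @param cohort A preprocessed `cicu_cohort` (normalize first).
#' @param scheme A fitted [fit_discretization()] scheme.
#' @param tranche_hours Tranche length in hours; must divide `window_hours`.
#' @param window_hours Modelling window counted back from the anchor
#'   (default 16).
#' @return A `predicate_store`: facts data.frame
#'   (`subject_id`, `feature`, `tranche`, `offset`, `bin`), subject labels,
#'   and the scheme.
#' @export
encode_predicates <- function(cohort, scheme, tranche_hours = 4,
                              window_hours = 16) {
  if (window_hours %% tranche_hours != 0)
    stop_config("tranche_hours must divide the modelling window")
  n_tranches <- window_hours / tranche_hours
  features <- scheme$features
  anchors <- subject_anchors(cohort)
  labels <- subject_labels(cohort)
  ids <- names(anchors)

  obs <- cohort[cohort$feature %in% features, , drop = FALSE]
  # floor onto the hourly grid, keep the latest observation within each hour
  obs$hour <- floor(obs$time_h)
  ord <- order(obs$subject_id, obs$feature, obs$hour, obs$time_h)
  obs <- obs[ord, ]
  lastk <- !duplicated(paste(obs$subject_id, obs$feature, obs$hour, sep = "\r"),
                       fromLast = TRUE)
  obs <- obs[lastk, ]

  facts <- lapply(split(obs[c("hour", "value", "feature", "subject_id")],
                        paste(obs$subject_id, obs$feature, sep = "\r")),
                  function(g) {
    A <- anchors[[g$subject_id[1]]]
    offsets <- seq_len(window_hours)
    qt <- A - offsets
    idx <- findInterval(qt, g$hour)   # g sorted by hour
    ok <- idx > 0L & qt >= 0
    if (!any(ok)) return(NULL)
    data.frame(subject_id = g$subject_id[1], feature = g$feature[1],
               offset = offsets[ok], value = g$value[idx[ok]],
               stringsAsFactors = FALSE)
  })
  facts <- do.call(rbind, facts)
  if (is.null(facts)) {
    facts <- data.frame(subject_id = character(0), feature = character(0),
                        tranche = integer(0), offset = integer(0),
                        bin = character(0), stringsAsFactors = FALSE)
  } else {
    facts$tranche <- n_tranches - ceiling(facts$offset / tranche_hours) + 1L
    facts$bin <- NA_character_
    for (f in unique(facts$feature)) {
      i <- facts$feature == f
      facts$bin[i] <- assign_bins(scheme, f, facts$value[i])
    }
    facts <- facts[order(facts$subject_id, facts$feature, -facts$offset),
                   c("subject_id", "feature", "tranche", "offset", "bin")]
    rownames(facts) <- NULL
  }
  structure(list(facts = facts, labels = labels, subjects = ids,
                 tranche_hours = tranche_hours, n_tranches = n_tranches,
                 window_hours = window_hours, scheme = scheme),
            class = "predicate_store")
}

#' @export
print.predicate_store <- function(x, ...) {
  cat(sprintf("Predicate store: %d facts over %d subjects (%d arrest), %d tranches of %g h\n",
              nrow(x$facts), length(x$subjects), sum(x$labels == 1),
              x$n_tranches, x$tranche_hours))
  invisible(x)
}

# Restrict a store to facts with offset >= lead (the data actually available
# when querying `lead` hours before the anchor).
truncate_store <- function(store, lead_h) {
  store$facts <- store$facts[store$facts$offset >= lead_h, , drop = FALSE]
  store
}

#' Write / read a predicate store as flat CSV
#'
#' Ground facts go to `path`; the subject labels travel in the same file as
#' a `label` column, and the discretization cut points to a JSON sidecar.
#'
#' @param store A `predicate_store`.
#' @param path CSV path.
#' @export
write_predicates <- function(store, path) {
  df <- store$facts
  df$label <- ifelse(store$labels[df$subject_id] == 1, "arrest", "control")
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(tranche_hours = store$tranche_hours,
         window_hours = store$window_hours,
         subjects = store$subjects,
         labels = as.list(store$labels),
         cuts = store$scheme$cuts),
    paste0(sub("\\.csv$", "", path), ".json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
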