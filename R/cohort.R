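# Synthetic CICU cohort generator: long-format measurement series with the
# statistical structure the downstream models assume (hourly vitals, sparse
# labs, per-feature missingness, a pre-arrest physiologic drift in cases).

#' Reference physiology for the synthetic generator
#'
#' Per-feature location/spread constants used by [generate_cohort()]:
#' population mean and SD in native units, the SD of a per-subject random
#' intercept, the SD of the per-observation noise, and clamping bounds where
#' the unit has hard limits (e.g. SpO2 <= 100). The values are plausible for
#' a pediatric CICU but otherwise arbitrary and fixed; the learning code
#' never depends on them.
#'
#' @return A data.frame with one row per feature.
#' @export
physiologic_baselines <- function() {
  data.frame(
    feature      = cicu_features(),
    mean         = c(120, 55, 92, 38, 0.40, 70, 75, 8, 0, 2.0, 0),
    sd           = c(15, 8, 3, 4, 0.08, 6, 6, 2, 3, 0.7, 0),
    intercept_sd = c(9, 5, 2, 2.5, 0.05, 4, 4, 1.2, 1.8, 0.4, 0),
    noise_sd     = c(12, 6.5, 2.5, 3.2, 0.06, 4.8, 4.8, 1.6, 2.4, 0.55, 0),
    lower        = c(30, 10, 50, 10, 0.21, 20, 20, -5, -25, 0, 0),
    upper        = c(250, 150, 100, 90, 1.00, 95, 95, 35, 25, 12, Inf),
    stringsAsFactors = FALSE
  )
}

default_drift_magnitudes <- function() {
  c(HR = 20, DBP = -15, SpO2 = -8, ETCO2 = -5, FiO2 = 0.15,
    rSO2c = -10, rSO2s = -14, anion_gap = 5, base_excess = -6,
    urine_output = -1, VIS = 10)
}

#' Default deterioration phenotypes
#'
#' Pre-arrest deterioration in children with heart disease is
#' heterogeneous: some children decompensate hemodynamically (heart-rate
#' and diastolic-pressure derangement, falling urine output, vasoactive
#' escalation, growing base deficit and anion gap), others through gas
#' exchange and oxygen delivery (falling saturations and regional oximetry,
#' rising ETCO2 derangement and FiO2 escalation). The generator assigns
#' each case one of these marker groups at random and expresses the drift
#' only through it, so no single channel moves in every case — an
#' OR-structure across marker groups that a per-feature independence model
#' cannot represent but existential tree tests can.
#'
#' @return Named list of two feature groups.
#' @export
default_phenotypes <- function() {
  list(
    hypoperfusion = c("HR", "DBP", "urine_output", "VIS",
                      "anion_gap", "base_excess"),
    hypoxia = c("SpO2", "rSO2c", "rSO2s", "ETCO2", "FiO2")
  )
}

default_missingness <- function() {
  c(HR = 0.02, DBP = 0.05, SpO2 = 0.02, ETCO2 = 0.25, FiO2 = 0.20,
    rSO2c = 0.15, rSO2s = 0.15, anion_gap = 0, base_excess = 0,
    urine_output = 0.05, VIS = 0)
}

#' Configuration for a synthetic cohort
#'
#' @param n_cases,n_controls Number of arrest and control subjects (each >= 1).
#' @param window_hours Length of each subject's record in hours (>= 16 so the
#'   16-hour modelling window fits). Case series end at the arrest; control
#'   series span the first `window_hours` of admission.
#' @param drift_onset Hours before the arrest at which the pre-arrest
#'   deterioration begins in cases.
#' @param drift_magnitudes Named vector of signed per-feature effect sizes, in
#'   native units, reached at the arrest time (piecewise-linear ramp from
#'   `drift_onset`). The `VIS` entry is instead the size of a step escalation
#'   at a random time inside the drift window. Entries you supply override
#'   the defaults; set all to zero for a null cohort.
#' @param missingness Named vector of per-feature probabilities that an hourly
#'   slot goes unrecorded; entries override the defaults.
#' @param lab_interval_hours Mean gap between laboratory draws (anion gap,
#'   base excess), which are sampled at irregular times rather than hourly.
#' @param vis_escalation_prob Probability a case receives the VIS step
#'   escalation (given a nonzero `VIS` drift magnitude).
#' @param phenotypes Deterioration phenotypes: a named list of feature
#'   groups. Each case expresses the drift only through the features of one
#'   phenotype, drawn uniformly at random, so the pre-arrest signal has an
#'   OR-structure across marker groups rather than moving every channel in
#'   every case (see [default_phenotypes()]). Set to `NULL` to apply the
#'   drift to all configured features in every case.
#' @param artifact_prob Probability that a charted hourly vital-sign value is
#'   a charting/probe artifact (drawn uniformly over the feature's plausible
#'   range instead of the physiologic model) — the dropped-probe SpO2 or
#'   flushed-line pressure familiar from real EHR data. Applies to the hourly
#'   charted channels (vitals and urine output, not labs or doses), in both
#'   classes; set to 0 for purely Gaussian noise.
#' @param seed Integer seed; identical configs with identical seeds generate
#'   byte-identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases, n_controls, window_hours = 48,
                          drift_onset = 12,
                          drift_magnitudes = NULL,
                          missingness = NULL,
                          lab_interval_hours = 8,
                          vis_escalation_prob = 0.6,
                          phenotypes = default_phenotypes(),
                          artifact_prob = 0.05,
                          seed = 1L) {
  if (!is.numeric(n_cases) || !is.numeric(n_controls) ||
      n_cases < 1 || n_controls < 1)
    stop_config("n_cases and n_controls must be >= 1")
  if (window_hours < 16)
    stop_config("window_hours must be >= 16 (the training window must fit)")
  if (drift_onset <= 0 || drift_onset > window_hours)
    stop_config("drift_onset must be in (0, window_hours]")
  if (lab_interval_hours <= 0)
    stop_config("lab_interval_hours must be positive")

  dm <- default_drift_magnitudes()
  if (!is.null(drift_magnitudes)) {
    check_features(names(drift_magnitudes), "drift_magnitudes")
    dm[names(drift_magnitudes)] <- drift_magnitudes
  }
  ms <- default_missingness()
  if (!is.null(missingness)) {
    check_features(names(missingness), "missingness")
    ms[names(missingness)] <- missingness
  }
  if (any(ms < 0 | ms > 1))
    stop_config("missingness probabilities must lie in [0, 1]")
  if (vis_escalation_prob < 0 || vis_escalation_prob > 1)
    stop_config("vis_escalation_prob must lie in [0, 1]")
  if (!is.null(phenotypes)) {
    if (!is.list(phenotypes) || !length(phenotypes))
      stop_config("phenotypes must be NULL or a nonempty list of feature groups")
    for (ph in phenotypes) check_features(ph, "phenotype feature")
  }
  if (artifact_prob < 0 || artifact_prob > 1)
    stop_config("artifact_prob must lie in [0, 1]")

  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 window_hours = window_hours,
                 drift_onset = drift_onset,
                 drift_magnitudes = dm,
                 missingness = ms,
                 lab_interval_hours = lab_interval_hours,
                 vis_escalation_prob = vis_escalation_prob,
                 phenotypes = phenotypes,
                 artifact_prob = artifact_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic CICU cohort configuration\n")
  cat(sprintf("  %d cases : %d controls over %g h (drift onset %g h before arrest)\n",
              x$n_cases, x$n_controls, x$window_hours, x$drift_onset))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic CICU cohort
#'
#' Simulates long-format measurement series for `n_cases` arrest subjects and
#' `n_controls` controls. Vitals (and VIS and urine output) are charted on the
#' hourly grid `0:window_hours` with per-feature missingness; labs arrive at
#' irregular draws with mean spacing `lab_interval_hours`. Each observation is
#' population mean + per-subject random intercept + Gaussian noise. Case
#' series end at the arrest (anchor = `window_hours`) and carry an additive
#' piecewise-linear drift on the configured features over the final
#' `drift_onset` hours; VIS escalates as a step in a random fraction of cases.
#'
#' @param config A [cohort_config()].
#' @return A `cicu_cohort`: a long data.frame with columns `subject_id`,
#'   `label` ("arrest"/"control"), `time_h`, `feature`, `value`, carrying the
#'   config and window length as attributes.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_config("config must be a cohort_config object")
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  W <- config$window_hours
  base <- physiologic_baselines()
  rownames(base) <- base$feature
  pad <- function(n) formatC(seq_len(n), width = 4, flag = "0")
  ids <- c(paste0("case_", pad(config$n_cases)),
           paste0("ctrl_", pad(config$n_controls)))
  is_case <- c(rep(TRUE, config$n_cases), rep(FALSE, config$n_controls))
  n_subj <- length(ids)

  ramp <- function(t) pmax(0, pmin(1, (t - (W - config$drift_onset)) /
                                     config$drift_onset))

  # which features each subject's drift expresses through (phenotype OR)
  applies <- matrix(TRUE, n_subj, length(cicu_features()),
                    dimnames = list(NULL, cicu_features()))
  if (!is.null(config$phenotypes)) {
    pidx <- sample.int(length(config$phenotypes), n_subj, replace = TRUE)
    applies[] <- FALSE
    for (k in seq_along(config$phenotypes))
      applies[pidx == k, config$phenotypes[[k]]] <- TRUE
  }

  hourly <- setdiff(cicu_features(), c(lab_features(), "VIS"))
  hours <- 0:W
  out <- vector("list", 4L)

  # hourly channels: grid of subject x feature x hour, fully vectorized
  grid <- expand.grid(si = seq_len(n_subj), feature = hourly, h = hours,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  b <- base[grid$feature, ]
  intercepts <- matrix(stats::rnorm(n_subj * length(hourly),
                                    sd = base[hourly, "intercept_sd"]),
                       nrow = n_subj, ncol = length(hourly), byrow = TRUE,
                       dimnames = list(NULL, hourly))
  val <- b$mean + intercepts[cbind(grid$si, match(grid$feature, hourly))] +
    stats::rnorm(nrow(grid), sd = b$noise_sd) +
    ifelse(is_case[grid$si] &
             applies[cbind(grid$si, match(grid$feature, cicu_features()))],
           config$drift_magnitudes[grid$feature] * ramp(grid$h), 0)
  val <- pmin(pmax(val, b$lower), b$upper)
  # charting/probe artifacts: occasional values anywhere in the plausible range
  art <- stats::runif(nrow(grid)) < config$artifact_prob
  if (any(art))
    val[art] <- stats::runif(sum(art), b$lower[art], b$upper[art])
  keep <- stats::runif(nrow(grid)) >= config$missingness[grid$feature]
  out[[1L]] <- data.frame(subject_id = ids[grid$si[keep]],
                          time_h = as.numeric(grid$h[keep]),
                          feature = grid$feature[keep],
                          value = val[keep], stringsAsFactors = FALSE)

  # VIS: nonnegative step function, mostly zero; cases may escalate once
  # inside the drift window
  vis_base <- sample(c(0, 2.5, 5, 10), n_subj, replace = TRUE,
                     prob = c(0.75, 0.10, 0.10, 0.05))
  esc_mag <- config$drift_magnitudes[["VIS"]]
  escalates <- is_case & esc_mag > 0 & applies[, "VIS"] &
    stats::runif(n_subj) < config$vis_escalation_prob
  esc_time <- stats::runif(n_subj, W - config$drift_onset, W)
  vg <- expand.grid(si = seq_len(n_subj), h = hours,
                    KEEP.OUT.ATTRS = FALSE)
  vval <- vis_base[vg$si] +
    ifelse(escalates[vg$si] & vg$h >= esc_time[vg$si], esc_mag, 0)
  vkeep <- stats::runif(nrow(vg)) >= config$missingness[["VIS"]]
  out[[2L]] <- data.frame(subject_id = ids[vg$si[vkeep]],
                          time_h = as.numeric(vg$h[vkeep]),
                          feature = "VIS", value = vval[vkeep],
                          stringsAsFactors = FALSE)

  # labs at irregular draw times
  lab_rows <- lapply(lab_features(), function(f) {
    bf <- base[f, ]
    ic <- stats::rnorm(n_subj, sd = bf$intercept_sd)
    per_subj <- lapply(seq_len(n_subj), function(i) {
      t <- cumsum(c(stats::runif(1, 0, config$lab_interval_hours),
                    stats::rexp(ceiling(3 * W / config$lab_interval_hours) + 5,
                                rate = 1 / config$lab_interval_hours)))
      t <- t[t <= W]
      if (!length(t)) return(NULL)
      keep <- stats::runif(length(t)) >= config$missingness[[f]]
      t <- t[keep]
      if (!length(t)) return(NULL)
      v <- bf$mean + ic[i] + stats::rnorm(length(t), sd = bf$noise_sd) +
        if (is_case[i] && applies[i, f]) config$drift_magnitudes[[f]] * ramp(t)
        else 0
      data.frame(subject_id = ids[i], time_h = t, feature = f,
                 value = pmin(pmax(v, bf$lower), bf$upper),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_subj)
  })
  out[[3L]] <- do.call(rbind, lab_rows)

  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  df$label <- ifelse(startsWith(df$subject_id, "case_"), "arrest", "control")
  df <- df[order(df$subject_id, df$feature, df$time_h),
           c("subject_id", "label", "time_h", "feature", "value")]
  rownames(df) <- NULL
  as_cicu_cohort(df, window_hours = W, config = config)
}

as_cicu_cohort <- function(df, window_hours = NULL, config = NULL) {
  need <- c("subject_id", "label", "time_h", "feature", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  as_binary_label(df$label)  # validates
  if (any(df$time_h < 0) || any(!is.finite(df$value)))
    stop_validation("cohort values must be finite and times nonnegative")
  check_features(unique(df$feature))
  attr(df, "window_hours") <- window_hours %||% max(df$time_h)
  attr(df, "config") <- config
  class(df) <- c("cicu_cohort", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-subject anchor time: arrest time for cases, window end for controls.
# Generated cohorts anchor every subject at window_hours.
subject_anchors <- function(cohort) {
  W <- attr(cohort, "window_hours") %||% max(cohort$time_h)
  ids <- unique(cohort$subject_id)
  stats::setNames(rep(W, length(ids)), ids)
}

subject_labels <- function(cohort) {
  u <- !duplicated(cohort$subject_id)
  stats::setNames(as_binary_label(cohort$label[u]), cohort$subject_id[u])
}

cohort_subset <- function(cohort, ids) {
  out <- cohort[cohort$subject_id %in% ids, , drop = FALSE]
  attr(out, "window_hours") <- attr(cohort, "window_hours")
  attr(out, "config") <- attr(cohort, "config")
  class(out) <- class(cohort)
  out
}

#' @export
print.cicu_cohort <- function(x, ...) {
  lab <- subject_labels(x)
  cat(sprintf("CICU cohort: %d subjects (%d arrest, %d control), %d measurements\n",
              length(lab), sum(lab == 1), sum(lab == 0), nrow(x)))
  cat(sprintf("  window: %g h; features: %s\n",
              attr(x, "window_hours") %||% max(x$time_h),
              paste(sort(unique(x$feature)), collapse = ", ")))
  invisible(x)
}

#' @export
summary.cicu_cohort <- function(object, ...) {
  counts <- table(object$feature)
  lab <- subject_labels(object)
  structure(list(n_arrest = sum(lab == 1), n_control = sum(lab == 0),
                 n_obs = nrow(object), per_feature = counts),
            class = "summary.cicu_cohort")
}

#' @export
print.summary.cicu_cohort <- function(x, ...) {
  cat(sprintf("%d arrest / %d control subjects, %d observations\n",
              x$n_arrest, x$n_control, x$n_obs))
  print(x$per_feature)
  invisible(x)
}

#' Write / read a cohort as long-format CSV with a YAML sidecar
#'
#' The CSV holds `subject_id,label,time_h,feature,value`; the sidecar (same
#' path with extension `.yaml`) records the full generator config and seed so
#' a run is reproducible from its outputs alone.
#'
#' @param cohort A `cicu_cohort`.
#' @param path CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   `cicu_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  cfg <- attr(cohort, "config")
  side <- list(window_hours = attr(cohort, "window_hours"))
  if (!is.null(cfg)) side$config <- lapply(unclass(cfg), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(side, yaml_sidecar(path))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  W <- NULL
  if (file.exists(yaml_sidecar(path))) {
    side <- yaml::read_yaml(yaml_sidecar(path))
    W <- side$window_hours
  }
  as_cicu_cohort(df, window_hours = W)
}

yaml_sidecar <- function(path) paste0(sub("\\.csv$", "", path), ".yaml")
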