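# Feature vocabulary and small shared helpers.

#' Feature vocabulary
#'
#' The eleven charted variables the models consume: heart rate (HR),
#' diastolic blood pressure (DBP), pulse-oximetry saturation (SpO2),
#' end-tidal CO2 (ETCO2), inspired oxygen fraction (FiO2), cerebral and
#' somatic regional oximetry (rSO2c, rSO2s), anion gap, base excess, urine
#' output (mL/kg/h) and the vasoactive-inotrope score (VIS).
#'
#' @return Character vector of the eleven feature names.
#' @export
cicu_features <- function() {
  c("HR", "DBP", "SpO2", "ETCO2", "FiO2", "rSO2c", "rSO2s",
    "anion_gap", "base_excess", "urine_output", "VIS")
}

#' Features normalized to the first-4-hour baseline
#'
#' HR and DBP vary with age, and the saturation/oximetry channels vary with
#' cyanotic physiology, so these five channels are expressed as change from
#' each subject's own first four hours of data.
#'
#' @return Character vector of the five normalized feature names.
#' @export
normalized_features <- function() c("HR", "DBP", "SpO2", "rSO2c", "rSO2s")

# Laboratory features charted at irregular draws rather than hourly.
lab_features <- function() c("anion_gap", "base_excess")

bin_levels <- function() c("low", "mid", "high")

sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate expr with a temporarily seeded RNG; the caller's RNG state is
# restored afterwards so seeded calls are reproducible and side-effect free.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("cicuboost_config_error", "error", "condition")))
}

stop_vocab <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("cicuboost_vocab_error", "error", "condition")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("cicuboost_validation_error", "error", "condition")))
}

stop_metric <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("cicuboost_metric_error", "error", "condition")))
}

check_features <- function(features, what = "feature") {
  bad <- setdiff(features, cicu_features())
  if (length(bad))
    stop_vocab("unknown ", what, "(s): ", paste(bad, collapse = ", "),
               " (vocabulary: ", paste(cicu_features(), collapse = ", "), ")")
  invisible(features)
}

# Coerce labels ("arrest"/"control", factor, logical or 0/1) to integer 0/1.
as_binary_label <- function(label) {
  if (is.factor(label)) label <- as.character(label)
  if (is.character(label)) {
    bad <- setdiff(unique(label), c("arrest", "control"))
    if (length(bad)) stop_validation("unknown label value(s): ",
                                     paste(bad, collapse = ", "))
    return(as.integer(label == "arrest"))
  }
  if (is.logical(label)) return(as.integer(label))
  if (!all(label %in% c(0, 1))) stop_validation("labels must be 0/1")
  as.integer(label)
}
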