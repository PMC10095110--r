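# JSON round-trip for fitted models. Node tests are stored by
# (feature, tranche, bin) rather than by column index so a serialized model
# is self-describing; reloading must be prediction-identical.

tree_to_list <- function(tree, tests) {
  if (is.null(tree$test)) return(list(value = tree$value))
  list(feature = tests$feature[tree$test],
       tranche = tests$tranche[tree$test],
       bin = tests$bin[tree$test],
       left = tree_to_list(tree$left, tests),
       right = tree_to_list(tree$right, tests))
}

tree_from_list <- function(node, tests) {
  if (!is.null(node$value)) return(list(value = node$value))
  j <- which(tests$feature == node$feature & tests$tranche == node$tranche &
               tests$bin == node$bin)
  if (length(j) != 1) stop_validation("corrupt model file: unknown node test")
  list(test = tests$id[j],
       left = tree_from_list(node$left, tests),
       right = tree_from_list(node$right, tests))
}

#' Serialize / load a fitted model as JSON
#'
#' Writes the stacked tree blocks (node tests by feature/tranche/bin, leaf
#' increments), `psi0`, shrinkage, the temporal geometry and the fitted
#' discretization cut points. `read_model()` restores an object whose
#' predictions are identical to the original's.
#'
#' @param object A `stacked_fgb` (or bare `stacked_fgb_fit`).
#' @param path JSON file path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(object, path) {
  fit <- if (inherits(object, "stacked_fgb")) object$fit else object
  if (!inherits(fit, "stacked_fgb_fit"))
    stop_validation("object must be a stacked_fgb or stacked_fgb_fit")
  payload <- list(
    format = "cicuboost_stacked_fgb",
    version = 1L,
    psi0 = fit$psi0,
    shrinkage = fit$shrinkage,
    trees_per_tranche = fit$trees_per_tranche,
    tranche_hours = fit$tranche_hours,
    n_tranches = fit$n_tranches,
    window_hours = fit$window_hours,
    features = fit$scheme$features,
    cuts = fit$scheme$cuts,
    blocks = lapply(fit$blocks, function(blk)
      lapply(blk, tree_to_list, tests = fit$tests))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(p$format) || p$format != "cicuboost_stacked_fgb")
    stop_validation("not a cicuboost model file: ", path)
  features <- unlist(p$features)
  cuts <- lapply(p$cuts, function(q) if (is.null(q)) NULL else unlist(q))
  names(cuts) <- names(p$cuts)
  scheme <- structure(list(cuts = cuts[features], features = features),
                      class = "discretization_scheme")
  tests <- candidate_tests(features, p$n_tranches)
  fit <- structure(list(
    blocks = lapply(p$blocks, function(blk)
      lapply(blk, tree_from_list, tests = tests)),
    tests = tests, psi0 = p$psi0, shrinkage = p$shrinkage,
    trees_per_tranche = p$trees_per_tranche,
    tranche_hours = p$tranche_hours, n_tranches = p$n_tranches,
    window_hours = p$window_hours, scheme = scheme),
    class = "stacked_fgb_fit")
  structure(list(fit = fit, scheme = scheme, features = features,
                 n_subjects = NA_integer_, n_arrest = NA_integer_,
                 call = quote(read_model())),
            class = "stacked_fgb")
}
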