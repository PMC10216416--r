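# JSON round-trips for configurations and fitted models.

#' Read a cohort configuration from JSON
#'
#' The file holds the [cohort_config()] fields by name; missing fields take
#' the defaults.
#'
#' @param path JSON file path.
#' @return a `cohort_config`.
#' @export
cohort_config_from_json <- function(path) {
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(cohort_config))
  unknown <- setdiff(names(fields), allowed)
  assert_that(length(unknown) == 0,
              paste("unknown cohort_config fields:", paste(unknown, collapse = ", ")))
  do.call(cohort_config, fields)
}

#' Read an experiment configuration from JSON
#'
#' The `cohort` entry is either a nested object of [cohort_config()] fields
#' or a manifest path string; the remaining entries are
#' [experiment_config()] fields.
#'
#' @param path JSON file path.
#' @return an `experiment_config`.
#' @export
experiment_config_from_json <- function(path) {
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(!is.null(fields$cohort), "config must have a 'cohort' entry")
  if (!is.character(fields$cohort)) {
    fields$cohort <- do.call(cohort_config, as.list(fields$cohort))
  }
  allowed <- names(formals(experiment_config))
  unknown <- setdiff(names(fields), allowed)
  assert_that(length(unknown) == 0,
              paste("unknown experiment_config fields:", paste(unknown, collapse = ", ")))
  do.call(experiment_config, fields)
}

#' Serialise a fitted model with a JSON sidecar
#'
#' Writes the model to `path` (RDS) and a human-readable sidecar
#' `<path>.json` with the hyperparameter configuration, the fitting seed and
#' the feature-name manifest, so predictions are replayable and auditable.
#'
#' @param model a [fit_model()] result.
#' @param path output RDS path.
#' @param seed the seed the model was fitted with (stored for the record).
#' @return `path`, invisibly.
#' @export
save_fitted_model <- function(model, path, seed = NA_integer_) {
  stopifnot(inherits(model, "fitted_model"))
  saveRDS(model, path)
  jsonlite::write_json(
    list(hyperparameters = model$hp, seed = seed,
         features = model$columns,
         pca_components = if (is.null(model$pca)) NULL else model$pca$L),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a serialised fitted model
#'
#' @param path RDS path written by [save_fitted_model()].
#' @return the `fitted_model`.
#' @export
load_fitted_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "fitted_model"))
  model
}
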