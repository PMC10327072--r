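#' CSV schemas for study tables
#'
#' Long-format schemas shared by the generator, the simulator and the
#' regression battery:
#' * `ratings.csv`: `participant`, `product`, `rating`
#' * `trials.csv`: `participant`, `trial`, `condition`, `framing`,
#'   `v1..v4`, `rt`, `choice`, `accuracy`, `omitted`, `kept_mask`
#'   (RT in seconds for behavioral tables; raw LCA batch tables are in
#'   simulation time units)
#' * `conflict.csv`: `participant`, `trial`, `conflict`
#'
#' Readers validate the schema and name any missing column; writers
#' round-trip values at full precision.
#'
#' @param x Table to write.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name study_io
NULL

schema_trials <- c("participant", "trial", "condition", "framing",
                   paste0("v", 1:4), "rt", "choice", "accuracy", "omitted",
                   "kept_mask")
schema_ratings <- c("participant", "product", "rating")
schema_conflict <- c("participant", "trial", "conflict")

check_schema <- function(x, schema, what) {
  miss <- setdiff(schema, names(x))
  if (length(miss)) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @rdname study_io
#' @export
write_trials <- function(x, path) {
  check_schema(x, schema_trials, "trials table")
  readr::write_csv(x[, union(schema_trials, names(x))], path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_trials <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         participant = readr::col_character(),
                         condition = readr::col_character(),
                         framing = readr::col_character(),
                         kept_mask = readr::col_character(),
                         .default = readr::col_guess()))
  check_schema(x, schema_trials, "trials table")
  x
}

#' @rdname study_io
#' @export
write_ratings <- function(x, path) {
  check_schema(x, schema_ratings, "ratings table")
  readr::write_csv(x[, union(schema_ratings, names(x))], path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_ratings <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         participant = readr::col_character(),
                         .default = readr::col_guess()))
  check_schema(x, schema_ratings, "ratings table")
  x
}

#' @rdname study_io
#' @export
write_conflict <- function(x, path) {
  check_schema(x, schema_conflict, "conflict table")
  readr::write_csv(x[, schema_conflict], path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_conflict <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         participant = readr::col_character(),
                         .default = readr::col_guess()))
  check_schema(x, schema_conflict, "conflict table")
  x
}

#' Run configuration
#'
#' Bundles everything one pipeline run needs: the top-level seed, the
#' study design, the condition-to-parameter map, model flags and grid
#' settings. Fully serialisable to YAML, so a saved config reproduces a
#' run exactly. Per-stage RNG streams are derived from the single seed by
#' fixed offsets (generate +0, simulate +1, identify +2, recover +3) so
#' partial re-runs stay reproducible.
#'
#' @param seed Integer top-level seed.
#' @param design A [design_spec] (or a list of its fields).
#' @param params_by_condition Named list of [lca_params] per condition.
#' @param log_rt Model log RT in the battery?
#' @param conflict_covariates Add RT/accuracy covariates to the conflict
#'   model?
#' @param grid Optional named list of grid value vectors for the
#'   identification stage.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1, design = design_spec(),
                       params_by_condition = default_condition_params(),
                       log_rt = FALSE, conflict_covariates = FALSE,
                       grid = NULL) {
  stopifnot(inherits(design, "design_spec"))
  structure(list(seed = as.integer(seed), design = design,
                 params_by_condition = params_by_condition,
                 log_rt = isTRUE(log_rt),
                 conflict_covariates = isTRUE(conflict_covariates),
                 grid = grid),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(x, path) {
  stopifnot(inherits(x, "run_config"))
  obj <- list(
    seed = x$seed,
    design = unclass(x$design),
    params_by_condition = lapply(x$params_by_condition, unclass),
    log_rt = x$log_rt,
    conflict_covariates = x$conflict_covariates,
    grid = x$grid
  )
  obj$design$conflict_coefs <- as.list(x$design$conflict_coefs)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  for (f in c("seed", "design", "params_by_condition")) {
    if (is.null(obj[[f]])) {
      stop("run config is missing required field: ", f, call. = FALSE)
    }
  }
  des <- obj$design
  des$conflict_coefs <- unlist(des$conflict_coefs)
  des$bad_participants <- as.character(des$bad_participants %||% character(0))
  design <- do.call(design_spec, des[intersect(names(des),
                                               names(formals(design_spec)))])
  params <- lapply(obj$params_by_condition,
                   function(p) do.call(lca_params, p))
  run_config(seed = obj$seed, design = design,
             params_by_condition = params,
             log_rt = isTRUE(obj$log_rt),
             conflict_covariates = isTRUE(obj$conflict_covariates),
             grid = obj$grid)
}

#' @rdname run_config
#' @export
config_hash <- function(x) {
  stopifnot(inherits(x, "run_config"))
  rlang::hash(list(x$seed, unclass(x$design),
                   lapply(x$params_by_condition, unclass), x$log_rt,
                   x$conflict_covariates, x$grid))
}
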