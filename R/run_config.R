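# Single-config orchestration: a YAML (or list) run configuration
# drives training and/or prediction end to end.

#' Run the pipeline from a configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' fields:
#' \describe{
#'   \item{mode}{`"train"`, `"predict"` or `"train+predict"`.}
#'   \item{tables}{feature-table TSV paths (training).}
#'   \item{structures}{PDB paths (prediction).}
#'   \item{model}{saved model directory (prediction without training).}
#'   \item{out_dir}{output directory (required).}
#'   \item{profile}{`"fast"` (default) or `"paper"`.}
#'   \item{n_trees, depth_grid, cv_folds}{optional overrides of the
#'     profile's boosting parameters.}
#'   \item{n_members}{ensemble size, default 10.}
#'   \item{seed}{base seed, default 1.}
#'   \item{threshold}{SHB call threshold, default 0.870.}
#'   \item{place_h}{place polar hydrogens before detection, default FALSE.}
#' }
#'
#' @param config path to a YAML file, or a named list.
#' @return list with the reports (and model) of the executed stages.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  mode <- config$mode %||% "train+predict"
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("usage error: config needs an out_dir")
  params <- shb_params(config$profile %||% "fast",
                       n_trees = config$n_trees,
                       depth_grid = config$depth_grid,
                       cv_folds = config$cv_folds)
  seed <- as.integer(config$seed %||% 1L)
  out <- list()
  model <- NULL
  if (grepl("train", mode)) {
    if (is.null(config$tables)) stop("usage error: train mode needs tables")
    missing <- config$tables[!file.exists(config$tables)]
    if (length(missing) > 0)
      stop("usage error: missing input file(s): ", paste(missing, collapse = ", "))
    tr <- run_train(unlist(config$tables), out_dir = out_dir, params = params,
                    n_members = as.integer(config$n_members %||% 10L),
                    seed = seed)
    model <- tr$model
    out$train <- tr$report
  }
  if (grepl("predict", mode)) {
    if (is.null(model)) {
      if (is.null(config$model)) stop("usage error: predict mode needs a model")
      model <- load_shb_model(config$model)
    }
    pr <- run_predict(model, unlist(config$structures), out_dir = out_dir,
                      threshold = as.numeric(config$threshold %||% 0.870),
                      place_h = isTRUE(config$place_h))
    out$predict <- pr$report
  }
  out$model <- model
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
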