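# Persistence of fitted ensembles: a directory holding one JSON model
# file per member plus a schema-versioned JSON manifest carrying the
# encoding map, hyperparameters, seeds, chosen depths and importances.

.MODEL_SCHEMA_VERSION <- 1L

#' Save / load a fitted ensemble
#'
#' `save_shb_model` writes each boosted-tree member as a JSON model
#' file (`member_01.json`, ...) plus `manifest.json` with the encoding
#' map, parameters, member seeds, chosen depths and importance table,
#' so a saved model is fully reproducible and inspectable.
#'
#' @param object a fitted `shb_ensemble`.
#' @param dir directory to create/write.
#' @return `save_shb_model` returns `dir` invisibly; `load_shb_model`
#'   returns the restored `shb_ensemble`.
#' @export
save_shb_model <- function(object, dir) {
  stopifnot(inherits(object, "shb_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("member_%02d.json", seq_len(object$n_members))
  for (i in seq_len(object$n_members))
    xgboost::xgb.save(object$members[[i]], file.path(dir, files[i]))
  manifest <- list(
    schema_version = .MODEL_SCHEMA_VERSION,
    package = "shbpred",
    n_members = object$n_members,
    member_files = files,
    params = unclass(object$params),
    seed = object$seed,
    member_seeds = object$member_seeds,
    depths = object$depths,
    class_counts = as.list(object$class_counts),
    importance = object$importance,
    per_member_importance = object$per_member_importance,
    map = object$map)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_shb_model
#' @export
load_shb_model <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a model directory (no manifest.json): ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (manifest$schema_version > .MODEL_SCHEMA_VERSION)
    stop("model schema version ", manifest$schema_version, " is newer than ",
         "this package supports (", .MODEL_SCHEMA_VERSION, ")")
  members <- lapply(manifest$member_files, function(f)
    xgboost::xgb.load(file.path(dir, f)))
  params <- do.call(shb_params, manifest$params[c("profile", "shrinkage",
                                                  "n_trees", "depth_grid",
                                                  "cv_folds", "bag_fraction",
                                                  "cv_metric")])
  structure(list(members = members,
                 map = as.list(manifest$map),
                 params = params,
                 n_members = manifest$n_members,
                 seed = manifest$seed,
                 member_seeds = manifest$member_seeds,
                 depths = manifest$depths,
                 cv = NULL,
                 importance = as.data.frame(manifest$importance),
                 per_member_importance = manifest$per_member_importance,
                 class_counts = unlist(manifest$class_counts),
                 call = NULL),
            class = "shb_ensemble")
}
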