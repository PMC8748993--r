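# End-to-end orchestration: structures -> detection -> features ->
# train/predict, with JSON run reports for provenance.  Data outputs
# are TSV; the only non-flat artifact is the saved model directory.

#' Train an ensemble from labeled feature tables
#'
#' Reads and validates the labeled tables, fits the undersampling
#' ensemble, persists the model directory and writes a JSON run report
#' with class counts, member seeds and chosen depths.
#'
#' @param tables character vector of feature-table TSV paths, or a
#'   single `shb_dataset`.
#' @param out_dir output directory; the model is saved under
#'   `<out_dir>/model` and the report as `<out_dir>/train_report.json`.
#'   `NULL` skips writing.
#' @param params an [shb_params()] object.
#' @param n_members ensemble size.
#' @param seed base seed.
#' @return list with `model` (the fitted `shb_ensemble`) and `report`.
#' @export
run_train <- function(tables, out_dir = NULL, params = shb_params(),
                      n_members = 10L, seed = 1L) {
  data <- if (inherits(tables, "shb_dataset")) tables
  else {
    parts <- lapply(tables, read_dataset)
    as_shb_dataset(do.call(rbind, lapply(parts, as.data.frame)),
                   provenance = unlist(lapply(parts, attr, "provenance")))
  }
  counts <- table(factor(data$label, levels = c("SHB", "NHB")))
  if (any(counts == 0))
    stop("training table has a single class (SHB=", counts[["SHB"]],
         ", NHB=", counts[["NHB"]], "); both classes are required")
  model <- shb_ensemble(data, params = params, n_members = n_members, seed = seed)
  report <- list(stage = "train",
                 n_rows = nrow(data),
                 class_counts = as.list(counts),
                 n_members = model$n_members,
                 member_seeds = model$member_seeds,
                 depths = model$depths,
                 params = unclass(params),
                 importance = model$importance,
                 package_version = as.character(utils::packageVersion("shbpred")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_shb_model(model, file.path(out_dir, "model"))
    jsonlite::write_json(report, file.path(out_dir, "train_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(model = model, report = report)
}

#' Predict SHBs in protein structures
#'
#' For each structure: read (if a path), optionally place polar
#' hydrogens, assign secondary structure, detect hydrogen bonds,
#' extract features and compute the ensemble probability of each bond
#' being an SHB with its class at the configured threshold.
#' Per-structure failures are isolated and logged; the run fails only
#' if every structure fails.
#'
#' @param model a fitted `shb_ensemble` or a saved model directory.
#' @param structures character vector of PDB paths or list of
#'   `protein_structure` objects.
#' @param out_dir optional output directory for `predictions.tsv` and
#'   `predict_report.json`.
#' @param threshold probability threshold for the SHB call (default
#'   0.870, the recommended operating point).
#' @param place_h add idealized polar hydrogens before detection.
#' @return list with `predictions` (data frame: bond identity,
#'   geometry, features, `prob`, `class`) and `report` (per-stage
#'   counts).
#' @export
run_predict <- function(model, structures, out_dir = NULL,
                        threshold = 0.870, place_h = FALSE) {
  if (is.character(model)) model <- load_shb_model(model)
  stopifnot(inherits(model, "shb_ensemble"))
  if (length(structures) == 0)
    stop("usage error: no input structures given")
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  preds <- list(); failures <- character()
  n_detected <- 0L; n_labeled <- 0L; n_read <- 0L
  for (item in structures) {
    res <- tryCatch({
      s <- if (is.character(item)) read_structure(item) else item
      n_read <- n_read + 1L
      if (place_h) s <- place_polar_hydrogens(s)
      s <- assign_secondary_structure(s)
      rec <- detect_hydrogen_bonds(s)
      n_detected <- n_detected + nrow(rec)
      n_labeled <- n_labeled + sum(rec$label != "unlabeled")
      if (nrow(rec) == 0) return_df <- NULL
      else {
        fv <- extract_features(rec, s)
        prob <- predict(model, fv, type = "prob")
        return_df <- cbind(rec[, c("structure_id", "chain_d", "resi_d", "resn_d",
                                   "atom_d", "chain_a", "resi_a", "resn_a",
                                   "atom_a", "acceptor_location", "R", "angle",
                                   "label")],
                           prob = round(prob, 3),
                           class = classify_shb(prob, threshold))
      }
      return_df
    }, error = function(e) {
      failures <<- c(failures, paste0(if (is.character(item)) item else "structure",
                                      ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) preds[[length(preds) + 1L]] <- res
  }
  if (length(failures) == length(structures))
    stop("all structures failed:\n  ", paste(failures, collapse = "\n  "))
  if (length(failures) > 0)
    warning(length(failures), " structure(s) failed: ",
            paste(failures, collapse = "; "))
  predictions <- if (length(preds) > 0) do.call(rbind, preds)
  else data.frame()
  report <- list(stage = "predict",
                 n_structures = length(structures),
                 n_read = n_read,
                 n_failed = length(failures),
                 failures = failures,
                 n_records_detected = n_detected,
                 n_records_labeled = n_labeled,
                 threshold = threshold,
                 n_predicted_shb = if (nrow(predictions) > 0)
                   sum(predictions$class == "SHB") else 0L,
                 package_version = as.character(utils::packageVersion("shbpred")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(predictions, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "predict_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(predictions = predictions, report = report)
}
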