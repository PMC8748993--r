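# The undersampling ensemble of gradient-boosted tree classifiers.
#
# Training follows the five-step workflow: (1) sample a subset of NHBs
# equal in size to the SHBs, (2) combine it with all SHBs into a
# balanced set, (3) fit a boosted-tree model (interaction depth chosen
# by stratified cross-validation minimizing binomial deviance), (4)
# repeat to obtain n_members models, (5) average their probabilities.
# Boosted trees are fit stagewise to the gradient of the binomial
# deviance via xgboost (binary:logistic) with the configured shrinkage,
# stage count, depth and bag fraction.

#' Boosting hyperparameters
#'
#' The `"paper"` profile uses shrinkage 0.01, 5000 trees, interaction
#' depths 1..15 tuned by 10-fold cross-validation and a bag fraction of
#' 0.5.  The `"fast"` profile (500 trees, depths 1..6, 5 folds) keeps
#' the same learning dynamics at desk scale and is the default.
#'
#' @param profile `"fast"` or `"paper"`.
#' @param shrinkage learning rate per stage, in (0, 1].
#' @param n_trees number of boosting stages.
#' @param depth_grid candidate interaction depths (max tree depth),
#'   within 1..15.
#' @param cv_folds cross-validation folds (>= 2).
#' @param bag_fraction row subsampling per stage.
#' @param cv_metric `"deviance"` (binomial deviance, the boosting loss;
#'   default) or `"error"` (misclassification rate).
#' @return an object of class `shb_params`.
#' @export
shb_params <- function(profile = c("fast", "paper"), shrinkage = 0.01,
                       n_trees = NULL, depth_grid = NULL, cv_folds = NULL,
                       bag_fraction = 0.5,
                       cv_metric = c("deviance", "error")) {
  profile <- match.arg(profile)
  cv_metric <- match.arg(cv_metric)
  if (is.null(n_trees)) n_trees <- if (profile == "paper") 5000L else 500L
  if (is.null(depth_grid)) depth_grid <- if (profile == "paper") 1:15 else 1:6
  if (is.null(cv_folds)) cv_folds <- if (profile == "paper") 10L else 5L
  if (!(shrinkage > 0 && shrinkage <= 1)) stop("shrinkage must be in (0, 1]")
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (any(depth_grid < 1 | depth_grid > 15)) stop("depths must lie in 1..15")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (!(bag_fraction > 0 && bag_fraction <= 1)) stop("bag_fraction must be in (0, 1]")
  structure(list(profile = profile, shrinkage = shrinkage,
                 n_trees = as.integer(n_trees),
                 depth_grid = sort(unique(as.integer(depth_grid))),
                 cv_folds = as.integer(cv_folds),
                 bag_fraction = bag_fraction, cv_metric = cv_metric),
            class = "shb_params")
}

#' @export
print.shb_params <- function(x, ...) {
  cat(sprintf(paste0("<shb_params> profile=%s: shrinkage %.3g, %d trees, ",
                     "depths %d..%d, %d-fold CV (%s), bag fraction %.2f\n"),
              x$profile, x$shrinkage, x$n_trees, min(x$depth_grid),
              max(x$depth_grid), x$cv_folds, x$cv_metric, x$bag_fraction))
  invisible(x)
}

label01 <- function(label) {
  if (is.numeric(label)) {
    stopifnot(all(label %in% c(0, 1)))
    return(as.integer(label))
  }
  stopifnot(all(label %in% c("SHB", "NHB")))
  as.integer(label == "SHB")
}

#' Undersample the majority class
#'
#' Keeps every SHB row and a uniform random without-replacement sample
#' of NHB rows of the same size, producing a balanced dataset.
#' Deterministic given `seed`.
#'
#' @param d an `shb_dataset` (or data frame with a `label` column)
#'   containing both classes with NHB in the majority.
#' @param seed integer seed for the NHB draw.
#' @return the balanced dataset with equal class counts.
#' @export
undersample_dataset <- function(d, seed) {
  y <- label01(d$label)
  i_shb <- which(y == 1L); i_nhb <- which(y == 0L)
  if (length(i_shb) == 0 || length(i_nhb) == 0)
    stop("undersampling requires both classes; counts: SHB=", length(i_shb),
         " NHB=", length(i_nhb))
  if (length(i_nhb) < length(i_shb))
    stop("balance error: undersampling assumes NHB majority (SHB=",
         length(i_shb), ", NHB=", length(i_nhb), ")")
  set.seed(seed)
  pick <- sort(sample(i_nhb, length(i_shb)))
  out <- d[c(i_shb, pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

binomial_deviance <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

xgb_fit <- function(x, y, depth, params, seed, n_trees = params$n_trees) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eta = params$shrinkage,
                  max_depth = as.integer(depth),
                  subsample = params$bag_fraction,
                  tree_method = "hist",
                  nthread = 1L,
                  seed = as.integer(seed %% .Machine$integer.max)),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
    nrounds = n_trees, verbose = 0)
}

make_stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Choose the interaction depth by cross-validation
#'
#' For each candidate depth, fits the boosting model on `cv_folds`
#' stratified folds and records the mean held-out binomial deviance
#' (or misclassification rate); returns the depth minimizing it, ties
#' broken by the smallest depth.  A degenerate fold (a single class)
#' triggers a re-draw of the folds with a new seed.
#'
#' @param x encoded feature matrix (from [encode_features()]).
#' @param y 0/1 labels (1 = SHB).
#' @param params an [shb_params()] object.
#' @param seed integer seed for fold assignment.
#' @return list with `depth` (chosen value) and `cv` (data frame of
#'   depth vs mean validation loss).
#' @export
tune_interaction_depth <- function(x, y, params = shb_params(), seed = 1) {
  stopifnot(length(unique(y)) == 2)
  k <- params$cv_folds
  fold <- make_stratified_folds(y, k, seed)
  for (redraw in 1:10) {
    degen <- any(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) < 2 || sum(fold == f) == 0, logical(1)))
    if (!degen) break
    message("degenerate CV fold; re-drawing folds")
    fold <- make_stratified_folds(y, k, seed + redraw)
  }
  fold_losses <- vapply(params$depth_grid, function(depth) {
    vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- xgb_fit(x[tr, , drop = FALSE], y[tr], depth, params,
                   seed = seed * 1000L + depth * 100L + f)
      p <- predict(m, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE], nthread = 1L))
      if (params$cv_metric == "deviance") binomial_deviance(y[!tr], p)
      else mean((p >= 0.5) != y[!tr])
    }, numeric(1))
  }, numeric(k))
  fold_losses <- matrix(fold_losses, nrow = k)
  losses <- colMeans(fold_losses)
  cv <- data.frame(depth = params$depth_grid, loss = losses,
                   se = apply(fold_losses, 2, stats::sd) / sqrt(k))
  list(depth = params$depth_grid[which.min(losses)], cv = cv)
}

member_importance <- function(model, map) {
  imp <- xgboost::xgb.importance(model = model)
  parent <- sub("=.*$", "", imp$Feature)
  gain <- tapply(imp$Gain, parent, sum)
  out <- setNames(numeric(length(map)), names(map))
  out[names(gain)] <- gain
  if (sum(out) > 0) out <- 100 * out / sum(out)
  out
}

#' Fit the undersampling ensemble of boosted-tree classifiers
#'
#' The main fitting function.  Each of the `n_members` members is
#' trained on an independent balanced undersample of the data (member
#' `i` uses `seed + i`), with its interaction depth chosen by
#' stratified cross-validation and the model then refit on the whole
#' balanced set.  The ensemble probability of any row is the unweighted
#' mean of the member probabilities.
#'
#' @param data an `shb_dataset` (21 feature columns + `label`), either
#'   imbalanced or balanced.
#' @param params an [shb_params()] object.
#' @param n_members number of ensemble members (default 10).
#' @param seed base integer seed; member seeds are `seed + 1 .. seed +
#'   n_members` and are recorded in the fitted object.
#' @param depth fix the interaction depth and skip cross-validation
#'   (`NULL`, the default, tunes it per member).
#' @param trace print per-member progress.
#' @return an object of class `shb_ensemble` with elements `members`
#'   (xgboost handles), `map` (encoding map), `params`,
#'   `member_seeds`, `depths`, `cv` (per-member CV tables),
#'   `importance` (21-feature percentage table), and `class_counts`.
#' @seealso [predict.shb_ensemble()], [feature_importance()],
#'   [threshold_table()]
#' @export
shb_ensemble <- function(data, params = shb_params(), n_members = 10L,
                         seed = 1L, depth = NULL, trace = FALSE) {
  if (!inherits(data, "shb_dataset")) data <- as_shb_dataset(data)
  if (n_members < 1) stop("n_members must be >= 1")
  y_all <- label01(data$label)
  if (length(unique(y_all)) < 2)
    stop("training requires both classes; counts: SHB=", sum(y_all == 1L),
         " NHB=", sum(y_all == 0L))
  map <- default_encoding_map()
  members <- vector("list", n_members)
  depths <- integer(n_members)
  cvs <- vector("list", n_members)
  imp <- matrix(0, n_members, length(map),
                dimnames = list(NULL, names(map)))
  member_seeds <- seed + seq_len(n_members)
  for (i in seq_len(n_members)) {
    bal <- undersample_dataset(data, member_seeds[i])
    x <- encode_features(bal, map)
    y <- label01(bal$label)
    if (is.null(depth)) {
      tuned <- tune_interaction_depth(x, y, params, seed = member_seeds[i])
      depths[i] <- tuned$depth
      cvs[[i]] <- tuned$cv
    } else depths[i] <- as.integer(depth)
    members[[i]] <- xgb_fit(x, y, depths[i], params, seed = member_seeds[i])
    imp[i, ] <- member_importance(members[[i]], map)
    if (trace)
      message(sprintf("member %d/%d: depth %d (n=%d balanced)",
                      i, n_members, depths[i], nrow(bal)))
  }
  importance <- data.frame(feature = names(map),
                           importance = colMeans(imp),
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$importance), ]
  rownames(importance) <- NULL
  structure(list(members = members, map = map, params = params,
                 n_members = n_members, seed = seed,
                 member_seeds = member_seeds, depths = depths, cv = cvs,
                 importance = importance, per_member_importance = imp,
                 class_counts = c(SHB = sum(y_all == 1L), NHB = sum(y_all == 0L)),
                 call = match.call()),
            class = "shb_ensemble")
}

#' Predict SHB probabilities or classes
#'
#' @param object a fitted `shb_ensemble`.
#' @param newdata data frame with the 21 feature columns (an
#'   `shb_dataset`, feature table, or output of [extract_features()]).
#' @param type `"prob"` (ensemble mean probability), `"class"`
#'   (`"SHB"`/`"NHB"` at `threshold`) or `"members"` (matrix of
#'   per-member probabilities).
#' @param threshold probability threshold for `type = "class"`; a bond
#'   is predicted SHB when its probability is greater or equal to the
#'   threshold.  Default 0.870, the recommended operating point.
#' @param ... unused.
#' @return numeric vector in \[0, 1\], character vector, or matrix.
#' @export
predict.shb_ensemble <- function(object, newdata,
                                 type = c("prob", "class", "members"),
                                 threshold = 0.870, ...) {
  type <- match.arg(type)
  x <- encode_features(newdata, object$map)
  dm <- xgboost::xgb.DMatrix(x, nthread = 1L)
  pm <- vapply(object$members, function(m) predict(m, dm),
               numeric(nrow(newdata)))
  pm <- matrix(pm, nrow = nrow(newdata))
  if (type == "members") return(pm)
  p <- rowMeans(pm)
  if (type == "prob") p else classify_shb(p, threshold)
}

#' Threshold a probability into SHB/NHB
#'
#' @param prob probabilities in \[0, 1\].
#' @param threshold cutoff; SHB iff `prob >= threshold` (inclusive).
#' @return character vector of `"SHB"`/`"NHB"`.
#' @export
classify_shb <- function(prob, threshold = 0.870) {
  stopifnot(threshold >= 0, threshold <= 1)
  ifelse(prob >= threshold, "SHB", "NHB")
}

#' @export
print.shb_ensemble <- function(x, ...) {
  cat(sprintf("<shb_ensemble> %d members, depths [%s]\n", x$n_members,
              paste(x$depths, collapse = ", ")))
  cat(sprintf("  trained on %d SHB / %d NHB (balanced undersamples of %d each)\n",
              x$class_counts["SHB"], x$class_counts["NHB"],
              min(x$class_counts)))
  cat("  top features: ",
      paste(sprintf("%s %.1f%%", utils::head(x$importance$feature, 3),
                    utils::head(x$importance$importance, 3)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.shb_ensemble <- function(object, ...) {
  print(object)
  cat("\nFeature importance (%):\n")
  print(feature_importance(object), row.names = FALSE)
  invisible(object)
}

#' Aggregated split-gain feature importance
#'
#' Per-member split-gain (Gain) importances of the one-hot columns are
#' summed to their 21 parent features, normalized to 100% per member,
#' then averaged (unweighted) across members.  With `group_other =
#' TRUE` features contributing at most 1% are collapsed into an
#' `"other"` row.
#'
#' @param object a fitted `shb_ensemble`.
#' @param group_other collapse features <= 1% into `"other"`.
#' @param ... unused.
#' @return data frame with columns `feature` and `importance`
#'   (percentages summing to 100).
#' @export
feature_importance <- function(object, ...) UseMethod("feature_importance")

#' @rdname feature_importance
#' @export
feature_importance.shb_ensemble <- function(object, group_other = FALSE, ...) {
  imp <- object$importance
  if (group_other && any(imp$importance <= 1)) {
    small <- imp$importance <= 1
    imp <- rbind(imp[!small, ],
                 data.frame(feature = "other",
                            importance = sum(imp$importance[small])))
    rownames(imp) <- NULL
  }
  imp
}

#' @export
plot.shb_ensemble <- function(x, ...) {
  imp <- feature_importance(x, group_other = TRUE)
  op <- graphics::par(mar = c(4, 7, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(imp$importance), names.arg = rev(imp$feature),
                    horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "importance (%)",
                    main = "Ensemble feature importance", ...)
  invisible(x)
}

#' Precision and recall at a probability threshold
#'
#' Precision is the proportion of true SHBs among predicted SHBs
#' (reported `NA` when nothing is predicted SHB); recall is the
#' proportion of SHBs recovered.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 or `"SHB"`/`"NHB"` true labels.
#' @param threshold probability cutoff (SHB iff `prob >= threshold`).
#' @return one-row data frame: `threshold`, `precision` (%), `recall`
#'   (%), `n_predicted_shb`.
#' @export
precision_recall <- function(probs, labels, threshold) {
  y <- label01(labels)
  pred <- probs >= threshold
  tp <- sum(pred & y == 1L); fp <- sum(pred & y == 0L); fn <- sum(!pred & y == 1L)
  data.frame(threshold = threshold,
             precision = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp),
             recall = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
             n_predicted_shb = tp + fp)
}

#' Precision/recall table over a threshold grid
#'
#' @param probs predicted probabilities.
#' @param labels true labels.
#' @param thresholds probability grid; the default spans the operating
#'   range from precision-oriented (0.996) to recall-oriented (0.062)
#'   around the recommended 0.870.
#' @return data frame with one row per threshold.
#' @export
threshold_table <- function(probs, labels,
                            thresholds = c(0.996, 0.979, 0.943, 0.870,
                                           0.740, 0.555, 0.062)) {
  out <- do.call(rbind, lapply(thresholds, function(t)
    precision_recall(probs, labels, t)))
  rownames(out) <- NULL
  out
}

#' Smallest threshold achieving a target precision
#'
#' Scans the observed probability values and returns the smallest one
#' whose precision is at least `target_precision`, with its metrics;
#' `NA` if unattainable.
#'
#' @param probs predicted probabilities.
#' @param labels true labels.
#' @param target_precision target precision in percent, in (0, 100].
#' @return one-row data frame as in [precision_recall()] (all `NA` when
#'   the target is unattainable).
#' @export
find_threshold_for_precision <- function(probs, labels, target_precision) {
  if (!(target_precision > 0 && target_precision <= 100))
    stop("target_precision must be in (0, 100]")
  cand <- sort(unique(probs))
  for (t in cand) {
    m <- precision_recall(probs, labels, t)
    if (!is.na(m$precision) && m$precision >= target_precision) return(m)
  }
  data.frame(threshold = NA_real_, precision = NA_real_, recall = NA_real_,
             n_predicted_shb = NA_integer_)
}

#' Odds ratio between two probabilities
#'
#' `(p1/(1-p1)) / (p2/(1-p2))`.
#'
#' @param p1,p2 probabilities strictly inside (0, 1).
#' @return the odds ratio (unrounded).
#' @examples
#' round(odds_ratio(0.32, 0.11), 1)  # 3.8
#' round(odds_ratio(0.65, 0.23), 1)  # 6.2
#' @export
odds_ratio <- function(p1, p2) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1))
    stop("probabilities must lie strictly inside (0, 1)")
  (p1 / (1 - p1)) / (p2 / (1 - p2))
}

#' Correct balanced-training probabilities to a target prevalence
#'
#' The ensemble is trained on balanced data, so its probabilities are
#' calibrated to a 50% prior.  This optional correction maps them to a
#' population prevalence `pi`:
#' `p' = p*pi / (p*pi + (1-p)*(1-pi))`.  It is OFF by default
#' throughout the package because the recommended thresholds are
#' defined on uncorrected outputs.
#'
#' @param p probabilities from the balanced-trained model.
#' @param prevalence true SHB prevalence in (0, 1).
#' @return corrected probabilities.
#' @export
prior_correction <- function(p, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  p * prevalence / (p * prevalence + (1 - p) * (1 - prevalence))
}
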