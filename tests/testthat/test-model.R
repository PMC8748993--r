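# Shared small fixtures: a donor-only synthetic table and a tiny fitted
# ensemble reused across blocks (fitting is the slow part).
d_small <- generate_feature_table(donor_only_config(n = 1500, seed = 3))
m_small <- shb_ensemble(d_small, params = fast_test_params(),
                        n_members = 3, seed = 42)

test_that("hyperparameter validation rejects out-of-domain values", {
  expect_error(shb_params(shrinkage = 0), "shrinkage")
  expect_error(shb_params(shrinkage = 1.5), "shrinkage")
  expect_error(shb_params(n_trees = 0), "n_trees")
  expect_error(shb_params(depth_grid = 0:3), "1..15")
  expect_error(shb_params(depth_grid = 16), "1..15")
  expect_error(shb_params(cv_folds = 1), "cv_folds")
  p <- shb_params("paper")
  expect_equal(p$n_trees, 5000L)
  expect_equal(p$depth_grid, 1:15)
  expect_equal(p$cv_folds, 10L)
  expect_equal(p$shrinkage, 0.01)
  expect_equal(p$bag_fraction, 0.5)
})

test_that("undersampling balances classes deterministically", {
  cfg <- donor_only_config(n = 1000, seed = 5, mode = "prevalence")
  d <- generate_feature_table(cfg)
  b1 <- undersample_dataset(d, seed = 9)
  expect_equal(sum(b1$label == "SHB"), sum(b1$label == "NHB"))
  expect_equal(sum(b1$label == "SHB"), sum(d$label == "SHB"))
  b2 <- undersample_dataset(d, seed = 9)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  b3 <- undersample_dataset(d, seed = 10)
  expect_false(identical(as.data.frame(b1), as.data.frame(b3)))
  # already balanced input: sizes unchanged
  bal <- generate_feature_table(donor_only_config(n = 400, seed = 6))
  expect_equal(nrow(undersample_dataset(bal, 1)), 400L)
  # SHB-majority input violates the undersampling precondition
  flip <- d
  flip$label <- ifelse(d$label == "SHB", "NHB", "SHB")
  expect_error(undersample_dataset(flip, 1), "balance error")
  one <- d[d$label == "SHB", ]
  expect_error(undersample_dataset(one, 1), "both classes")
})

test_that("depth tuning prefers interactions for interaction-only signal", {
  set.seed(21)
  n <- 1200
  base <- as.data.frame(generate_feature_table(donor_only_config(n = n, seed = 8)))
  base$donor_res <- sample(c("TYR", "ARG"), n, TRUE)
  base$acceptor_res <- sample(c("ASP", "GLU"), n, TRUE)
  # pure XOR: no main effects, only the interaction carries signal
  p <- ifelse((base$donor_res == "TYR") == (base$acceptor_res == "ASP"), 0.9, 0.1)
  y <- rbinom(n, 1, p)
  x <- encode_features(base)
  tuned <- tune_interaction_depth(x, y, fast_test_params(depth_grid = 1:3), seed = 2)
  expect_gte(tuned$depth, 2L)
  expect_gt(tuned$cv$loss[tuned$cv$depth == 1], min(tuned$cv$loss))
})

test_that("depth 1 is within one standard error for a single-feature signal", {
  set.seed(22)
  n <- 1200
  base <- as.data.frame(generate_feature_table(donor_only_config(n = n, seed = 9)))
  y <- rbinom(n, 1, ifelse(base$donor_res == "TYR", 0.9, 0.1))
  x <- encode_features(base)
  tuned <- tune_interaction_depth(x, y, fast_test_params(depth_grid = 1:3), seed = 2)
  cv <- tuned$cv
  best <- which.min(cv$loss)
  expect_lte(cv$loss[cv$depth == 1], cv$loss[best] + cv$se[best])
})

test_that("a perfectly separable feature yields near-certain training probabilities", {
  set.seed(23)
  d <- as.data.frame(generate_feature_table(donor_only_config(n = 600, seed = 10)))
  d$donor_res <- ifelse(seq_len(600) %% 2 == 0, "TYR", "ARG")
  d$label <- ifelse(d$donor_res == "TYR", "SHB", "NHB")
  m <- shb_ensemble(as_shb_dataset(d), params = fast_test_params(n_trees = 500),
                    n_members = 1, seed = 1, depth = 1)
  p <- predict(m, d)
  expect_true(all(p[d$label == "SHB"] >= 0.99))
  expect_true(all(p[d$label == "NHB"] <= 0.01))
})

test_that("pure-noise features give held-out probabilities near one half", {
  set.seed(24)
  d <- as.data.frame(generate_feature_table(donor_only_config(n = 2000, seed = 11)))
  d$label <- sample(c("SHB", "NHB"), 2000, TRUE)   # labels independent of features
  tr <- seq_len(1000); te <- 1001:2000
  m <- shb_ensemble(as_shb_dataset(d[tr, ]), params = fast_test_params(n_trees = 200),
                    n_members = 2, seed = 7, depth = 1)
  p <- predict(m, d[te, ])
  expect_equal(mean(p), 0.5, tolerance = 0.05)
})

test_that("the ensemble probability is exactly the member mean", {
  pm <- predict(m_small, d_small[1:50, ], type = "members")
  p <- predict(m_small, d_small[1:50, ], type = "prob")
  expect_equal(p, rowMeans(pm), tolerance = 1e-12)
  expect_equal(ncol(pm), 3L)
  expect_true(all(p >= 0 & p <= 1))
  # duplicate rows get identical probabilities
  dup <- d_small[c(1, 1), ]
  expect_equal(predict(m_small, dup)[1], predict(m_small, dup)[2])
})

test_that("a 1-member ensemble equals a single undersampled boosting fit", {
  d <- d_small
  m1 <- shb_ensemble(d, params = fast_test_params(), n_members = 1,
                     seed = 5, depth = 2)
  bal <- undersample_dataset(d, seed = 6)   # member 1 uses seed + 1
  x <- encode_features(bal)
  fit <- shbpred:::xgb_fit(x, shbpred:::label01(bal$label), 2,
                           fast_test_params(), seed = 6)
  p_manual <- predict(fit, xgboost::xgb.DMatrix(encode_features(d), nthread = 1L))
  expect_equal(predict(m1, d), p_manual, tolerance = 1e-12)
})

test_that("training and prediction are deterministic given the seed", {
  m2 <- shb_ensemble(d_small, params = fast_test_params(), n_members = 3, seed = 42)
  expect_equal(predict(m_small, d_small), predict(m2, d_small), tolerance = 1e-10)
  expect_identical(m_small$depths, m2$depths)
})

test_that("single-class training data is rejected", {
  one <- d_small[d_small$label == "SHB", ]
  expect_error(shb_ensemble(one, params = fast_test_params()), "both classes")
})

test_that("classification threshold is inclusive at the boundary", {
  expect_equal(classify_shb(0.870, 0.870), "SHB")
  expect_equal(classify_shb(0.869, 0.870), "NHB")
  expect_true(all(classify_shb(runif(20), 0) == "SHB"))
  expect_error(classify_shb(0.5, 1.5), "threshold")
})

test_that("precision and recall follow their defining ratios", {
  probs <- c(0.9, 0.9, 0.9, 0.9, 0.1)
  labels <- c(1, 1, 1, 0, 1)   # TP=3 FP=1 FN=1 at 0.5
  m <- precision_recall(probs, labels, 0.5)
  expect_equal(m$precision, 75)
  expect_equal(m$recall, 75)
  expect_equal(m$n_predicted_shb, 4L)
  # threshold 0 predicts everything SHB: recall 100
  expect_equal(precision_recall(probs, labels, 0)$recall, 100)
  # no predicted SHBs: precision undefined
  expect_true(is.na(precision_recall(probs, labels, 0.99)$precision))
})

test_that("recall and predicted counts are non-increasing in the threshold", {
  p <- predict(m_small, d_small)
  tab <- threshold_table(p, d_small$label,
                         thresholds = sort(unique(round(p, 2))))
  expect_true(all(diff(tab$recall) <= 1e-9))
  expect_true(all(diff(tab$n_predicted_shb) <= 0))
})

test_that("threshold search returns the smallest threshold meeting the target", {
  out <- find_threshold_for_precision(c(0.9, 0.8, 0.2), c(1, 0, 0), 100)
  expect_equal(out$threshold, 0.9)
  expect_equal(out$recall, 100)
  expect_error(find_threshold_for_precision(c(0.5), c(1), 101), "target_precision")
  # all labels positive: minimum probability already achieves 100%
  out <- find_threshold_for_precision(c(0.3, 0.7), c(1, 1), 100)
  expect_equal(out$threshold, 0.3)
  expect_equal(out$precision, 100)
  # unattainable target
  out <- find_threshold_for_precision(c(0.5, 0.5), c(0, 1), 99)
  expect_true(is.na(out$threshold))
})

test_that("odds ratios reproduce the printed interaction contrasts", {
  expect_equal(round(odds_ratio(0.32, 0.11), 1), 3.8)
  expect_equal(round(odds_ratio(0.65, 0.23), 1), 6.2)
  expect_equal(odds_ratio(0.4, 0.4), 1.0)
  expect_error(odds_ratio(0, 0.5), "strictly inside")
  expect_error(odds_ratio(0.5, 1), "strictly inside")
})

test_that("importance is normalized and aggregated to the 21 features", {
  imp <- feature_importance(m_small)
  expect_equal(sum(imp$importance), 100, tolerance = 0.1)
  expect_setequal(imp$feature, shbpred:::.FEATURE_NAMES)
  grouped <- feature_importance(m_small, group_other = TRUE)
  expect_equal(sum(grouped$importance), 100, tolerance = 0.1)
  expect_true("other" %in% grouped$feature)
  # donor-only generating signal: donor_res carries the top score
  expect_equal(imp$feature[1], "donor_res")
})

test_that("prior correction maps balanced probabilities to a prevalence", {
  expect_equal(prior_correction(0.5, 0.187), 0.187)
  expect_equal(prior_correction(0.9, 0.5), 0.9)
  expect_error(prior_correction(0.5, 0), "prevalence")
})

test_that("a saved model reloads with identical predictions and metadata", {
  dir <- tempfile()
  save_shb_model(m_small, dir)
  m2 <- load_shb_model(dir)
  expect_equal(predict(m2, d_small[1:100, ]), predict(m_small, d_small[1:100, ]),
               tolerance = 1e-12)
  expect_equal(m2$depths, m_small$depths)
  expect_equal(m2$member_seeds, m_small$member_seeds)
  expect_equal(m2$importance$importance, m_small$importance$importance,
               tolerance = 1e-6)
  expect_error(load_shb_model(tempfile()), "manifest")
})
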