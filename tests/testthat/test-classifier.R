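# Harness tests use the fast deterministic logistic adapter wherever the
# property under test is adapter-independent; the tree ensembles are covered
# by the separability and recovery checks.

test_that("cross-validation is seeded-deterministic end to end", {
  train <- gen_labeled_peptides(60, 60, seed = 4)
  g <- data.frame(max_depth = 3L, eta = 0.3, nrounds = 30L)
  a <- cross_validate(train, "lightgbm", grid = g, seed = 9)
  b <- cross_validate(train, "lightgbm", grid = g, seed = 9)
  expect_identical(a$fold_metrics, b$fold_metrics)
  expect_identical(a$importance, b$importance)
  expect_equal(nrow(a$fold_metrics), 5L)
  expect_true(all(a$mean_metrics >= 0 & a$mean_metrics <= 1))
})

test_that("folds are stratified within one sample of global proportions", {
  y <- rep(c(1L, 0L), c(73, 41))
  set.seed(2)
  folds <- peptiforge:::.stratified_folds(y, 5L)
  for (k in 1:5) {
    n1 <- sum(y[folds == k] == 1)
    expect_true(abs(n1 - 73 / 5) <= 1)
    n0 <- sum(y[folds == k] == 0)
    expect_true(abs(n0 - 41 / 5) <= 1)
  }
})

test_that("separable data is classified nearly perfectly, permuted labels at chance", {
  sep <- separable_peptides(150)
  for (algo in c("logistic", "lightgbm")) {
    g <- if (algo == "logistic") data.frame(dummy = 1) else
      data.frame(max_depth = 3L, eta = 0.3, nrounds = 50L)
    cv <- cross_validate(sep, algo, grid = g, seed = 2)
    expect_gte(cv$mean_metrics[["auc"]], 0.99)
  }
  perm <- gen_labeled_peptides(200, 200, seed = 31)[, c("sequence", "label")]
  set.seed(8)
  perm$label <- sample(perm$label)
  cvp <- cross_validate(perm, "logistic", seed = 8)
  expect_equal(cvp$mean_metrics[["auc"]], 0.5, tolerance = 0.1)
})

test_that("all four tree-ensemble algorithms recover strong sequence-activity structure", {
  strong <- activity_model(p_pro2_active = 1, p_pro2_inactive = 0,
                           p_hydrophobic_terminal_active = 1,
                           p_hydrophobic_terminal_inactive = 0)
  train <- gen_labeled_peptides(400, 400, model = strong, seed = 3)
  for (algo in c("gbdt", "rf", "lightgbm", "xgboost")) {
    g <- if (algo == "rf") data.frame(ntree = 200L) else
      data.frame(max_depth = 4L, eta = 0.1, nrounds = 80L)
    cv <- cross_validate(train, algo, grid = g, seed = 11)
    expect_gt(cv$mean_metrics[["auc"]], 0.8)
  }
})

test_that("grid search maximizes mean AUC with stated tie-breaking", {
  train <- gen_labeled_peptides(50, 50, seed = 12)
  # identical grid points: the first listed must win
  g <- data.frame(max_depth = c(3L, 3L), eta = c(0.2, 0.2),
                  nrounds = c(20L, 20L))
  cv <- cross_validate(train, "gbdt", grid = g, seed = 5)
  expect_identical(cv$best_params,
                   as.list(g[1L, , drop = FALSE]))
  expect_error(cross_validate(train, "gbdt", grid = g[0, ], seed = 1),
               "empty")
  onecls <- data.frame(sequence = train$sequence, label = 1L)
  expect_error(cross_validate(onecls, "gbdt", seed = 1), "both classes")
})

test_that("feature importances are ranked, normalized and recover a planted signal", {
  train <- gen_labeled_peptides(80, 80, seed = 6)
  cv <- cross_validate(train, "gbdt",
                       grid = data.frame(max_depth = 3L, eta = 0.3,
                                         nrounds = 30L), seed = 3)
  rk <- rank_feature_importance(cv)
  expect_equal(sum(rk$weight), 1, tolerance = 1e-9)
  expect_true(all(diff(rk$weight) <= 1e-12))
  # equal importances keep the original index order
  cv2 <- cv
  cv2$importance[] <- 1 / 27
  rk2 <- rank_feature_importance(cv2)
  expect_identical(rk2$feature, pseaac_feature_names())
  expect_equal(rk2$weight, rep(1 / 27, 27))
  # label determined by mean residue mass only: mass feature ranks first
  set.seed(44)
  seqs <- vapply(1:300, function(i) random_sequence(3, 8), character(1))
  mass <- featurize_matrix(seqs)[, "mean_mass"]
  planted <- data.frame(sequence = seqs,
                        label = as.integer(mass > median(mass)))
  cvm <- cross_validate(planted, "gbdt",
                        grid = data.frame(max_depth = 3L, eta = 0.3,
                                          nrounds = 50L), seed = 7)
  expect_identical(rank_feature_importance(cvm)$feature[1L], "mean_mass")
})

test_that("candidate scoring replays the training transformation", {
  train <- gen_labeled_peptides(120, 80, seed = 10)
  fit <- dppiv_classifier(train, algorithm = "lightgbm",
                          grid = data.frame(max_depth = 3L, eta = 0.3,
                                            nrounds = 40L), seed = 10)
  pred <- predict(fit, train$sequence[1:20])
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  # threshold 0 flags everything
  all_flagged <- predict_candidates(fit, c("FPL", "YW"), threshold = 0)
  expect_true(all(all_flagged$high_confidence))
  # invalid rows are skipped with a warning, not an error
  expect_warning(mix <- predict_candidates(fit, c("FPL", "FPX")),
                 "FPX")
  expect_true(is.na(mix$probability[2]))
  expect_false(is.na(mix$probability[1]))
  # enriched active-like candidates outrank inactive-like ones
  strong <- activity_model(p_pro2_active = 1, p_pro2_inactive = 0,
                           p_hydrophobic_terminal_active = 1,
                           p_hydrophobic_terminal_inactive = 0)
  tr <- gen_labeled_peptides(250, 250, model = strong, seed = 20)
  fit2 <- dppiv_classifier(tr, algorithm = "gbdt",
                           grid = data.frame(max_depth = 4L, eta = 0.2,
                                             nrounds = 60L), seed = 20)
  fresh <- gen_labeled_peptides(80, 80, model = strong, seed = 21)
  p <- predict(fit2, fresh$sequence)$probability
  wt <- wilcox.test(p[fresh$label == 1], p[fresh$label == 0],
                    alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
})
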