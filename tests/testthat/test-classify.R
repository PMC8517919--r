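planted_features <- function(seed, n_per_group = 12, p = 40, n_inf = 5,
                             delta = 2) {
  set.seed(seed)
  n <- 2 * n_per_group
  X <- matrix(rnorm(n * p), n)
  y <- rep(c("control", "patient"), each = n_per_group)
  X[y == "patient", seq_len(n_inf)] <-
    X[y == "patient", seq_len(n_inf)] - delta
  colnames(X) <- paste0("F", seq_len(p), "_L--F", seq_len(p), "_R")
  structure(list(X = X, y = factor(y, levels = c("control", "patient")),
                 feature_names = colnames(X),
                 subjects = paste0("S", seq_len(n))),
            class = "feature_table")
}

test_that("feature tables vectorise the unique connections", {
  set.seed(1)
  trains <- lapply(1:8, function(i)
    burst_train(rbinom(300, 1, 0.3), 100, region_id = sprintf("R%02d", i)))
  cns <- lapply(1:4, function(s) burst_connectome(trains[sample(8)]))
  ## same labels order across subjects is required; rebuild consistently
  cns <- lapply(1:4, function(s) burst_connectome(trains))
  ft <- feature_table(cns, rep(c("patient", "control"), 2))
  expect_equal(ncol(ft$X), 8 * 7 / 2)
  expect_equal(ft$feature_names[1], "R01--R02")
  expect_equal(unname(ft$X[1, "R03--R05"]),
               unname(cns[[1]]$J["R03", "R05"]))
})

test_that("a perfectly separating feature survives every recursion", {
  set.seed(2)
  n <- 24
  X <- matrix(rnorm(n * 30), n)
  y <- factor(rep(c("control", "patient"), each = n / 2),
              levels = c("control", "patient"))
  X[, 17] <- ifelse(y == "patient", 5, -5) + rnorm(n, 0, 0.01)
  colnames(X) <- paste0("E", 1:30)
  cfg <- classifier_config(n_trees = 100, n_resamples = 5,
                           min_features = 3, seed = 4)
  sel <- rrf_select(X, y, cfg)
  expect_true(17 %in% sel)
  ## determinism under the same seed
  expect_identical(sel, rrf_select(X, y, cfg))
})

test_that("informative connections are recovered by consensus voting", {
  ## effect size ~1.8 SD gives single-feature AUC near 0.9
  hit <- vapply(1:6, function(sd) {
    ft <- planted_features(sd, delta = 1.8)
    cfg <- classifier_config(n_trees = 150, n_resamples = 5,
                             min_features = 5, seed = sd)
    sel <- suppressMessages(rrf_select(ft$X, ft$y, cfg))
    sum(sel %in% 1:5)
  }, 0)
  expect_gte(mean(hit >= 4), 0.8)
})

test_that("cross-validated SVM separates planted groups and stays honest", {
  ft <- planted_features(9, n_per_group = 12, delta = 3)
  cfg <- classifier_config(n_trees = 100, n_resamples = 4,
                           min_features = 3, n_folds = 6, seed = 2)
  res <- suppressMessages(svm_cv(ft, cfg))
  expect_length(res$fold_auc, 6)
  expect_gt(res$mean_auc, 0.9)
  ## a feature equal to the label separates perfectly
  ft2 <- ft
  ft2$X[, 1] <- ifelse(ft2$y == "patient", 1, 0)
  res2 <- suppressMessages(svm_cv(ft2, cfg))
  expect_equal(res2$mean_auc, 1)
  ## test folds partition the subjects
  expect_setequal(unlist(res$fold_test_subjects), ft$subjects)
})

test_that("feature selection never sees the held-out fold", {
  ft <- planted_features(5, n_per_group = 10, p = 25)
  cfg <- classifier_config(n_trees = 80, n_resamples = 3,
                           min_features = 3, n_folds = 5, seed = 7)
  res <- suppressMessages(svm_cv(ft, cfg))
  ## corrupting the test-fold rows must leave per-fold selection unchanged
  ft_corrupt <- ft
  ft_corrupt$X[ft$subjects %in% res$fold_test_subjects[[1]], ] <-
    matrix(rnorm(sum(ft$subjects %in% res$fold_test_subjects[[1]]) *
                   ncol(ft$X)) * 50,
           ncol = ncol(ft$X))
  res_c <- suppressMessages(svm_cv(ft_corrupt, cfg))
  expect_identical(res$selected_per_fold[[1]], res_c$selected_per_fold[[1]])
})

test_that("permutation p-values follow the rank formula and its floor", {
  ft <- planted_features(3, n_per_group = 8, p = 15, delta = 3)
  cfg <- classifier_config(n_trees = 60, n_resamples = 3, min_features = 3,
                           n_folds = 4, seed = 5)
  pt <- suppressMessages(permutation_test(ft, cfg, n_perm = 9))
  expect_gte(pt$p, 1 / 10)
  expect_equal(pt$p, (1 + sum(pt$null_auc >= pt$observed_auc)) / 10)
  if (all(pt$null_auc < pt$observed_auc)) expect_equal(pt$p, 0.1)
})

test_that("the selected-edge report reduces correctly and tracks symptoms", {
  ft <- planted_features(6, n_per_group = 10, p = 21)
  cfg <- classifier_config(n_trees = 80, n_resamples = 3, min_features = 3,
                           n_folds = 5, seed = 3)
  res <- suppressMessages(svm_cv(ft, cfg))
  ## force a consensus of all edges: the per-subject mean must equal the
  ## global mean over connections
  res_all <- res
  res_all$consensus_features <- ft$feature_names
  rep_all <- selected_edge_report(res_all, ft)
  expect_equal(unname(rep_all$per_subject$value), unname(rowMeans(ft$X)))
  expect_equal(rep_all$n_selected, 21)
  ## interhemispheric bookkeeping: all planted names are L--R pairs
  expect_equal(rep_all$interhemispheric_fraction, 1)
  ## symptom coupling through the report
  scores <- setNames(10 - 5 * rowMeans(ft$X[, 1:5]) + rnorm(20, 0, 0.1),
                     ft$subjects)
  rep_s <- selected_edge_report(res_all, ft, symptom_scores = scores)
  expect_true(!is.null(rep_s$spearman_patients))
  res_none <- res
  res_none$consensus_features <- character(0)
  expect_error(selected_edge_report(res_none, ft), "empty consensus")
})
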