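#' Feature table from subject connectomes
#'
#' Vectorises the upper triangle of each subject's coincidence connectome
#' into one row of features (`R(R-1)/2` connection values), named by the
#' region pair.
#'
#' @param connectomes named list of `connectome` objects (names = subject
#'   ids).
#' @param groups character vector of `"patient"`/`"control"`, one per
#'   subject.
#' @return object of class `feature_table`: list with `X` (subjects x
#'   features matrix), `y` (factor with levels control, patient),
#'   `feature_names`, `subjects`.
#' @export
feature_table <- function(connectomes, groups) {
  stopifnot(length(connectomes) == length(groups))
  tabs <- lapply(connectomes, connection_table)
  fnames <- paste(tabs[[1]]$region_a, tabs[[1]]$region_b, sep = "--")
  X <- do.call(rbind, lapply(tabs, `[[`, "value"))
  colnames(X) <- fnames
  rownames(X) <- names(connectomes) %||%
    sprintf("S%02d", seq_along(connectomes))
  if (any(!is.finite(X))) stop("missing values in features")
  structure(list(X = X,
                 y = factor(groups, levels = c("control", "patient")),
                 feature_names = fnames, subjects = rownames(X)),
            class = "feature_table")
}

#' Classifier configuration
#'
#' Constants of the recursive random-forest feature selection and SVM
#' stage.  Selection recursion: fit a forest, drop features whose
#' permutation importance is below the mean importance, refit, until the
#' set is stable or the floor is reached; this is repeated over
#' `n_resamples` bootstrap resamples of the training subjects, and the
#' consensus set keeps features selected in at least `consensus_fraction`
#' of resamples.
#'
#' @param n_trees forest size (default 500).
#' @param n_resamples internal resamples for consensus voting
#'   (default 10).
#' @param consensus_fraction consensus threshold (default 0.5).
#' @param min_features recursion floor (default 5).
#' @param n_folds cross-validation folds (default 10).
#' @param seed integer seed.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(n_trees = 500L, n_resamples = 10L,
                              consensus_fraction = 0.5, min_features = 5L,
                              n_folds = 10L, seed = 1L) {
  structure(list(n_trees = as.integer(n_trees),
                 n_resamples = as.integer(n_resamples),
                 consensus_fraction = consensus_fraction,
                 min_features = as.integer(min_features),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "classifier_config")
}

## one recursion of importance-threshold elimination on given rows
rrf_recursion <- function(X, y, config, seed) {
  keep <- seq_len(ncol(X))
  repeat {
    rf <- ranger::ranger(
      x = X[, keep, drop = FALSE], y = y,
      num.trees = config$n_trees, importance = "permutation",
      seed = seed, num.threads = 1L)
    imp <- rf$variable.importance
    imp[is.na(imp)] <- 0           # features never used in any tree
    thr <- mean(imp)
    nxt <- keep[imp >= thr]
    if (length(nxt) < config$min_features) {
      nxt <- keep[order(imp, decreasing = TRUE)[
        seq_len(min(config$min_features, length(keep)))]]
      return(nxt)
    }
    if (length(nxt) == length(keep)) return(nxt)
    keep <- nxt
  }
}

#' Recursive random-forest feature selection with consensus voting
#'
#' See [classifier_config()] for the procedure.  Deterministic under a
#' fixed seed.  If no feature reaches consensus the top
#' `min_features` by mean selection frequency are returned (with a
#' message).
#'
#' @param X training feature matrix (subjects x features).
#' @param y training labels (factor, 2 levels, both present at least
#'   twice).
#' @param config a [classifier_config()].
#' @return integer vector of selected feature column indices.
#' @export
rrf_select <- function(X, y, config = classifier_config()) {
  if (min(table(y)) < 2) stop("need >= 2 subjects per class")
  votes <- numeric(ncol(X))
  set.seed(config$seed)
  boot_seeds <- sample.int(1e6, config$n_resamples)
  for (r in seq_len(config$n_resamples)) {
    set.seed(boot_seeds[r])
    ## stratified bootstrap of training subjects
    idx <- unlist(lapply(levels(y), function(lv) {
      w <- which(y == lv); sample(w, length(w), replace = TRUE)
    }))
    sel <- rrf_recursion(X[idx, , drop = FALSE], y[idx], config,
                         seed = boot_seeds[r])
    votes[sel] <- votes[sel] + 1
  }
  consensus <- which(votes / config$n_resamples >= config$consensus_fraction)
  if (length(consensus) == 0) {
    message("no feature reached consensus; falling back to top-",
            config$min_features, " by vote count")
    consensus <- order(votes, decreasing = TRUE)[seq_len(config$min_features)]
  }
  sort(consensus)
}

## rank-based AUC of decision values against binary truth
roc_auc <- function(truth, score) {
  as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score, levels = c("control", "patient"),
    direction = "<", quiet = TRUE)))
}

#' Cross-validated SVM classification of connectome features
#'
#' Stratified k-fold cross-validation.  Within each training fold only:
#' recursive random-forest feature selection, feature standardisation,
#' and a linear-kernel SVM fit; the held-out fold is scored by the SVM
#' decision value and summarised as ROC-AUC.  Test subjects never enter
#' selection or scaling (no leakage); the identities of each fold's test
#' subjects are recorded in `fold_test_subjects` so this can be audited.
#'
#' @param features a [feature_table()].
#' @param config a [classifier_config()].
#' @return object of class `classification_result`: list with `fold_auc`,
#'   `mean_auc`, `sd_auc`, `selected_per_fold` (list of feature-name
#'   vectors), `consensus_features` (features selected in at least half
#'   of the folds), `fold_test_subjects`, `config`.
#' @export
svm_cv <- function(features, config = classifier_config()) {
  stopifnot(inherits(features, "feature_table"))
  X <- features$X; y <- features$y
  n <- nrow(X)
  if (n < config$n_folds) stop("fewer subjects than folds")
  set.seed(config$seed)
  ## stratified fold assignment
  fold <- integer(n)
  for (lv in levels(y)) {
    w <- sample(which(y == lv))
    fold[w] <- rep_len(seq_len(config$n_folds), length(w))
  }
  fold_auc <- numeric(config$n_folds)
  selected <- vector("list", config$n_folds)
  test_subj <- vector("list", config$n_folds)
  fold_seeds <- sample.int(1e6, config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 1)
      stop("stratification failed: a fold lost a class")
    cfg_f <- config; cfg_f$seed <- fold_seeds[f]
    sel <- rrf_select(X[tr, , drop = FALSE], y[tr], cfg_f)
    mu <- colMeans(X[tr, sel, drop = FALSE])
    sg <- apply(X[tr, sel, drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Ztr <- sweep(sweep(X[tr, sel, drop = FALSE], 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(X[te, sel, drop = FALSE], 2, mu), 2, sg, "/")
    fit <- e1071::svm(x = Ztr, y = y[tr], kernel = "linear", scale = FALSE)
    dvm <- attr(stats::predict(fit, Zte, decision.values = TRUE),
                "decision.values")
    dv <- dvm[, 1]
    ## orient decision values so larger = more "patient"
    if (grepl("^control/", colnames(dvm)[1])) dv <- -dv
    fold_auc[f] <- if (length(unique(y[te])) == 2)
      roc_auc(y[te], dv) else NA_real_
    selected[[f]] <- features$feature_names[sel]
    test_subj[[f]] <- features$subjects[te]
  }
  sel_tab <- table(unlist(selected))
  consensus <- names(sel_tab)[sel_tab >= config$n_folds / 2]
  structure(list(fold_auc = fold_auc,
                 mean_auc = mean(fold_auc, na.rm = TRUE),
                 sd_auc = stats::sd(fold_auc, na.rm = TRUE),
                 selected_per_fold = selected,
                 consensus_features = consensus,
                 fold_test_subjects = test_subj,
                 config = config),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> mean ROC-AUC %.3f (SD %.3f) over %d folds\n",
              x$mean_auc, x$sd_auc, length(x$fold_auc)))
  cat(sprintf("  consensus features: %d\n", length(x$consensus_features)))
  invisible(x)
}

#' Label-permutation significance test of the classifier
#'
#' Reruns the full cross-validated pipeline (feature selection inside the
#' folds) with permuted group labels, and reports
#' `p = (1 + #\{null AUC >= observed\}) / (1 + n_perm)`.
#'
#' @param features a [feature_table()].
#' @param config a [classifier_config()].
#' @param n_perm number of permutations (default 100).
#' @param observed optionally a precomputed `classification_result` for
#'   the true labels (recomputed if `NULL`).
#' @return list with `observed_auc`, `null_auc` (length `n_perm`), `p`.
#' @export
permutation_test <- function(features, config = classifier_config(),
                             n_perm = 100L, observed = NULL) {
  if (is.null(observed)) observed <- svm_cv(features, config)
  set.seed(config$seed + 7L)
  perm_seeds <- sample.int(1e6, n_perm)
  null_auc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(perm_seeds[b])
    fp <- features
    fp$y <- sample(features$y)
    cfg_b <- config; cfg_b$seed <- perm_seeds[b]
    null_auc[b] <- svm_cv(fp, cfg_b)$mean_auc
  }
  list(observed_auc = observed$mean_auc, null_auc = null_auc,
       p = (1 + sum(null_auc >= observed$mean_auc)) / (1 + n_perm))
}

#' Report on the selected connections
#'
#' For the consensus connections of a fitted classifier: per-subject mean
#' connectivity over the selected edges, patient-vs-control rank-sum
#' comparison, Spearman correlation with symptom severity (patients only
#' and combined), and the interhemispheric fraction of the selected
#' edges.
#'
#' @param result a `classification_result` with a non-empty consensus
#'   set.
#' @param features the [feature_table()] the classifier was fit to.
#' @param symptom_scores optional named numeric vector of severity
#'   scores.
#' @return list with `per_subject` (data frame subject, group, value),
#'   `group_test`, `spearman_patients`, `spearman_combined`,
#'   `interhemispheric_fraction`, `n_selected`.
#' @export
selected_edge_report <- function(result, features, symptom_scores = NULL) {
  stopifnot(inherits(result, "classification_result"),
            inherits(features, "feature_table"))
  sel <- result$consensus_features
  if (length(sel) == 0) stop("empty consensus feature set")
  vals <- rowMeans(features$X[, sel, drop = FALSE])
  per_subject <- data.frame(subject = features$subjects,
                            group = as.character(features$y),
                            value = vals, stringsAsFactors = FALSE)
  gt <- wilcoxon_rank_sum(vals[features$y == "patient"],
                          vals[features$y == "control"])
  parts <- do.call(rbind, strsplit(sel, "--", fixed = TRUE))
  ihf <- interhemispheric_fraction(
    data.frame(region_a = parts[, 1], region_b = parts[, 2]))
  sp <- sc <- NULL
  if (!is.null(symptom_scores)) {
    ss <- symptom_scores[features$subjects]
    pat <- features$y == "patient"
    if (sum(pat) >= 3) sp <- spearman(ss[pat], vals[pat])
    sc <- spearman(ss, vals)
  }
  list(per_subject = per_subject, group_test = gt,
       spearman_patients = sp, spearman_combined = sc,
       interhemispheric_fraction = ihf, n_selected = length(sel))
}
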