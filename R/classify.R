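#' Map emotion labels to the binary stress task
#'
#' Negative emotion is the psychological-stress class; neutral and positive
#' are non-stress.
#'
#' @param labels character/factor vector over
#'   `{"neutral", "negative", "positive"}`.
#' @return factor with levels `c("stress", "non-stress")`.
#' @export
stress_binarize <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0)
    return(factor(character(0), levels = c("stress", "non-stress")))
  ok <- labels %in% c("neutral", "negative", "positive")
  if (!all(ok)) stop("unknown label(s): ", paste(unique(labels[!ok]), collapse = ", "))
  factor(ifelse(labels == "negative", "stress", "non-stress"),
         levels = c("stress", "non-stress"))
}

# Macro-averaged metrics from a confusion matrix (rows = truth, cols = pred).
macro_metrics <- function(cm) {
  classes <- rownames(cm)
  prec <- rec <- f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    tp <- cm[i, i]
    prec[i] <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec[i] <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  c(accuracy = sum(diag(cm)) / sum(cm), recall = mean(rec),
    precision = mean(prec), f1 = mean(f1))
}

# Stratified fold assignment (window-level) or grouped-by-subject folds.
make_folds <- function(y, subjects, folds, cv_mode) {
  n <- length(y)
  fold_id <- integer(n)
  if (cv_mode == "grouped_by_subject") {
    subj <- unique(subjects)
    if (length(subj) < folds)
      stop("grouped CV needs at least as many subjects as folds")
    perm <- sample(subj)
    assign <- rep(seq_len(folds), length.out = length(perm))
    fold_id <- assign[match(subjects, perm)]
  } else {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      if (length(idx) < folds)
        stop("stratification failure: class ", cl,
             " has fewer samples than folds")
      fold_id[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
  }
  fold_id
}

fit_predict <- function(classifier, xtr, ytr, xte, hyper) {
  switch(classifier,
    knn = class::knn(xtr, xte, ytr, k = hyper$knn_k),
    decision_tree = {
      df <- data.frame(.y = ytr, xtr)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      predict(fit, newdata = data.frame(xte), type = "class")
    },
    random_forest = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = hyper$rf_ntree)
      predict(fit, xte)
    },
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = hyper$svm_cost,
                        gamma = 1 / ncol(xtr), scale = FALSE)
      predict(fit, xte)
    },
    stop("unknown classifier: ", classifier))
}

#' Cross-validated evaluation of a feature subset
#'
#' Stratified k-fold (default 10) cross-validation of the requested
#' classifiers on the given feature columns. Features are standardised using
#' training-fold statistics only. Metrics (accuracy, macro recall/precision/
#' F1) are computed per fold from the fold's confusion matrix and averaged
#' over folds. Deterministic given `seed`.
#'
#' `cv_mode = "pooled_window"` pools windows across subjects into folds — the
#' protocol shape implied by window-level feature matrices, but it leaks
#' subjects between train and test; `"grouped_by_subject"` keeps each
#' subject's windows in a single fold and is the honest default.
#'
#' @param fm a `feature_matrix` (or data.frame with the columns below).
#' @param features character vector of feature column names to use.
#' @param task `"emotion3"` (neutral/negative/positive) or `"stress2"`.
#' @param classifiers subset of
#'   `c("knn", "decision_tree", "random_forest", "svm")`.
#' @param folds number of folds (>= 2).
#' @param cv_mode `"grouped_by_subject"` or `"pooled_window"`.
#' @param seed integer seed for fold assignment and stochastic learners.
#' @param hyper list of hyperparameters (`knn_k`, `rf_ntree`, `svm_cost`).
#' @return Object of class `classifier_report`: `metrics` (data.frame, one
#'   row per classifier), `per_fold`, `confusion` (summed over folds),
#'   `cv_mode`, `leakage_warning`.
#' @export
evaluate <- function(fm, features, task = c("emotion3", "stress2"),
                     classifiers = c("knn", "decision_tree",
                                     "random_forest", "svm"),
                     folds = 10, cv_mode = c("grouped_by_subject",
                                             "pooled_window"),
                     seed = 1,
                     hyper = list(knn_k = 5, rf_ntree = 100, svm_cost = 1)) {
  task <- match.arg(task)
  cv_mode <- match.arg(cv_mode)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (folds < 2) stop("folds must be >= 2")
  if (length(features) == 0) stop("empty feature set")
  keep <- fm$label %in% c("neutral", "negative", "positive")
  fm <- fm[keep, , drop = FALSE]
  y <- if (task == "stress2") stress_binarize(fm$label)
       else factor(fm$label, levels = c("neutral", "negative", "positive"))
  y <- droplevels(y)
  X <- as.matrix(fm[, features, drop = FALSE])
  set.seed(seed)
  fold_id <- make_folds(y, fm$subject, folds, cv_mode)
  per_fold <- array(NA_real_, c(length(classifiers), folds, 4),
                    dimnames = list(classifiers, NULL,
                                    c("accuracy", "recall", "precision", "f1")))
  cms <- stats::setNames(vector("list", length(classifiers)), classifiers)
  for (k in seq_len(folds)) {
    tr <- fold_id != k; te <- !tr
    if (length(unique(y[te])) < 1 || sum(te) == 0) next
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    xtr <- scale(X[tr, , drop = FALSE], mu, sg)
    xte <- scale(X[te, , drop = FALSE], mu, sg)
    for (ci in seq_along(classifiers)) {
      pred <- fit_predict(classifiers[ci], xtr, y[tr], xte, hyper)
      cm <- table(factor(y[te], levels = levels(y)),
                  factor(pred, levels = levels(y)))
      per_fold[ci, k, ] <- macro_metrics(cm)
      cms[[ci]] <- if (is.null(cms[[ci]])) cm else cms[[ci]] + cm
    }
  }
  metrics <- data.frame(classifier = classifiers,
                        t(apply(per_fold, 1, function(m) colMeans(m, na.rm = TRUE))),
                        row.names = NULL)
  structure(list(metrics = metrics, per_fold = per_fold, confusion = cms,
                 task = task, cv_mode = cv_mode, folds = folds,
                 features = features, fold_id = fold_id,
                 subjects = fm$subject,
                 leakage_warning = if (cv_mode == "pooled_window")
                   "pooled_window folds share subjects between train and test"
                 else NULL),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> task=%s cv=%s folds=%d features=%d\n",
              x$task, x$cv_mode, x$folds, length(x$features)))
  print(x$metrics, digits = 3)
  if (!is.null(x$leakage_warning)) cat("note:", x$leakage_warning, "\n")
  invisible(x)
}

#' Run all three selection methods end to end and evaluate each subset
#'
#' Selects features by M1 (discrete Kruskal-Wallis), M2 (per-group PCA) and
#' M3 (transition-based paired tests), then evaluates each method's subset
#' with [evaluate()] for every requested signal combination. For M2 the
#' evaluation uses the retained component scores of the combination's
#' groups.
#'
#' @param fm a `feature_matrix`.
#' @param alpha significance level for M1/M3.
#' @param task,classifiers,folds,cv_mode,seed passed to [evaluate()].
#' @param combinations list of character vectors over
#'   `c("ECG", "BVP", "GSR")`; default: all 7 non-empty combinations.
#' @param group_dims PCA dimensions for M2.
#' @return List per method (`M1`, `M2`, `M3`): `selection` and `reports`
#'   (one `classifier_report` per combination, `NULL` with a note when a
#'   method selects no feature for a combination).
#' @export
compare_methods <- function(fm, alpha = 0.05, task = "emotion3",
                            classifiers = c("knn", "decision_tree",
                                            "random_forest", "svm"),
                            folds = 10, cv_mode = "grouped_by_subject",
                            seed = 1, combinations = NULL,
                            group_dims = c(ECG = 6, BVP = 5, GSR = 6)) {
  if (is.null(combinations)) {
    g <- c("ECG", "BVP", "GSR")
    combinations <- unlist(lapply(1:3, function(k)
      utils::combn(g, k, simplify = FALSE)), recursive = FALSE)
  }
  sel1 <- discrete_select(fm, alpha = alpha)
  sel3 <- transition_select(fm, alpha = alpha)
  pca <- pca_reduce(fm, group_dims)
  run <- function(feats, data) {
    if (length(feats) == 0) return(NULL)
    evaluate(data, feats, task = task, classifiers = classifiers,
             folds = folds, cv_mode = cv_mode, seed = seed)
  }
  out <- list()
  for (meth in c("M1", "M2", "M3")) {
    reports <- list()
    for (comb in combinations) {
      nm <- paste(comb, collapse = "&")
      feats <- switch(meth,
        M1 = sel1$final_subset[feature_signal_group(sel1$final_subset) %in% comb],
        M3 = sel3$final_subset[feature_signal_group(sel3$final_subset) %in% comb],
        M2 = grep(paste0("^(", paste(comb, collapse = "|"), ")_PC"),
                  names(pca), value = TRUE))
      data <- if (meth == "M2") pca else fm
      reports[[nm]] <- run(feats, data)
    }
    out[[meth]] <- list(
      selection = switch(meth, M1 = sel1, M3 = sel3, M2 = pca),
      reports = reports)
  }
  out
}
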