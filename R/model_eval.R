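# Grouped cross-validated training and evaluation of logistic regression,
# support vector machines and gradient-boosted trees, with grid search,
# confusion-matrix metrics (reported as percentages) and ROC / PR curves.
# The positive class is "patient" throughout.

POSITIVE_CLASS <- "patient"

#' Grouped k-fold partition
#'
#' Assigns whole groups to folds so that no group (patient visit) ever
#' appears in two folds; fold sizes are balanced in group counts (+/- 1).
#'
#' @param groups group key per row.
#' @param k number of folds; must not exceed the number of distinct groups.
#' @param seed integer seed for the group shuffle.
#' @return integer fold id per row (1..k).
#' @export
grouped_kfold <- function(groups, k, seed = 1) {
  ug <- unique(as.character(groups))
  if (k > length(ug)) {
    gm_stop(sprintf("k = %d exceeds the %d distinct groups", k, length(ug)),
            "gaitmat_parameter_error")
  }
  perm <- with_seed(seed, sample(ug))
  fold_of_group <- stats::setNames(rep(seq_len(k), length.out = length(ug)), perm)
  unname(fold_of_group[as.character(groups)])
}

#' Model configuration
#'
#' Defaults follow the hyperparameters that performed best for each
#' algorithm on the standard feature set: LR with l2 penalty at C = 1,
#' SVM with an RBF kernel at C = 3 (degree 3 for polynomial kernels), XGB
#' with eta 0.3, depth 3 and a logistic objective. A non-degenerate `grid`
#' (any entry with > 1 candidate) triggers an inner grouped-CV grid search.
#'
#' @param algorithm `"LR"`, `"SVM"` or `"XGB"`.
#' @param params named list of hyperparameters overriding the defaults.
#' @param grid named list: hyperparameter -> candidate values.
#' @param seed integer seed.
#' @return object of class `model_config`.
#' @export
model_config <- function(algorithm = c("SVM", "LR", "XGB"), params = list(),
                         grid = NULL, seed = 1) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    LR = list(penalty = "l2", C = 1),
    SVM = list(kernel = "radial", C = 3, degree = 3),
    XGB = list(max_depth = 3, eta = 0.3, objective = "binary:logistic",
               nrounds = 50))
  p <- utils::modifyList(defaults, params)
  structure(list(algorithm = algorithm, params = p, grid = grid, seed = seed),
            class = "model_config")
}

#' Default hyperparameter grids
#'
#' The published search spaces: LR penalties l1/l2/elasticnet with
#' C in {1000, 100, 10, 1, 0.1, 0.01}; SVM kernels poly/rbf/sigmoid with
#' C in {5, 3, 1, 0.5, 0.1} and degrees 3-5; XGB depth {2, 3},
#' eta {0.3, 0.4} and logistic / logitraw / hinge objectives.
#' @param algorithm `"LR"`, `"SVM"` or `"XGB"`.
#' @return named list of candidate values.
#' @export
default_grid <- function(algorithm = c("SVM", "LR", "XGB")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    LR = list(penalty = c("l1", "l2", "elasticnet"),
              C = c(1000, 100, 10, 1.0, 0.1, 0.01)),
    SVM = list(kernel = c("polynomial", "radial", "sigmoid"),
               C = c(5, 3, 1.0, 0.5, 0.1),
               degree = c(3, 4, 5)),
    XGB = list(max_depth = c(2, 3), eta = c(0.3, 0.4),
               objective = c("binary:logistic", "binary:logitraw",
                             "binary:hinge")))
}

fit_classifier <- function(config, x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  yf <- factor(y, levels = c(setdiff(unique(y), POSITIVE_CLASS), POSITIVE_CLASS))
  p <- config$params
  model <- switch(config$algorithm,
    LR = {
      alpha <- switch(p$penalty, l1 = 1, l2 = 0, elasticnet = 0.5,
                      gm_stop("unknown LR penalty", "gaitmat_parameter_error"))
      glmnet::glmnet(x, yf, family = "binomial", alpha = alpha,
                     lambda = 1 / (p$C * nrow(x)), standardize = FALSE)
    },
    SVM = e1071::svm(x, yf, kernel = p$kernel, cost = p$C,
                     degree = p$degree %||% 3, scale = FALSE),
    XGB = {
      lab <- as.numeric(yf == POSITIVE_CLASS)
      dtrain <- xgboost::xgb.DMatrix(data = x, label = lab, nthread = 1)
      with_seed(config$seed, xgboost::xgb.train(
        params = list(max_depth = p$max_depth, eta = p$eta,
                      objective = p$objective, nthread = 1),
        data = dtrain, nrounds = p$nrounds %||% 50, verbose = 0))
    })
  structure(list(algorithm = config$algorithm, params = p, model = model,
                 levels = levels(yf)), class = "gait_classifier")
}

#' Continuous decision scores of a fitted classifier
#'
#' Probability of the positive (patient) class for LR and XGB
#' (raw margin for the logitraw/hinge objectives), signed decision-hyperplane
#' margin for SVM, oriented so larger means more patient-like.
#' @param fit a fitted `gait_classifier`.
#' @param x feature matrix.
#' @return numeric scores.
#' @export
predict_scores <- function(fit, x) {
  x <- as.matrix(x)
  switch(fit$algorithm,
    LR = as.numeric(stats::predict(fit$model, newx = x, type = "response")),
    SVM = {
      pr <- stats::predict(fit$model, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      nm <- colnames(dv)[1]
      s <- as.numeric(dv[, 1])
      # orient toward the positive class
      if (startsWith(nm, paste0(POSITIVE_CLASS, "/"))) s else -s
    },
    XGB = as.numeric(stats::predict(fit$model, x)))
}

predict_classes <- function(fit, x) {
  s <- predict_scores(fit, x)
  thr <- if (fit$algorithm == "SVM") 0
         else if (fit$algorithm == "XGB" &&
                  fit$params$objective == "binary:logitraw") 0
         else 0.5
  ifelse(s >= thr, POSITIVE_CLASS, setdiff(fit$levels, POSITIVE_CLASS)[1])
}

#' Exhaustive grid search with grouped inner cross-validation
#'
#' Evaluates every combination of the grid by mean inner grouped-CV
#' accuracy and returns the best; ties resolve to the first combination in
#' grid order.
#'
#' @param config a [model_config()] whose `grid` is non-empty.
#' @param x,y training matrix and labels.
#' @param groups group key per row.
#' @param inner_k inner folds; default 3.
#' @param seed integer seed.
#' @return list with `best` (a `model_config`), `table` of combinations
#'   and mean accuracies.
#' @export
grid_search <- function(config, x, y, groups, inner_k = 3, seed = 1) {
  grid <- config$grid
  if (is.null(grid) || !length(grid)) gm_stop("empty grid", "gaitmat_parameter_error")
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  inner_k <- min(inner_k, length(unique(groups)))
  fold_id <- grouped_kfold(groups, inner_k, seed = seed)
  y <- as.character(y)
  acc <- rep(NA_real_, nrow(combos))
  errors <- character(0)
  for (ci in seq_len(nrow(combos))) {
    cfg <- model_config(config$algorithm, params = as.list(combos[ci, , drop = FALSE]),
                        seed = config$seed)
    fold_acc <- vapply(seq_len(inner_k), function(fi) {
      tr <- fold_id != fi; te <- fold_id == fi
      if (length(unique(y[tr])) < 2 || !any(te)) return(NA_real_)
      fit <- tryCatch(fit_classifier(cfg, x[tr, , drop = FALSE], y[tr]),
                      error = function(e) e)
      if (inherits(fit, "error")) return(NA_real_)
      mean(predict_classes(fit, x[te, , drop = FALSE]) == y[te])
    }, numeric(1))
    if (all(is.na(fold_acc))) {
      errors <- c(errors, sprintf("combination %d failed on all folds", ci))
    }
    acc[ci] <- mean(fold_acc, na.rm = TRUE)
  }
  if (all(is.na(acc) | is.nan(acc))) {
    gm_stop(paste("all grid combinations failed:",
                  paste(errors, collapse = "; ")), "gaitmat_fit_error")
  }
  best_i <- which(acc >= max(acc, na.rm = TRUE) - 1e-12)[1]
  best <- model_config(config$algorithm,
                       params = as.list(combos[best_i, , drop = FALSE]),
                       seed = config$seed)
  list(best = best, table = cbind(combos, mean_accuracy = acc))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 as percentages:
#' accuracy = (TN+TP)/(TN+TP+FN+FP) x 100, precision = TP/(TP+FP) x 100,
#' recall = TP/(TP+FN) x 100, F1 = 2 x precision x recall /
#' (precision + recall). A metric with a zero denominator is reported as
#' missing, never as 0.
#'
#' @param tp,tn,fp,fn non-negative counts (not all zero).
#' @return named numeric: accuracy, precision, recall, f1 (percent).
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  accuracy <- (tn + tp) / (tn + tp + fn + fp) * 100
  precision <- if (tp + fp > 0) tp / (tp + fp) * 100 else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(accuracy = accuracy, precision = precision, recall = recall, f1 = f1)
}

#' ROC and precision-recall curves with areas
#'
#' Sweeps every distinct score threshold. AUROC is the trapezoidal area
#' under the ROC curve (equal to the Mann-Whitney concordance fraction);
#' AUPRC is the step-wise average precision.
#'
#' @param scores continuous decision scores, larger = more positive.
#' @param labels class labels; positive class `"patient"` (or `TRUE`/1).
#' @return list with `roc` (fpr, tpr, threshold), `pr` (recall, precision,
#'   threshold), `auroc`, `auprc`.
#' @export
roc_pr_curves <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else as.character(labels) %in%
    c(POSITIVE_CLASS, "1", "TRUE")
  if (!any(pos) || all(pos)) gm_stop("both classes must be present", "gaitmat_parameter_error")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  n_pos <- sum(p); n_neg <- sum(!p)
  cum_tp <- cumsum(p); cum_fp <- cumsum(!p)
  last <- c(diff(s) != 0, TRUE)          # indices closing each distinct threshold
  tp <- cum_tp[last]; fp <- cum_fp[last]; thr <- s[last]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp); rec <- tp / n_pos
  auprc <- sum(diff(c(0, rec)) * prec)   # step-wise average precision
  list(roc = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       pr = data.frame(threshold = thr, recall = rec, precision = prec),
       auroc = auroc, auprc = auprc)
}

eval_report <- function(pred, truth, scores, per_fold, chosen_params, selection) {
  pos <- truth == POSITIVE_CLASS
  tp <- sum(pred == POSITIVE_CLASS & pos)
  tn <- sum(pred != POSITIVE_CLASS & !pos)
  fp <- sum(pred == POSITIVE_CLASS & !pos)
  fn <- sum(pred != POSITIVE_CLASS & pos)
  curves <- roc_pr_curves(scores, truth)
  structure(
    list(confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
         metrics = confusion_metrics(tp, tn, fp, fn),
         auroc = curves$auroc, auprc = curves$auprc,
         roc = curves$roc, pr = curves$pr,
         per_fold = per_fold, chosen_params = chosen_params,
         selection = selection),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<eval_report> acc %.1f%% | prec %.1f%% | rec %.1f%% | F1 %.1f%% | AUROC %.3f | AUPRC %.3f\n",
              m["accuracy"], m["precision"], m["recall"], m["f1"], x$auroc, x$auprc))
  cat(sprintf("  confusion: TP=%d TN=%d FP=%d FN=%d\n",
              x$confusion["tp"], x$confusion["tn"], x$confusion["fp"], x$confusion["fn"]))
  invisible(x)
}

#' Run a full grouped cross-validated classification experiment
#'
#' For each feature set and each model: outer grouped k-fold over patient
#' visits; inside every fold the preprocessing pipeline (SMOTE, scaling,
#' correlation filter, ANOVA ranking, size selection) is fitted on the
#' training rows only and applied to the test rows; an optional grid
#' search tunes hyperparameters on the training folds. Test predictions
#' are pooled over folds into one report per (feature set, model), and the
#' augmented-minus-standard metric deltas are tabulated when both sets run.
#'
#' @param features feature table from [extract_features()].
#' @param specs list of [feature_set_spec()]s.
#' @param configs list of [model_config()]s.
#' @param k outer folds; default 5.
#' @param seed master seed; the whole experiment is reproducible from it.
#' @param size_folds folds for subset-size selection.
#' @param k_smote SMOTE neighbour count (reduce for very small cohorts).
#' @param height_normalize divide foot-geometry features by subject height
#'   before modelling.
#' @return object of class `gait_experiment`: `reports[[set]][[algorithm]]`
#'   plus a `comparison` data.frame of deltas.
#' @export
run_experiment <- function(features,
                           specs = list(feature_set_spec("standard"),
                                        feature_set_spec("augmented")),
                           configs = list(model_config("SVM")),
                           k = 5, seed = 1, size_folds = 5, k_smote = 5,
                           height_normalize = TRUE) {
  if (height_normalize) features <- normalize_by_height(features)
  fold_id <- grouped_kfold(features$visit_id, k, seed = seed)
  reports <- list()
  for (spec in specs) {
    needed <- c(spec$numeric_features, spec$categorical_features)
    usable <- stats::complete.cases(features[, needed])
    for (config in configs) {
      pred <- character(0); truth <- character(0); scores <- numeric(0)
      per_fold <- data.frame(fold = integer(0), n_test = integer(0),
                             accuracy = numeric(0), chosen_size = integer(0))
      chosen_params <- list(); selections <- list()
      for (fi in seq_len(k)) {
        tr_rows <- features[usable & fold_id != fi, , drop = FALSE]
        te_rows <- features[usable & fold_id == fi, , drop = FALSE]
        if (nrow(te_rows) == 0 || length(unique(tr_rows$class_label)) < 2) next
        fseed <- as.integer((as.numeric(seed) * 101 + fi) %% 2100000000)
        prep <- withCallingHandlers(
          preprocess_fit(tr_rows, spec, seed = fseed, size_folds = size_folds,
                         k_smote = k_smote),
          gaitmat_warning = function(w) invokeRestart("muffleWarning"))
        te <- prep$transform(te_rows)
        trb <- prep$train_design       # SMOTE-balanced, scaled, selected features
        cfg <- config
        if (!is.null(config$grid)) {
          gs <- grid_search(config, trb$x, trb$y, trb$groups,
                            seed = fseed + 1L)
          cfg <- gs$best
        }
        fit <- fit_classifier(cfg, trb$x, trb$y)
        pr_cls <- predict_classes(fit, te$x)
        pr_sc <- predict_scores(fit, te$x)
        pred <- c(pred, pr_cls); truth <- c(truth, as.character(te$y))
        scores <- c(scores, pr_sc)
        per_fold <- rbind(per_fold, data.frame(
          fold = fi, n_test = length(pr_cls),
          accuracy = mean(pr_cls == te$y),
          chosen_size = prep$selection$chosen_size))
        chosen_params[[length(chosen_params) + 1L]] <- cfg$params
        selections[[length(selections) + 1L]] <- prep$selection$final_features
      }
      reports[[spec$name]][[config$algorithm]] <-
        eval_report(pred, truth, scores, per_fold, chosen_params, selections)
    }
  }
  comparison <- NULL
  if (all(c("standard", "augmented") %in% names(reports))) {
    algos <- intersect(names(reports$standard), names(reports$augmented))
    comparison <- do.call(rbind, lapply(algos, function(a) {
      s <- reports$standard[[a]]; g <- reports$augmented[[a]]
      data.frame(algorithm = a,
                 metric = c(names(s$metrics), "auroc", "auprc"),
                 standard = c(unname(s$metrics), s$auroc, s$auprc),
                 augmented = c(unname(g$metrics), g$auroc, g$auprc),
                 delta = c(unname(g$metrics - s$metrics),
                           g$auroc - s$auroc, g$auprc - s$auprc))
    }))
  }
  structure(list(reports = reports, comparison = comparison, k = k, seed = seed),
            class = "gait_experiment")
}

#' @export
print.gait_experiment <- function(x, ...) {
  for (set in names(x$reports)) {
    cat(sprintf("== %s feature set ==\n", set))
    for (a in names(x$reports[[set]])) {
      cat(sprintf("  [%s] ", a)); print(x$reports[[set]][[a]])
    }
  }
  invisible(x)
}
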