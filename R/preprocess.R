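# Leakage-aware preprocessing and feature-selection pipeline: SMOTE class
# balancing, train-fitted z-scaling, height normalisation, Pearson
# correlation filtering at |r| >= 0.8, ANOVA-F ranking, cross-validated
# subset-size selection with an SVM, and reintroduction of categorical
# features. Everything is fitted on training folds only and applied
# unchanged to test folds.

#' Feature-set specification
#'
#' The standard set holds the classic spatiotemporal parameters (signed
#' toe angle included, foot type categorical). The augmented set replaces
#' the signed toe angle by its magnitude plus a binary toe direction and
#' adds the geometric features: foot length/width/area, convex-hull area,
#' base-of-support area and line-of-progression deviation angle.
#'
#' @param name `"standard"` or `"augmented"`.
#' @return list with `name`, `numeric_features`, `categorical_features`.
#' @export
feature_set_spec <- function(name = c("standard", "augmented")) {
  name <- match.arg(name)
  base_numeric <- c("step_time", "stride_time", "step_velocity",
                    "stride_velocity", "single_support_time",
                    "double_support_time", "stance_time",
                    "step_length", "step_width", "stride_length",
                    "stride_width", "base_width")
  if (name == "standard") {
    list(name = "standard",
         numeric_features = c(base_numeric, "toe_angle_signed"),
         categorical_features = "foot_type")
  } else {
    list(name = "augmented",
         numeric_features = c(base_numeric, "toe_angle_unsigned",
                              "foot_length", "foot_width", "foot_area",
                              "hull_area", "bos_area", "lop_deviation_angle"),
         categorical_features = c("foot_type", "toe_direction"))
  }
}

#' Read feature-set specifications from a YAML file
#'
#' The file maps set names to `numeric_features` / `categorical_features`
#' lists; absent entries fall back to the built-in defaults.
#' @param path YAML file.
#' @return named list of feature-set specs.
#' @export
read_feature_sets <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    gm_stop("the 'yaml' package is required to read feature-set files",
            "gaitmat_io_error")
  }
  raw <- yaml::read_yaml(path)
  lapply(stats::setNames(names(raw), names(raw)), function(nm) {
    list(name = nm,
         numeric_features = unlist(raw[[nm]]$numeric_features),
         categorical_features = unlist(raw[[nm]]$categorical_features))
  })
}

#' SMOTE class balancing
#'
#' Synthesises minority-class samples until the two classes are balanced:
#' each synthetic row lies on the segment between a randomly chosen
#' minority sample and one of its k nearest minority neighbours (both
#' choices random, interpolation factor uniform). Categorical columns are
#' copied from the seed sample.
#'
#' @param rows data.frame of training rows.
#' @param labels class labels (two classes).
#' @param k_neighbors number of nearest minority neighbours; default 5.
#' @param seed integer seed.
#' @param numeric_cols columns to interpolate; default all numeric columns.
#' @return list with `rows`, `labels`, `base_index` (the seed row of each
#'   synthetic sample, `NA` for originals).
#' @export
smote_balance <- function(rows, labels, k_neighbors = 5, seed = 1,
                          numeric_cols = NULL) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2) gm_stop("SMOTE needs exactly two classes", "gaitmat_parameter_error")
  if (tab[1] == tab[2]) {
    return(list(rows = rows, labels = labels, base_index = rep(NA_integer_, nrow(rows))))
  }
  minority <- names(tab)[which.min(tab)]
  min_idx <- which(labels == minority)
  n_new <- max(tab) - min(tab)
  if (length(min_idx) <= k_neighbors) {
    gm_stop(sprintf(
      "minority class has %d samples, not enough for k_neighbors = %d; use a smaller k",
      length(min_idx), k_neighbors), "gaitmat_parameter_error")
  }
  if (is.null(numeric_cols)) {
    numeric_cols <- names(rows)[vapply(rows, is.numeric, logical(1))]
  }
  xm <- as.matrix(rows[min_idx, numeric_cols, drop = FALSE])
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  synth <- with_seed(seed, {
    base <- sample(seq_along(min_idx), n_new, replace = TRUE)
    pick <- sample.int(k_neighbors, n_new, replace = TRUE)
    tt <- stats::runif(n_new)
    nb <- nn[cbind(base, pick)]
    new_num <- xm[base, , drop = FALSE] +
      tt * (xm[nb, , drop = FALSE] - xm[base, , drop = FALSE])
    list(base = base, num = new_num)
  })
  new_rows <- rows[min_idx[synth$base], , drop = FALSE]
  new_rows[, numeric_cols] <- synth$num
  rownames(new_rows) <- NULL
  out_rows <- rbind(rows, new_rows)
  rownames(out_rows) <- NULL
  list(rows = out_rows,
       labels = c(labels, rep(minority, n_new)),
       base_index = c(rep(NA_integer_, nrow(rows)), min_idx[synth$base]))
}

#' Fit a z-scaler on training columns
#'
#' Population mean/sd per column (sd with divisor n). Zero-variance
#' columns are flagged and later centred only, never divided by zero.
#' @param x numeric matrix or data.frame.
#' @return object of class `zscaler`.
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
  constant <- sdev < 1e-12
  if (any(constant)) {
    gm_warn(sprintf("zero-variance column(s) passed through centred: %s",
                    paste(colnames(x)[constant], collapse = ", ")))
  }
  structure(list(mean = mu, sd = ifelse(constant, 1, sdev), constant = constant),
            class = "zscaler")
}

#' Apply a fitted z-scaler
#'
#' Test data are always scaled with the training statistics.
#' @param scaler a `zscaler` from [zscore_fit()].
#' @param x matrix/data.frame with the scaler's columns.
#' @return scaled matrix.
#' @export
zscore_apply <- function(scaler, x) {
  x <- as.matrix(x)[, names(scaler$mean), drop = FALSE]
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Normalise foot-geometry features by subject height
#'
#' Divides foot length, foot width, foot area and hull area by the
#' subject's height in cm; all other columns are untouched.
#' @param rows feature rows with a `height_cm` column.
#' @param cols columns to normalise.
#' @return rows with the named columns divided by height.
#' @export
normalize_by_height <- function(rows, cols = c("foot_length", "foot_width",
                                               "foot_area", "hull_area")) {
  if (!"height_cm" %in% names(rows)) gm_stop("missing height_cm", "gaitmat_format_error")
  h <- rows$height_cm
  if (any(is.na(h) | h <= 0)) {
    gm_stop(sprintf("missing or non-positive height for row(s) %s",
                    paste(utils::head(which(is.na(h) | h <= 0), 5), collapse = ", ")),
            "gaitmat_format_error")
  }
  for (cl in intersect(cols, names(rows))) rows[[cl]] <- rows[[cl]] / h
  rows
}

#' Pearson correlation filter
#'
#' Greedy filter: features are visited in priority order (by default the
#' given column order; in the pipeline, descending ANOVA F) and kept only
#' if their absolute Pearson correlation with every already-kept feature
#' stays below the threshold, so the lower-priority member of a correlated
#' pair is dropped. Correlations that are undefined (constant columns)
#' count as zero with a warning.
#'
#' @param x numeric training matrix.
#' @param threshold drop threshold on |r|; default 0.8.
#' @param priority character vector ordering the columns (highest first).
#' @return list with `retained` and `dropped` (feature, partner, r).
#' @export
correlation_filter <- function(x, threshold = 0.8, priority = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  x <- as.matrix(x)
  cm <- suppressWarnings(stats::cor(x))
  if (any(is.na(cm))) {
    gm_warn("NaN correlations (constant column?) treated as 0")
    cm[is.na(cm)] <- 0
  }
  order_cols <- priority %||% colnames(x)
  stopifnot(all(order_cols %in% colnames(x)))
  kept <- character(0)
  dropped <- list()
  for (f in order_cols) {
    if (length(kept) == 0) { kept <- f; next }
    r <- cm[f, kept]
    worst <- which.max(abs(r))
    if (abs(r[worst]) >= threshold) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(feature = f, partner = kept[worst], r = unname(r[worst]))
    } else {
      kept <- c(kept, f)
    }
  }
  list(retained = kept,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(feature = character(0), partner = character(0), r = numeric(0)))
}

#' One-way ANOVA F score per feature
#'
#' Closed-form one-way ANOVA F statistic of each column against the class
#' labels, in descending order. For two classes F equals the square of the
#' pooled two-sample t statistic. A feature with zero within-group
#' variance but distinct group means separates the classes perfectly and
#' is ranked first with an infinite score.
#'
#' @param x numeric matrix.
#' @param labels class labels (>= 2 groups, >= 2 rows each).
#' @return named numeric vector of F scores, descending.
#' @export
anova_rank <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  groups <- split(seq_len(nrow(x)), labels)
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    gm_stop("anova_rank needs >= 2 groups with >= 2 rows each", "gaitmat_parameter_error")
  }
  n <- nrow(x); g <- length(groups)
  grand <- colMeans(x)
  ssb <- rep(0, ncol(x)); ssw <- rep(0, ncol(x))
  for (idx in groups) {
    gm <- colMeans(x[idx, , drop = FALSE])
    ssb <- ssb + length(idx) * (gm - grand)^2
    ssw <- ssw + colSums(sweep(x[idx, , drop = FALSE], 2, gm)^2)
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[ssw < 1e-300 & ssb > 0] <- Inf
  f[ssw < 1e-300 & ssb <= 1e-300] <- 0
  names(f) <- colnames(x)
  sort(f, decreasing = TRUE)
}

#' Choose the feature-subset size by cross-validated SVM accuracy
#'
#' For every size s of the ranked feature list, a grouped k-fold
#' cross-validation with a default-configuration SVM measures prediction
#' accuracy on the training data; the size with the highest mean accuracy
#' wins, ties going to the smallest size.
#'
#' @param ranked character vector of features, strongest first.
#' @param x scaled training matrix containing those columns.
#' @param labels class labels.
#' @param groups group key per row (folds never split a group).
#' @param folds number of CV folds; default 5.
#' @param seed integer seed for the fold shuffle.
#' @return list with `chosen_size` and `accuracy` (per-size mean CV accuracy).
#' @export
select_size <- function(ranked, x, labels, groups, folds = 5, seed = 1) {
  if (length(ranked) == 0) gm_stop("no ranked features", "gaitmat_parameter_error")
  x <- as.matrix(x)
  y <- factor(labels)
  folds_eff <- min(folds, length(unique(groups)))
  fold_id <- grouped_kfold(groups, folds_eff, seed = seed)
  acc <- vapply(seq_along(ranked), function(s) {
    cols <- ranked[seq_len(s)]
    fold_acc <- vapply(seq_len(folds_eff), function(fi) {
      tr <- fold_id != fi; te <- fold_id == fi
      if (length(unique(y[tr])) < 2 || !any(te)) return(NA_real_)
      fit <- e1071::svm(x[tr, cols, drop = FALSE], y[tr], scale = FALSE)
      mean(predict(fit, x[te, cols, drop = FALSE]) == y[te])
    }, numeric(1))
    mean(fold_acc, na.rm = TRUE)
  }, numeric(1))
  chosen <- which(acc >= max(acc) - 1e-12)[1]   # ties -> smallest size
  list(chosen_size = chosen, accuracy = acc)
}

#' Reintroduce categorical features after numeric selection
#'
#' @param survivors selected numeric features (ordered).
#' @param spec a [feature_set_spec()].
#' @return final ordered feature list.
#' @export
finalize_features <- function(survivors, spec) {
  if (length(survivors) == 0) {
    gm_warn("no numeric survivors: final set holds categorical features only")
  }
  c(survivors, spec$categorical_features)
}

encode_categoricals <- function(rows, cats) {
  out <- list()
  for (cl in cats) {
    v <- rows[[cl]]
    out[[cl]] <- if (is.numeric(v)) as.numeric(v) else as.numeric(v == "right")
  }
  if (length(out)) do.call(cbind, out) else NULL
}

#' Fit the preprocessing and feature-selection pipeline on training rows
#'
#' Order of operations (height normalisation is applied to the whole table
#' beforehand, it is a per-row transform): SMOTE balancing, z-scaler fit,
#' ANOVA-F ranking, correlation filter (priority = descending F),
#' re-ranking of survivors, cross-validated subset-size selection,
#' categorical reintroduction. The returned object transforms any test
#' table with the training statistics only.
#'
#' @param train feature rows (training folds only; complete cases for the
#'   spec's features).
#' @param spec a [feature_set_spec()].
#' @param seed integer seed (SMOTE draws + size-selection folds).
#' @param k_smote SMOTE neighbour count.
#' @param cor_threshold correlation-filter threshold.
#' @param size_folds folds for subset-size selection.
#' @return object of class `gait_preprocessor` with `$selection`
#'   (a SelectionResult: drop log, F scores, per-size accuracies, chosen
#'   size, final features) and `$transform(rows)`.
#' @export
preprocess_fit <- function(train, spec, seed = 1, k_smote = 5,
                           cor_threshold = 0.8, size_folds = 5) {
  needed <- c(spec$numeric_features, spec$categorical_features)
  stopifnot(all(needed %in% names(train)))
  cc <- stats::complete.cases(train[, needed])
  train <- train[cc, , drop = FALSE]
  sm <- smote_balance(train, train$class_label, k_neighbors = k_smote,
                      seed = seed, numeric_cols = spec$numeric_features)
  bal <- sm$rows
  bal_groups <- bal$visit_id
  y_bal <- sm$labels
  scaler <- withCallingHandlers(
    zscore_fit(bal[, spec$numeric_features]),
    gaitmat_warning = function(w) invokeRestart("muffleWarning"))
  xs <- zscore_apply(scaler, bal[, spec$numeric_features])
  f_all <- anova_rank(xs, y_bal)
  cf <- correlation_filter(xs, threshold = cor_threshold, priority = names(f_all))
  ranked <- names(f_all)[names(f_all) %in% cf$retained]
  sel <- select_size(ranked, xs, y_bal, bal_groups, folds = size_folds,
                     seed = as.integer((seed * 13 + 7) %% 2100000000))
  survivors <- ranked[seq_len(sel$chosen_size)]
  final <- finalize_features(survivors, spec)
  selection <- list(
    dropped_by_correlation = cf$dropped, anova_scores = f_all,
    chosen_size = sel$chosen_size, size_accuracy = sel$accuracy,
    final_features = final, n_dropped_incomplete = sum(!cc)
  )
  transform <- function(rows) {
    cc2 <- stats::complete.cases(rows[, needed])
    rows <- rows[cc2, , drop = FALSE]
    xs2 <- zscore_apply(scaler, rows[, spec$numeric_features])
    xnum <- xs2[, survivors, drop = FALSE]
    xcat <- encode_categoricals(rows, spec$categorical_features)
    x <- cbind(xnum, xcat)
    colnames(x) <- final
    list(x = x, y = rows$class_label, groups = rows$visit_id,
         rows_kept = which(cc2))
  }
  xcat_bal <- encode_categoricals(bal, spec$categorical_features)
  train_design <- list(
    x = {
      xb <- cbind(xs[, survivors, drop = FALSE], xcat_bal)
      colnames(xb) <- final
      xb
    },
    y = y_bal, groups = bal_groups
  )
  structure(
    list(spec = spec, scaler = scaler, selection = selection,
         survivors = survivors, transform = transform,
         train_design = train_design),
    class = "gait_preprocessor"
  )
}
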