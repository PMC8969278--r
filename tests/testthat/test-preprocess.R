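test_that("SMOTE balances the classes with on-segment synthetic samples", {
  set.seed(31)
  rows <- data.frame(a = c(rnorm(60, 5), rnorm(10)), b = c(rnorm(60, -2), rnorm(10)))
  labels <- rep(c("patient", "control"), c(60, 10))
  out <- smote_balance(rows, labels, k_neighbors = 5, seed = 2)
  expect_equal(unname(table(out$labels)["control"]), 60)
  expect_equal(unname(table(out$labels)["patient"]), 60)
  # already balanced: unchanged
  bal <- smote_balance(rows[1:20, ], rep(c("patient", "control"), 10), seed = 2)
  expect_identical(bal$rows, rows[1:20, ])
  # too few minority samples for k
  expect_error(smote_balance(rows[c(1:60, 61:64), ], labels[c(1:60, 61:64)], k_neighbors = 5),
               class = "gaitmat_parameter_error")
})

test_that("1-D SMOTE synthetics are convex combinations of neighbour pairs", {
  rows <- data.frame(v = c(10, 11, 12, 13, 14, 15, 16, 0, 1, 2))
  labels <- rep(c("patient", "control"), c(7, 3))
  out <- smote_balance(rows, labels, k_neighbors = 2, seed = 5)
  synth <- out$rows$v[out$labels == "control"][-(1:3)]
  minority <- c(0, 1, 2)
  expect_true(all(synth >= 0 - 1e-9 & synth <= 2 + 1e-9))
  # brute-force segment membership: each synthetic value sits between a
  # minority point and one of its 2 nearest minority neighbours
  on_segment <- vapply(synth, function(s) {
    any(vapply(seq_along(minority), function(i) {
      nb <- minority[order(abs(minority - minority[i]))][2:3]
      any(s >= pmin(minority[i], nb) - 1e-9 & s <= pmax(minority[i], nb) + 1e-9)
    }, logical(1)))
  }, logical(1))
  expect_true(all(on_segment))
})

test_that("z-scaling uses training statistics only", {
  sc <- zscore_fit(cbind(v = c(1, 2, 3)))
  scaled <- zscore_apply(sc, cbind(v = c(1, 2, 3)))
  expect_equal(mean(scaled), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(scaled^2)), 1, tolerance = 1e-12)   # population sd
  expect_equal(as.numeric(scaled), c(-1, 0, 1) / sqrt(2 / 3))
  # constant column: flagged, centred, not divided by zero
  expect_warning(sc2 <- zscore_fit(cbind(v = rep(4, 5))), regexp = "zero-variance")
  expect_equal(as.numeric(zscore_apply(sc2, cbind(v = rep(4, 3)))), rep(0, 3))
  # test data scaled with train stats keeps its shift
  shifted <- zscore_apply(sc, cbind(v = c(11, 12, 13)))
  expect_gt(abs(mean(shifted)), 1)
})

test_that("height normalisation rescales only the foot-geometry columns", {
  rows <- data.frame(foot_length = 24, foot_width = 9, foot_area = 200,
                     hull_area = 180, step_length = 60, height_cm = 160)
  out <- normalize_by_height(rows)
  expect_equal(out$foot_length, 0.15)
  expect_equal(out$step_length, 60)
  rows2 <- rbind(rows, rows)
  rows2$height_cm <- c(150, 200)
  out2 <- normalize_by_height(rows2)
  expect_equal(out2$foot_length[1] / out2$foot_length[2], 200 / 150)
  rows$height_cm <- 0
  expect_error(normalize_by_height(rows), class = "gaitmat_format_error")
})

test_that("correlation filter drops the lower-priority member of tight pairs", {
  set.seed(41)
  x <- cbind(a = rnorm(200))
  x <- cbind(x, b = 2 * x[, "a"], c = rnorm(200), d = rnorm(200))
  res <- correlation_filter(x, threshold = 0.8, priority = c("a", "b", "c", "d"))
  expect_setequal(res$retained, c("a", "c", "d"))
  expect_equal(res$dropped$feature, "b")
  expect_equal(res$dropped$partner, "a")
  expect_gt(abs(res$dropped$r), 0.99)
  # independent noise at this n never crosses 0.8
  noise <- matrix(rnorm(200 * 6), 200, dimnames = list(NULL, letters[1:6]))
  expect_length(correlation_filter(noise)$retained, 6)
  # retained pairwise correlations all below threshold
  cm <- abs(stats::cor(x[, res$retained]))
  expect_true(all(cm[upper.tri(cm)] < 0.8))
})

test_that("a stride column built as ~2x step is dropped under F priority", {
  set.seed(43)
  lab <- rep(c("patient", "control"), each = 100)
  step <- c(rnorm(100, 48, 3), rnorm(100, 60, 3))
  stride <- 2 * step + rnorm(200, 0, 1)
  other <- rnorm(200)
  x <- cbind(step = step, stride = stride, other = other)
  f <- anova_rank(x, lab)
  res <- correlation_filter(x, priority = names(f))
  expect_true("stride" %in% res$dropped$feature || "step" %in% res$dropped$feature)
  expect_false(all(c("step", "stride") %in% res$retained))
  # the dropped one is the lower-F member
  pair <- c("step", "stride")
  expect_equal(res$dropped$feature[res$dropped$feature %in% pair],
               pair[which.min(f[pair])])
})

test_that("ANOVA F matches the hand-worked case and the t-test identity", {
  x <- cbind(v = c(0, 1, 2, 3))
  f <- anova_rank(x, c("A", "A", "B", "B"))
  expect_equal(unname(f["v"]), 8.0)
  # mirrored distribution: F collapses to zero
  x2 <- cbind(v = c(1, 2, 1, 2))
  expect_lt(unname(anova_rank(x2, c("A", "A", "B", "B"))["v"]), 1e-9)
  # F = t^2 with the pooled-variance t statistic
  set.seed(11)
  for (i in 1:25) {
    vals <- rnorm(30)
    lab <- sample(rep(c("A", "B"), 15))
    f <- unname(anova_rank(cbind(v = vals), lab)["v"])
    t2 <- unname(t.test(vals ~ lab, var.equal = TRUE)$statistic)^2
    expect_equal(f, t2, tolerance = 1e-9)
  }
  # perfect separator: infinite score ranked first
  x3 <- cbind(sep = rep(c(0, 1), each = 4), noise = rnorm(8))
  f3 <- anova_rank(x3, rep(c("A", "B"), each = 4))
  expect_equal(names(f3)[1], "sep")
  expect_true(is.infinite(f3["sep"]))
})

test_that("subset-size selection finds a single separating feature", {
  set.seed(21)
  n <- 120
  lab <- rep(c("patient", "control"), each = n / 2)
  groups <- rep(sprintf("g%02d", 1:12), each = 10)
  x <- cbind(sep = ifelse(lab == "patient", 1, -1) + rnorm(n, 0, 0.1),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  sel <- select_size(c("sep", "n1", "n2", "n3"), x, lab, groups, seed = 3)
  expect_equal(sel$chosen_size, 1)
  expect_gt(sel$accuracy[1], 0.95)
  # identical copies: tie resolves to the smallest size
  xc <- cbind(a = x[, "sep"], b = x[, "sep"], c = x[, "sep"])
  sel2 <- select_size(c("a", "b", "c"), xc, lab, groups, seed = 3)
  expect_equal(sel2$chosen_size, 1)
})

test_that("categoricals are reintroduced after numeric selection", {
  expect_length(finalize_features(paste0("f", 1:9), feature_set_spec("standard")), 10)
  expect_length(finalize_features(paste0("f", 1:13), feature_set_spec("augmented")), 15)
  expect_warning(out <- finalize_features(character(0), feature_set_spec("standard")),
                 regexp = "categorical")
  expect_equal(out, "foot_type")
})

test_that("the fitted pipeline never touches test labels", {
  feats <- noisy_cohort()$features
  feats <- normalize_by_height(feats)
  spec <- feature_set_spec("standard")
  folds <- grouped_kfold(feats$visit_id, 3, seed = 1)
  train <- feats[folds != 1, ]
  test <- feats[folds == 1, ]
  prep <- suppressWarnings(preprocess_fit(train, spec, seed = 5, size_folds = 3))
  t1 <- prep$transform(test)
  test_shuffled <- test
  test_shuffled$class_label <- sample(test$class_label)
  t2 <- prep$transform(test_shuffled)
  expect_identical(t1$x, t2$x)
  # scaled balanced training design: mean 0, population sd 1 per numeric column
  xs <- prep$train_design$x[, prep$survivors, drop = FALSE]
  expect_true(all(abs(colMeans(xs)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(sweep(xs, 2, colMeans(xs))^2)) - 1) < 1e-9))
})
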