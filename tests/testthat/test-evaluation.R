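test_that("metrics on a perfectly ranked set are all one", {
  m <- compute_metrics(c(0.9, 0.8, 0.3, 0.2),
                       c("positive", "positive", "negative", "negative"), 0.5)
  expect_equal(m$auc, 1)
  expect_equal(m$aupr, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
})

test_that("all-equal scores give AUC 0.5 by the tie convention", {
  m <- compute_metrics(rep(0.4, 6), rep(c("positive", "negative"), 3), 0.5)
  expect_equal(m$auc, 0.5)
})

test_that("rank AUC equals the all-pairs concordance oracle, and metric identities hold", {
  set.seed(41)
  for (r in 1:20) {
    scores <- round(runif(200), 2)  # rounding forces ties
    labels <- sample(c("positive", "negative"), 200, replace = TRUE)
    if (length(unique(labels)) < 2) next
    m <- compute_metrics(scores, labels, cutoff = runif(1))
    expect_equal(m$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(m$accuracy, (m$tp + m$tn) / (m$tp + m$tn + m$fp + m$fn),
                 tolerance = 1e-12)
    expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
    expect_equal(m$specificity, m$tn / (m$tn + m$fp))
    expect_equal(m$tp + m$fn, sum(labels == "positive"))
    expect_equal(m$tn + m$fp, sum(labels == "negative"))
  }
  expect_error(compute_metrics(c(0.1, 0.2), c("positive", "positive")),
               "single class")
})

test_that("rank AUC agrees with an independent ROC library", {
  set.seed(42)
  scores <- runif(150)
  labels <- sample(c("positive", "negative"), 150, replace = TRUE)
  ours <- compute_metrics(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                        levels = c("negative", "positive"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("stratified folds partition every compound exactly once", {
  labels <- rep(c("positive", "negative"), c(37, 23))
  folds <- make_folds(labels, 10, seed = 3)
  expect_length(folds, 60)
  expect_setequal(unique(folds), 1:10)
  for (f in 1:10) {
    expect_true(any(folds == f & labels == "positive"))
    expect_true(any(folds == f & labels == "negative"))
  }
  expect_error(make_folds(labels, 24, seed = 1), "smallest class")
  expect_error(make_folds(labels, 1, seed = 1), "at least 2")
})

test_that("cross-validation of separable data is perfect and covers each compound once", {
  ds <- separable_dataset()
  rep <- crossvalidate(ds, model_config("svm", seed = 2), n_folds = 10)
  expect_equal(rep$pooled$auc, 1)
  expect_setequal(names(rep$fold_assignment), ds$ids)
  expect_length(rep$scores, length(ds$ids))
  rep_rf <- crossvalidate(ds, model_config("rf", n_trees = 200, seed = 2),
                          n_folds = 10)
  expect_equal(rep_rf$pooled$auc, 1)
  # the sensitivity-targeted cutoff keeps at least the target's share of
  # positives in every fold's calibration, so pooled sensitivity stays high
  expect_gte(rep_rf$pooled$sensitivity, 0.8)
  expect_gte(rep$pooled$specificity, 0.8)
})

test_that("grid search keeps the full table, includes the unweighted baseline, and maximizes", {
  ds <- synth_generate(synth_spec(n_pos = 30, n_neg = 30, n_bits = 60, seed = 17))
  gr <- grid_search(ds, "svm", thetas = c(1.5, Inf), n_mults = c(10, 15),
                    n_folds = 5, seed = 4, calibrate = FALSE)
  expect_equal(nrow(gr$table), 4)
  expect_true(any(is.infinite(gr$table$theta)))
  baseline <- gr$table$auc[is.infinite(gr$table$theta)][1]
  expect_gte(gr$table$auc[gr$best], baseline)

  one <- grid_search(ds, "svm", thetas = 1.5, n_mults = 15, n_folds = 5,
                     seed = 4, calibrate = FALSE)
  expect_equal(nrow(one$table), 1)
  expect_equal(one$best, 1L)
  # shared fold split across cells
  expect_identical(gr$reports[[1]]$fold_assignment, gr$reports[[4]]$fold_assignment)
})

test_that("grid search tags the failing cell", {
  ds <- separable_dataset(n_pos = 10, n_neg = 10)
  expect_error(grid_search(ds, "svm", thetas = -1, n_mults = 15, n_folds = 5,
                           seed = 1),
               "grid cell theta=-1")
})

test_that("independent test equals resubstitution on the training set and guards overlap", {
  ds <- synth_generate(synth_spec(n_pos = 25, n_neg = 25, n_bits = 40, seed = 19))
  m <- dili_train(ds, model_config("svm", seed = 7, calibrate = FALSE))
  res <- independent_test(m, ds, allow_overlap = TRUE)
  s <- predict_scores(m, ds)
  direct <- compute_metrics(s, ds$labels, cutoff = m$decision_cutoff)
  expect_equal(res$auc, direct$auc)
  expect_equal(res$tp, direct$tp)
  expect_error(independent_test(m, ds), "shares")
})

test_that("held-out performance tracks the cross-validated estimate on matched draws", {
  diffs <- vapply(1:8, function(s) {
    spec_tr <- synth_spec(n_pos = 60, n_neg = 60, n_bits = 120, seed = 1000 + s)
    spec_te <- synth_spec(n_pos = 60, n_neg = 60, n_bits = 120, seed = 2000 + s)
    tr <- synth_generate(spec_tr)
    te <- synth_generate(spec_te)
    te$ids <- paste0("te_", te$ids)
    rownames(te$X) <- te$ids
    cfg <- model_config("svm", seed = s, calibrate = FALSE)
    cv_auc <- crossvalidate(tr, cfg, n_folds = 5)$pooled$auc
    test_auc <- independent_test(dili_train(tr, cfg), te)$auc
    abs(test_auc - cv_auc)
  }, 0)
  expect_lt(mean(diffs), 0.1)
})

test_that("weight-estimation leakage mode computes one global weight vector", {
  ds <- synth_generate(synth_spec(n_pos = 20, n_neg = 20, n_bits = 40, seed = 23))
  cfg <- model_config("svm", seed = 3, calibrate = FALSE)
  leaky <- crossvalidate(ds, cfg, n_folds = 4, paper_style_leakage = TRUE)
  clean <- crossvalidate(ds, cfg, n_folds = 4, paper_style_leakage = FALSE)
  expect_true(leaky$paper_style_leakage)
  expect_false(clean$paper_style_leakage)
  expect_length(leaky$scores, length(ds$ids))
})
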