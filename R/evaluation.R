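#' Classification metrics at a decision cutoff
#'
#' Computes ranking metrics (AUC-ROC via the midrank statistic, so tied
#' scores count one half; AUPR by the step rule, summing precision times
#' recall increments over descending score thresholds) and confusion-based
#' metrics (accuracy, sensitivity, specificity, TP/FP/TN/FN) with the rule
#' "score >= cutoff is positive".
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Matching labels in `{positive, negative}`.
#' @param cutoff Decision cutoff (default 0.5).
#' @return An object of class `metric_set`: a list with `auc`, `aupr`,
#'   `accuracy`, `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn`,
#'   `cutoff`, `n`.
#' @export
compute_metrics <- function(scores, labels, cutoff = 0.5) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == "positive"
  neg <- labels == "negative"
  if (!all(pos | neg)) stop("labels must be positive/negative")
  if (!any(pos) || !any(neg)) {
    stop("both classes are required for AUC, AUPR and specificity; got a single class")
  }
  pred_pos <- scores >= cutoff
  tp <- sum(pred_pos & pos); fp <- sum(pred_pos & neg)
  fn <- sum(!pred_pos & pos); tn <- sum(!pred_pos & neg)
  structure(list(auc = auc_rank(scores, pos), aupr = aupr_step(scores, pos),
                 accuracy = (tp + tn) / length(scores),
                 sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 cutoff = cutoff, n = length(scores)),
            class = "metric_set")
}

# AUC-ROC as the normalized Mann-Whitney statistic; midranks give tied
# positive/negative pairs weight 1/2.
auc_rank <- function(scores, pos) {
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Area under the precision-recall curve: thresholds descend over distinct
# score values; each step contributes (recall gain) x (precision there).
aupr_step <- function(scores, pos) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index within each tie group
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / sum(pos)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> AUC=%.3f AUPR=%.3f acc=%.3f sens=%.3f spec=%.3f (cutoff=%.3g, n=%d)\n",
              x$auc, x$aupr, x$accuracy, x$sensitivity, x$specificity, x$cutoff, x$n))
  invisible(x)
}

#' Stratified fold assignment
#'
#' @param labels Character labels; folds are stratified within each class.
#' @param n_folds Number of folds (at least 2, at most the smallest class
#'   count so every fold keeps both classes).
#' @param seed Seed for the shuffle.
#' @return Integer vector of fold indices in `1..n_folds`.
#' @export
make_folds <- function(labels, n_folds, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  counts <- table(labels)
  if (n_folds > min(counts)) {
    stop("n_folds (", n_folds, ") exceeds the smallest class count (", min(counts),
         "); stratified folds would leave a fold without one class")
  }
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Cross-validate a weighted-fingerprint model
#'
#' Stratified k-fold cross-validation in which, by default, the substructure
#' statistics and weight vector are re-estimated inside each fold from the
#' nine training subsamples only, so the held-out compounds never influence
#' their own feature weights. Setting `paper_style_leakage = TRUE` instead
#' computes one weight vector from the full dataset before splitting, which
#' leaks label information into the evaluation and tends to inflate it; the
#' flag exists to quantify that effect.
#'
#' @param ds A labeled [fp_dataset()].
#' @param config A [model_config()].
#' @param n_folds Number of folds (default 10).
#' @param seed Seed for the fold split (defaults to `config$seed`).
#' @param folds Optional externally supplied fold assignment (used by
#'   [grid_search()] to share one split across the grid).
#' @param paper_style_leakage Estimate weights once on the full dataset.
#' @return An object of class `evaluation_report`: per-fold `metric_set`s,
#'   pooled metrics (AUC/AUPR over all held-out scores; confusion counts
#'   pooled across folds at each fold's calibrated cutoff), the pooled
#'   held-out `scores`, `fold_assignment` named by compound id, and `config`.
#' @export
crossvalidate <- function(ds, config, n_folds = 10L, seed = config$seed,
                          folds = NULL, paper_style_leakage = FALSE) {
  stopifnot(inherits(ds, "fp_dataset"), inherits(config, "model_config"))
  ds <- labeled_subset(ds)
  if (is.null(folds)) folds <- make_folds(ds$labels, n_folds, seed = seed)
  stopifnot(length(folds) == length(ds$ids))
  n_folds <- max(folds)
  fixed_wv <- if (paper_style_leakage) {
    build_weight_vector(smoothed_stats(count_substructures(ds), k = config$k),
                        theta = config$theta, n_mult = config$n_mult)
  } else NULL
  scores <- stats::setNames(numeric(length(ds$ids)), ds$ids)
  per_fold <- vector("list", n_folds)
  conf <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (f in seq_len(n_folds)) {
    tr <- subset_fp_dataset(ds, folds != f)
    te <- subset_fp_dataset(ds, folds == f)
    model <- dili_train(tr, config, fixed_weights = fixed_wv)
    s <- predict_scores(model, te)
    scores[folds == f] <- s
    m <- compute_metrics(s, te$labels, cutoff = model$decision_cutoff)
    per_fold[[f]] <- m
    conf <- conf + c(tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn)
  }
  pos <- ds$labels == "positive"
  pooled <- list(auc = auc_rank(scores, pos), aupr = aupr_step(scores, pos),
                 accuracy = (conf[["tp"]] + conf[["tn"]]) / length(scores),
                 sensitivity = conf[["tp"]] / (conf[["tp"]] + conf[["fn"]]),
                 specificity = conf[["tn"]] / (conf[["tn"]] + conf[["fp"]]),
                 tp = conf[["tp"]], fp = conf[["fp"]],
                 tn = conf[["tn"]], fn = conf[["fn"]])
  structure(list(per_fold = per_fold, pooled = pooled,
                 mean_fold = list(auc = mean(vapply(per_fold, `[[`, 0, "auc")),
                                  aupr = mean(vapply(per_fold, `[[`, 0, "aupr")),
                                  accuracy = mean(vapply(per_fold, `[[`, 0, "accuracy"))),
                 scores = scores, labels = ds$labels,
                 fold_assignment = stats::setNames(folds, ds$ids),
                 config = config, paper_style_leakage = paper_style_leakage),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d-fold CV (%s): pooled AUC=%.3f AUPR=%.3f acc=%.3f sens=%.3f spec=%.3f\n",
              length(x$per_fold), x$config$algorithm, x$pooled$auc, x$pooled$aupr,
              x$pooled$accuracy, x$pooled$sensitivity, x$pooled$specificity))
  invisible(x)
}

#' Grid search over weighting parameters
#'
#' Cross-validates every (theta, n_mult) combination with the same stratified
#' fold split and returns the full table plus the best cell under the
#' selection metric. Including `theta = Inf` in `thetas` adds the unweighted
#' baseline to the comparison.
#'
#' @param ds A labeled [fp_dataset()].
#' @param algorithm `"rf"` or `"svm"`.
#' @param thetas Numeric vector of selection thresholds (default
#'   `c(0.5, 1, 1.5, 2, 2.5)`).
#' @param n_mults Numeric vector of multipliers (default `c(5, 10, 15, 20)`).
#' @param n_folds,seed Passed to the shared fold split.
#' @param metric Pooled selection metric (default `"auc"`).
#' @param ... Further arguments to [model_config()] (e.g. `k`, `cost`,
#'   `calibrate`).
#' @return An object of class `grid_result`: `table` (one row per cell with
#'   pooled metrics), `best` (row index of the argmax), `reports`, and the
#'   shared `fold_assignment`.
#' @export
grid_search <- function(ds, algorithm, thetas = c(0.5, 1, 1.5, 2, 2.5),
                        n_mults = c(5, 10, 15, 20), n_folds = 10L, seed = 1L,
                        metric = "auc", ...) {
  stopifnot(length(thetas) >= 1, length(n_mults) >= 1)
  ds <- labeled_subset(ds)
  folds <- make_folds(ds$labels, n_folds, seed = seed)
  cells <- expand.grid(theta = thetas, n_mult = n_mults)
  reports <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    config <- model_config(algorithm = algorithm, theta = cells$theta[i],
                           n_mult = cells$n_mult[i], seed = seed, ...)
    rep_i <- tryCatch(
      crossvalidate(ds, config, folds = folds),
      error = function(e) stop("grid cell theta=", cells$theta[i], ", n_mult=",
                               cells$n_mult[i], ": ", conditionMessage(e)))
    reports[[i]] <- rep_i
    rows[[i]] <- data.frame(theta = cells$theta[i], n_mult = cells$n_mult[i],
                            algorithm = algorithm,
                            auc = rep_i$pooled$auc, aupr = rep_i$pooled$aupr,
                            accuracy = rep_i$pooled$accuracy,
                            sensitivity = rep_i$pooled$sensitivity,
                            specificity = rep_i$pooled$specificity)
  }
  table <- do.call(rbind, rows)
  structure(list(table = table, best = which.max(table[[metric]]),
                 metric = metric, reports = reports,
                 fold_assignment = stats::setNames(folds, ds$ids)),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  b <- x$table[x$best, ]
  cat("<grid_result> ", nrow(x$table), " cells; best by ", x$metric, ": theta=",
      b$theta, ", n_mult=", b$n_mult, " (", x$metric, "=",
      round(b[[x$metric]], 3), ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Evaluate a frozen model on an independent test set
#'
#' Applies a trained model — weights and calibrated cutoff fixed from the
#' training data — to a labeled test set. The test set must be disjoint from
#' the training compounds (prepare it with [merge_deduplicate()]); an overlap
#' is an error unless explicitly overridden, since shared compounds make the
#' test no longer independent.
#'
#' @param model A `dili_model`.
#' @param test_ds A labeled [fp_dataset()].
#' @param allow_overlap Skip the train/test disjointness check (e.g. for
#'   deliberate resubstitution sanity runs).
#' @return A `metric_set` computed at the model's calibrated cutoff.
#' @export
independent_test <- function(model, test_ds, allow_overlap = FALSE) {
  stopifnot(inherits(model, "dili_model"), inherits(test_ds, "fp_dataset"))
  test_ds <- labeled_subset(test_ds)
  if (!allow_overlap) {
    overlap <- intersect(test_ds$ids, model$training_ids)
    if (length(overlap)) {
      stop("test set shares ", length(overlap), " compound(s) with the training set ",
           "(e.g. '", overlap[1], "'); deduplicate first or set allow_overlap = TRUE")
    }
  }
  s <- predict_scores(model, test_ds)
  compute_metrics(s, test_ds$labels, cutoff = model$decision_cutoff)
}
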