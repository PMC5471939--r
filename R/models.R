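#' Model configuration
#'
#' Bundles every tunable of the weighted-fingerprint pipeline. Defaults follow
#' the package's standard study conditions: add-one Laplace smoothing,
#' log-odds threshold 1.5 with multiplier 15, 500 random-forest trees, SVM
#' cost 1 on the continuous Tanimoto kernel, and a decision cutoff calibrated
#' to sensitivity 0.8 — toxic compounds missed are costlier than nontoxic
#' compounds flagged.
#'
#' @param algorithm `"rf"` (random forest on the weighted feature matrix) or
#'   `"svm"` (C-classification on the precomputed Tanimoto kernel of weighted
#'   fingerprints).
#' @param theta Log-odds selection threshold (> 0; `Inf` disables weighting).
#' @param n_mult Weight amplification multiplier.
#' @param k Laplace pseudo-count.
#' @param n_trees Number of random-forest trees.
#' @param cost SVM cost parameter C.
#' @param kernel_variant `"continuous"` or `"binary"` Tanimoto kernel.
#' @param target_sensitivity Sensitivity the decision cutoff is calibrated to.
#' @param seed Integer seed for all stochastic components.
#' @param calibrate Calibrate the cutoff on held-out training scores
#'   (out-of-bag votes for RF, inner 5-fold decision values for SVM). When
#'   `FALSE` the cutoff is fixed at 0.5; ranking metrics are unaffected.
#' @return An object of class `model_config`.
#' @export
model_config <- function(algorithm = c("rf", "svm"), theta = 1.5, n_mult = 15,
                         k = 1, n_trees = 500L, cost = 1,
                         kernel_variant = c("continuous", "binary"),
                         target_sensitivity = 0.8, seed = 1L,
                         calibrate = TRUE) {
  algorithm <- match.arg(algorithm)
  kernel_variant <- match.arg(kernel_variant)
  stopifnot(is.numeric(theta), length(theta) == 1L,
            n_mult > 0, k >= 0, n_trees >= 1, cost > 0,
            target_sensitivity > 0, target_sensitivity <= 1)
  structure(list(algorithm = algorithm, theta = theta, n_mult = n_mult, k = k,
                 n_trees = as.integer(n_trees), cost = cost,
                 kernel_variant = kernel_variant,
                 target_sensitivity = target_sensitivity,
                 seed = as.integer(seed), calibrate = isTRUE(calibrate)),
            class = "model_config")
}

labeled_subset <- function(ds) {
  subset_fp_dataset(ds, ds$labels %in% c("positive", "negative"))
}

label_factor <- function(labels) factor(labels, levels = c("negative", "positive"))

#' Train a weighted-fingerprint DILI classifier
#'
#' Computes substructure statistics and the weight vector from the (labeled)
#' training data only, applies the weights element-wise to the fingerprints,
#' and fits the configured learner: a random forest on the weighted feature
#' matrix, or an SVM on the precomputed Tanimoto kernel of the weighted rows.
#' The decision cutoff is then calibrated to `config$target_sensitivity` on
#' held-out training scores (out-of-bag votes for RF; inner 5-fold decision
#' values for SVM) so resubstitution optimism does not leak into the cutoff.
#'
#' @param ds A labeled [fp_dataset()] (unlabeled records are ignored).
#' @param config A [model_config()].
#' @param fixed_weights Optional `weight_vector` to use instead of estimating
#'   one from `ds` (used e.g. to study weight-estimation leakage in
#'   cross-validation).
#' @return An object of class `dili_model`.
#' @export
dili_train <- function(ds, config, fixed_weights = NULL) {
  stopifnot(inherits(ds, "fp_dataset"), inherits(config, "model_config"))
  ds <- labeled_subset(ds)
  if (!any(ds$labels == "positive") || !any(ds$labels == "negative")) {
    stop("training data must contain both positive and negative compounds")
  }
  y <- label_factor(ds$labels)
  set.seed(config$seed)
  wv <- fixed_weights %||%
    build_weight_vector(smoothed_stats(count_substructures(ds), k = config$k),
                        theta = config$theta, n_mult = config$n_mult)
  Xw <- apply_weights(ds$X, wv)
  model <- list(config = config, weight_vector = wv, algorithm = config$algorithm,
                training_ids = ds$ids, training_labels = ds$labels,
                n_bits = ds$n_bits)
  if (config$algorithm == "rf") {
    fit <- randomForest::randomForest(x = Xw, y = y, ntree = config$n_trees,
                                      mtry = max(1L, floor(sqrt(ncol(Xw)))))
    model$fit <- fit
    calib_scores <- fit$votes[, "positive"]
  } else {
    K <- kernel_matrix(Xw, variant = config$kernel_variant)$K
    sv <- fit_kernel_svm(K, y, config$cost)
    model$fit <- sv$fit
    model$sv_index <- sv$sv_index
    model$sign <- sv$sign
    model$train_Xw <- Xw
    calib_scores <- if (config$calibrate) {
      svm_inner_cv_scores(K, y, config$cost, n_folds = 5L, seed = config$seed)
    } else NULL
  }
  model$decision_cutoff <- if (config$calibrate) {
    calibrate_cutoff(calib_scores, ds$labels, config$target_sensitivity)
  } else 0.5
  structure(model, class = "dili_model")
}

# Fit a C-SVM on a precomputed kernel and record the decision-value
# orientation (kernlab's sign depends on factor-level ordering internals).
fit_kernel_svm <- function(K, y, cost) {
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc", C = cost)
  svi <- kernlab::SVindex(fit)
  dec <- kernlab::predict(fit, kernlab::as.kernelMatrix(K[, svi, drop = FALSE]),
                          type = "decision")[, 1]
  sgn <- if (mean(dec[y == "positive"]) >= mean(dec[y == "negative"])) 1 else -1
  list(fit = fit, sv_index = svi, sign = sgn)
}

# Held-out decision scores for cutoff calibration: stratified inner CV over
# the training kernel.
svm_inner_cv_scores <- function(K, y, cost, n_folds = 5L, seed = 1L) {
  n_folds <- min(n_folds, min(table(y)))
  folds <- make_folds(as.character(y), n_folds, seed = seed)
  scores <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- folds == f
    sv <- fit_kernel_svm(K[tr, tr, drop = FALSE], y[tr], cost)
    dec <- kernlab::predict(sv$fit,
                            kernlab::as.kernelMatrix(
                              K[te, tr, drop = FALSE][, sv$sv_index, drop = FALSE]),
                            type = "decision")[, 1]
    scores[te] <- stats::plogis(sv$sign * dec)
  }
  scores
}

#' @export
print.dili_model <- function(x, ...) {
  cat("<dili_model> ", x$algorithm, "; ", length(x$training_ids),
      " training compounds; ", length(x$weight_vector$selected),
      " weighted bits (theta=", x$config$theta, ", n=", x$config$n_mult,
      "); cutoff=", signif(x$decision_cutoff, 4), "\n", sep = "")
  invisible(x)
}

#' Score compounds with a trained model
#'
#' Applies the model's stored weight vector to the new fingerprints and
#' returns one score per compound in `[0, 1]`, higher meaning more
#' DILI-positive: the fraction of trees voting positive (RF) or a logistic
#' transform of the SVM decision value computed on the Tanimoto kernel
#' between the weighted test rows and the weighted training rows.
#'
#' @param model A `dili_model`.
#' @param ds An [fp_dataset()] (labels not required).
#' @return Named numeric vector of scores.
#' @export
predict_scores <- function(model, ds) {
  stopifnot(inherits(model, "dili_model"), inherits(ds, "fp_dataset"))
  if (ds$n_bits != model$n_bits) {
    stop("fingerprint bit count (", ds$n_bits, ") does not match the model (",
         model$n_bits, ")")
  }
  if (length(ds$ids) == 0L) return(stats::setNames(numeric(0), character(0)))
  Xw <- apply_weights(ds$X, model$weight_vector)
  if (model$algorithm == "rf") {
    p <- stats::predict(model$fit, Xw, type = "prob")[, "positive"]
  } else {
    K <- kernel_matrix(Xw, model$train_Xw, variant = model$config$kernel_variant)$K
    dec <- kernlab::predict(model$fit,
                            kernlab::as.kernelMatrix(K[, model$sv_index, drop = FALSE]),
                            type = "decision")[, 1]
    p <- stats::plogis(model$sign * dec)
  }
  stats::setNames(as.numeric(p), ds$ids)
}

#' Calibrate a decision cutoff to a target sensitivity
#'
#' Returns the largest cutoff `c` such that the fraction of positive-labeled
#' compounds with score `>= c` is at least `target_sensitivity`; the
#' classification rule is "score `>= c` is positive". A high target trades
#' specificity for sensitivity deliberately: flagging a nontoxic compound is
#' safer than clearing a hepatotoxic one.
#'
#' @param scores Numeric scores.
#' @param labels Matching labels (`"positive"`/`"negative"`; others ignored).
#' @param target_sensitivity Required sensitivity in `(0, 1]` (default 0.8).
#' @return The calibrated cutoff.
#' @export
calibrate_cutoff <- function(scores, labels, target_sensitivity = 0.8) {
  stopifnot(length(scores) == length(labels),
            target_sensitivity > 0, target_sensitivity <= 1)
  ps <- scores[labels == "positive"]
  if (length(ps) == 0L) stop("cutoff calibration requires at least one positive compound")
  for (cand in sort(unique(ps), decreasing = TRUE)) {
    if (mean(ps >= cand) >= target_sensitivity) return(cand)
  }
  min(ps)
}

#' Predict class labels with a trained model
#'
#' @param model A `dili_model`.
#' @param ds An [fp_dataset()].
#' @param cutoff Decision cutoff; defaults to the model's calibrated cutoff.
#' @return Named character vector, `"positive"` where score `>= cutoff`.
#' @export
predict_labels <- function(model, ds, cutoff = model$decision_cutoff) {
  s <- predict_scores(model, ds)
  stats::setNames(ifelse(s >= cutoff, "positive", "negative"), names(s))
}

#' Persist a trained model to a directory
#'
#' Writes the weight table (CSV + JSON), the resolved configuration (JSON),
#' the training fingerprints and IDs, and the opaque fitted learner state, so
#' that [load_model()] reproduces predictions bit-identically on the same
#' platform.
#'
#' @param model A `dili_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "dili_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_weight_table(model$weight_vector, file.path(dir, "weights.csv"))
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(model$training_ids, file.path(dir, "training_ids.txt"))
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a model saved with [save_model()]
#'
#' @param dir Model directory.
#' @return A `dili_model`.
#' @export
load_model <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) stop("no model.rds under ", dir)
  model <- readRDS(path)
  stopifnot(inherits(model, "dili_model"))
  model
}
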