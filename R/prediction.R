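#' Binarize age into young/old classes
#'
#' Subjects at or above the cutoff are labeled `old` (the conventional
#' "elderly" threshold of 65 years is the default), the rest `young`.
#'
#' @param meta Sample metadata.
#' @param cutoff Age cutoff in years (default 65); `age >= cutoff` is old.
#' @return Factor with levels `young`, `old`, named by sample id.
#' @export
binarize_age <- function(meta, cutoff = 65) {
  .check_metadata(meta)
  lab <- factor(ifelse(meta$age >= cutoff, "old", "young"),
                levels = c("young", "old"))
  if (any(tabulate(lab, 2L) == 0L))
    stop("age cutoff ", cutoff, " leaves the '",
         levels(lab)[tabulate(lab, 2L) == 0L][1L], "' class empty")
  setNames(lab, meta$sample_id)
}

#' Define a binary classification task on a profile matrix
#'
#' @param pm A [profile_matrix()] at stage `"log10"`, or a numeric matrix
#'   (features x samples).
#' @param labels Binary labels aligned with the matrix columns (factor or
#'   character).
#' @param positive Name of the positive class (drives sensitivity); default
#'   the second factor level.
#' @return An object of class `classification_task`.
#' @export
classification_task <- function(pm, labels, positive = NULL) {
  values <- if (inherits(pm, "profile_matrix")) pm$values else pm
  stopifnot(is.matrix(values), ncol(values) == length(labels))
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("labels must have exactly two observed classes")
  labels <- droplevels(labels)
  if (is.null(positive)) positive <- levels(labels)[2L]
  if (!positive %in% levels(labels))
    stop("positive class '", positive, "' not among the labels")
  # glmnet's binomial coding treats the second level as the modeled class
  labels <- factor(labels, levels = c(setdiff(levels(labels), positive),
                                      positive))
  structure(list(x = t(values), y = labels, positive = positive),
            class = "classification_task")
}

#' Accuracy, sensitivity and specificity of binary predictions
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / n`. A metric whose denominator is zero (no
#' positive, or no negative, truth labels) is reported as `NA`.
#'
#' @param truth,predicted Vectors of class labels, equal length.
#' @param positive Name of the positive class.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(truth, predicted, positive) {
  stopifnot(length(truth) == length(predicted))
  truth_pos <- truth == positive
  pred_pos <- predicted == positive
  tp <- sum(truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Configuration for resampled penalized classification
#'
#' @param alpha Elastic-net mixing parameter in \[0, 1\] (0.8 for feature
#'   selection; 0 for ridge refits).
#' @param n_lambda Length of the penalty path (default 100).
#' @param n_folds Cross-validation folds for selecting `lambda.min`
#'   (default 10; selection criterion is the binomial deviance).
#' @param train_fraction Fraction of samples in each training split
#'   (default 2/3; splits are stratified by class).
#' @param n_iter Number of train/test resampling iterations (default 500).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return A validated list of class `penalized_config`.
#' @export
penalized_config <- function(alpha = 0.8, n_lambda = 100, n_folds = 10,
                             train_fraction = 2 / 3, n_iter = 500,
                             seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, n_lambda >= 2, n_folds >= 3,
            train_fraction > 0, train_fraction < 1, n_iter >= 1)
  structure(list(alpha = alpha, n_lambda = as.integer(n_lambda),
                 n_folds = as.integer(n_folds),
                 train_fraction = train_fraction,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "penalized_config")
}

# One stratified train/test split of indices by class.
.stratified_split <- function(y, train_fraction) {
  train <- integer(0)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

#' Resampled penalized-logistic classification with importance index
#'
#' Runs `n_iter` iterations of: a stratified 2/3-1/3 train/test split; a
#' penalized logistic regression (glmnet) on the training set along a
#' 100-value lambda path with the penalty strength chosen by 10-fold
#' cross-validated deviance (`lambda.min`; features are standardized
#' internally on the training data, so no test information leaks into the
#' fit); prediction on the test set thresholded at probability 0.5; and
#' accuracy/sensitivity/specificity on the test set. A feature's
#' importance index is the number of iterations in which its coefficient in
#' the selected model is nonzero. The standard deviation of accuracy across
#' iterations measures model stability. An iteration whose cross-validation
#' fit degenerates (e.g. a single-class fold in a tiny class) is redrawn
#' and counted in `n_redrawn`.
#'
#' @param task A [classification_task()].
#' @param cfg A [penalized_config()].
#' @return A list with `report` (class `resample_report`: per-iteration
#'   metric table plus `mean_accuracy`, `mean_sensitivity`,
#'   `mean_specificity`, `sd_accuracy`, `n_redrawn`) and `importance`
#'   (data.frame `feature_id`, `importance`, sorted by decreasing
#'   importance, ties by id).
#' @export
resampled_elastic_net <- function(task, cfg = penalized_config()) {
  stopifnot(inherits(task, "classification_task"),
            inherits(cfg, "penalized_config"))
  if (min(table(task$y)) < 3L)
    stop("each class needs at least 3 samples")
  iter_seeds <- .child_seeds(cfg$seed, cfg$n_iter)
  nf <- ncol(task$x)
  counts <- setNames(integer(nf), colnames(task$x))
  metrics <- matrix(NA_real_, cfg$n_iter, 3,
                    dimnames = list(NULL, c("accuracy", "sensitivity",
                                            "specificity")))
  n_redrawn <- 0L
  for (i in seq_len(cfg$n_iter)) {
    res <- .with_seed(iter_seeds[i], {
      attempt <- NULL
      for (try_ in 1:100) {
        train <- .stratified_split(task$y, cfg$train_fraction)
        test <- setdiff(seq_along(task$y), train)
        fit <- tryCatch(
          glmnet::cv.glmnet(task$x[train, , drop = FALSE], task$y[train],
                            family = "binomial", alpha = cfg$alpha,
                            nlambda = cfg$n_lambda, nfolds = cfg$n_folds,
                            type.measure = "deviance", standardize = TRUE),
          error = function(e) NULL)
        if (!is.null(fit)) { attempt <- list(fit = fit, train = train,
                                             test = test, tries = try_); break }
      }
      if (is.null(attempt)) stop("cross-validated fit failed repeatedly")
      attempt
    })
    n_redrawn <- n_redrawn + (res$tries - 1L)
    prob <- predict(res$fit, newx = task$x[res$test, , drop = FALSE],
                    s = "lambda.min", type = "response")[, 1L]
    pred <- ifelse(prob > 0.5, task$positive,
                   setdiff(levels(task$y), task$positive))
    metrics[i, ] <- classification_metrics(task$y[res$test], pred,
                                           task$positive)
    beta <- coef(res$fit, s = "lambda.min")[-1L, 1L]
    counts[beta != 0] <- counts[beta != 0] + 1L
  }
  importance <- data.frame(feature_id = names(counts),
                           importance = unname(counts),
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$importance,
                                 importance$feature_id), , drop = FALSE]
  rownames(importance) <- NULL
  report <- structure(list(
    metrics = as.data.frame(metrics),
    mean_accuracy = mean(metrics[, "accuracy"]),
    mean_sensitivity = mean(metrics[, "sensitivity"], na.rm = TRUE),
    mean_specificity = mean(metrics[, "specificity"], na.rm = TRUE),
    sd_accuracy = sd(metrics[, "accuracy"]),
    n_iter = cfg$n_iter, n_redrawn = n_redrawn, config = cfg
  ), class = "resample_report")
  list(report = report, importance = importance)
}

#' @export
print.resample_report <- function(x, ...) {
  cat(sprintf(paste0("<resample_report> %d iterations: accuracy %.3f ",
                     "(SD %.3f), sensitivity %.3f, specificity %.3f\n"),
              x$n_iter, x$mean_accuracy, x$sd_accuracy, x$mean_sensitivity,
              x$mean_specificity))
  invisible(x)
}

#' Ridge refits on the top-k most important features
#'
#' For each `k`, restricts the task to the `k` features with the highest
#' importance index (ties broken by feature id) and repeats the full
#' resampling procedure with a pure ridge penalty (`alpha = 0`), reporting
#' mean accuracy/sensitivity/specificity and the SD of accuracy per `k`.
#'
#' @param task A [classification_task()].
#' @param importance Importance table from [resampled_elastic_net()].
#' @param ks Panel sizes to evaluate (default `c(2, 5, 10, 15, 20)`).
#' @param cfg A [penalized_config()]; its `alpha` is overridden to 0.
#' @return A `data.frame` with one row per `k` (`k`, `mean_accuracy`,
#'   `mean_sensitivity`, `mean_specificity`, `sd_accuracy`); full
#'   per-k reports in `attr(, "reports")`.
#' @export
top_k_ridge <- function(task, importance, ks = c(2, 5, 10, 15, 20),
                        cfg = penalized_config()) {
  stopifnot(inherits(task, "classification_task"))
  missing_feats <- setdiff(colnames(task$x), importance$feature_id)
  if (length(missing_feats))
    stop("importance table does not cover the matrix features")
  ever <- sum(importance$importance > 0)
  if (max(ks) > ever)
    stop("only ", ever, " feature(s) were ever selected; the largest ",
         "attainable k is ", ever)
  ord <- importance[order(-importance$importance, importance$feature_id), ]
  cfg_ridge <- cfg
  cfg_ridge$alpha <- 0
  reports <- lapply(ks, function(k) {
    feats <- ord$feature_id[seq_len(k)]
    sub <- classification_task(t(task$x[, feats, drop = FALSE]), task$y,
                               positive = task$positive)
    resampled_elastic_net(sub, cfg_ridge)$report
  })
  out <- data.frame(
    k = ks,
    mean_accuracy = vapply(reports, `[[`, numeric(1), "mean_accuracy"),
    mean_sensitivity = vapply(reports, `[[`, numeric(1), "mean_sensitivity"),
    mean_specificity = vapply(reports, `[[`, numeric(1), "mean_specificity"),
    sd_accuracy = vapply(reports, `[[`, numeric(1), "sd_accuracy")
  )
  attr(out, "reports") <- setNames(reports, ks)
  out
}
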