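# Tumour grading: SVM classification of image-level aberrance features,
# repeated stratified cross-validation, per-class metrics, ROC, and the
# Kruskal-Wallis group test.

GRADES <- c("normal", "low_grade", "high_grade")

#' Grading configuration
#'
#' @param task `"two_class"` (normal vs cancer; low and high grade merged)
#'   or `"three_class"`.
#' @param feature_set `"fs1"` (mean BAM + BAM entropy) or `"fs2"`
#'   (fs1 + Regularity Index).
#' @param kernel SVM kernel: `"rbf"` (default), `"linear"`, `"polynomial"`
#'   or `"sigmoid"`.
#' @param C regularization cost (default 1).
#' @param gamma kernel width, or `"auto"` for
#'   `1 / (n_features * pooled feature variance)` computed on the
#'   standardized training features.
#' @param folds cross-validation folds (default 3).
#' @param repeats number of repeated CV rounds with reshuffled folds
#'   (default 10).
#' @param seed RNG seed for fold shuffling (default 0).
#' @return list of class `grading_config`.
#' @export
grading_config <- function(task = c("three_class", "two_class"),
                           feature_set = c("fs2", "fs1"),
                           kernel = c("rbf", "linear", "polynomial", "sigmoid"),
                           C = 1, gamma = "auto", folds = 3L, repeats = 10L,
                           seed = 0L) {
  task <- match.arg(task)
  feature_set <- match.arg(feature_set)
  kernel <- match.arg(kernel)
  if (folds < 2) gb_stop("glandbam_invalid_configuration", "folds must be >= 2")
  if (repeats < 1) gb_stop("glandbam_invalid_configuration", "repeats must be >= 1")
  structure(list(task = task, feature_set = feature_set, kernel = kernel,
                 C = C, gamma = gamma, folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "grading_config")
}

feature_columns <- function(feature_set) {
  if (feature_set == "fs1") c("mean_bam", "bam_entropy")
  else c("mean_bam", "bam_entropy", "regularity_index")
}

grading_matrix <- function(features, cfg) {
  cols <- feature_columns(cfg$feature_set)
  missing <- setdiff(cols, names(features))
  if (length(missing))
    gb_stop("glandbam_schema", "feature table lacks column(s): %s",
            paste(missing, collapse = ", "))
  as.matrix(features[, cols, drop = FALSE])
}

grading_labels <- function(features, cfg) {
  lab <- as.character(features$label)
  bad <- setdiff(unique(lab), GRADES)
  if (length(bad))
    gb_stop("glandbam_schema", "unknown grade label(s): %s", paste(bad, collapse = ", "))
  if (cfg$task == "two_class") {
    lab[lab %in% c("low_grade", "high_grade")] <- "cancer"
    factor(lab, levels = c("normal", "cancer"))
  } else {
    factor(lab, levels = GRADES)
  }
}

#' Train a grading SVM
#'
#' Standardizes the selected feature columns to zero mean / unit variance
#' (statistics stored in the model) and fits a maximum-margin classifier with
#' the configured kernel. For the two-class task low- and high-grade images
#' are merged into one cancer class before fitting.
#'
#' @param features feature table (rows = images) with the columns of the
#'   configured feature set and a `label` column.
#' @param cfg a [grading_config()].
#' @return object of class `grading_model`.
#' @export
train_grader <- function(features, cfg = grading_config()) {
  X <- grading_matrix(features, cfg)
  y <- droplevels(grading_labels(features, cfg))
  if (nlevels(y) < 2)
    gb_stop("glandbam_invalid_input", "training data contains a single class")
  center <- colMeans(X)
  scale_ <- apply(X, 2L, sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(X, center = center, scale = scale_)
  gamma <- if (identical(cfg$gamma, "auto"))
    1 / (ncol(Xs) * mean(apply(Xs, 2L, var))) else cfg$gamma
  kern <- switch(cfg$kernel, rbf = "radial", cfg$kernel)
  fit <- e1071::svm(Xs, y, kernel = kern, cost = cfg$C, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale_,
                 levels = levels(y), cfg = cfg),
            class = "grading_model")
}

#' @export
predict.grading_model <- function(object, newdata, decision_values = FALSE, ...) {
  X <- grading_matrix(newdata, object$cfg)
  Xs <- scale(X, center = object$center, scale = object$scale)
  pred <- predict(object$fit, Xs, decision.values = decision_values)
  if (!decision_values) return(pred)
  list(class = factor(as.character(pred), levels = object$levels),
       scores = ovr_scores(attr(pred, "decision.values"), object$levels))
}

# one-vs-rest scores from libsvm's pairwise decision values: for class k, sum
# the signed decision values of every pair involving k (positive favours the
# first-named class of the pair). Deterministic, unlike Platt probabilities.
ovr_scores <- function(dv, levels) {
  scores <- matrix(0, nrow(dv), length(levels),
                   dimnames = list(NULL, levels))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1L]]
    scores[, pair[1L]] <- scores[, pair[1L]] + dv[, cn]
    scores[, pair[2L]] <- scores[, pair[2L]] - dv[, cn]
  }
  scores
}

binary_metrics <- function(tp, fn, fp, tn) {
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
}

per_class_metrics <- function(truth, pred, classes) {
  out <- lapply(classes, function(k) {
    tp <- sum(truth == k & pred == k)
    fn <- sum(truth == k & pred != k)
    fp <- sum(truth != k & pred == k)
    tn <- sum(truth != k & pred != k)
    binary_metrics(tp, fn, fp, tn)
  })
  names(out) <- classes
  out
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      gb_stop("glandbam_invalid_configuration",
              "class '%s' has %d member(s), fewer than %d folds", cl, length(idx), k)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Repeated stratified cross-validation of the grader
#'
#' Stratified k-fold cross-validation at the image level, repeated with
#' reshuffled folds. Accuracy is the fraction of images classified correctly;
#' per-class precision, recall, specificity and F1 are computed per
#' fold-run and summarized as mean and standard deviation across runs. Held-out
#' one-vs-rest decision scores are pooled into one ROC curve and AUC per
#' class. For the three-class task the pooled predictions are additionally
#' collapsed into the two binary views (cancer vs normal; high grade vs rest)
#' via [evaluate_binary_views()].
#'
#' @param features feature table with a `label` column.
#' @param cfg a [grading_config()].
#' @return list of class `eval_report`: `accuracy` (mean, sd), `per_class`
#'   data frame, summed `confusion` matrix, `roc` (per class: points + AUC),
#'   `binary_views` (three-class task only), plus the run bookkeeping.
#' @export
cross_validate <- function(features, cfg = grading_config()) {
  y <- grading_labels(features, cfg)
  classes <- levels(y)
  set.seed(cfg$seed)
  acc_runs <- numeric(0)
  class_runs <- list()
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(truth = classes, pred = classes))
  pooled_pred <- character(0)
  pooled_truth <- character(0)
  pooled_scores <- NULL
  for (rep_i in seq_len(cfg$repeats)) {
    fold <- stratified_folds(y, cfg$folds)
    for (f in seq_len(cfg$folds)) {
      test <- fold == f
      model <- train_grader(features[!test, , drop = FALSE], cfg)
      pr <- predict(model, features[test, , drop = FALSE], decision_values = TRUE)
      truth <- y[test]
      pred <- factor(as.character(pr$class), levels = classes)
      acc_runs <- c(acc_runs, mean(pred == truth))
      class_runs[[length(class_runs) + 1L]] <-
        per_class_metrics(truth, pred, classes)
      confusion <- confusion + unclass(table(truth, pred))
      pooled_pred <- c(pooled_pred, as.character(pred))
      pooled_truth <- c(pooled_truth, as.character(truth))
      sc <- matrix(NA_real_, sum(test), length(classes),
                   dimnames = list(NULL, classes))
      sc[, colnames(pr$scores)] <- pr$scores
      pooled_scores <- rbind(pooled_scores, sc)
    }
  }
  per_class <- do.call(rbind, lapply(classes, function(k) {
    vals <- t(vapply(class_runs, function(run) run[[k]], numeric(5L)))
    data.frame(class = k,
               t(setNames(colMeans(vals, na.rm = TRUE),
                          paste0(colnames(vals), "_mean"))),
               t(setNames(apply(vals, 2L, sd, na.rm = TRUE),
                          paste0(colnames(vals), "_sd"))),
               stringsAsFactors = FALSE)
  }))
  roc <- lapply(setNames(classes, classes), function(k)
    roc_analysis(pooled_scores[, k], pooled_truth, positive = k))
  out <- list(task = cfg$task, feature_set = cfg$feature_set,
              n_images = nrow(features), folds = cfg$folds,
              repeats = cfg$repeats,
              accuracy = c(mean = mean(acc_runs), sd = sd(acc_runs)),
              per_class = per_class, confusion = confusion, roc = roc)
  if (cfg$task == "three_class")
    out$binary_views <- evaluate_binary_views(pooled_truth, pooled_pred)
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s / %s: accuracy %.2f%% +/- %.2f%% (%d-fold x %d repeats, n = %d)\n",
              x$task, x$feature_set, 100 * x$accuracy[["mean"]],
              100 * x$accuracy[["sd"]], x$folds, x$repeats, x$n_images))
  for (k in names(x$roc))
    cat(sprintf("  AUC[%s] = %.3f\n", k, x$roc[[k]]$auc))
  invisible(x)
}

#' Binary views of three-class predictions
#'
#' Collapses three-class predictions into the two clinically meaningful
#' binary problems: *Cancer* (low and high grade positive, normal negative)
#' and *High grade* (high grade positive, normal and low grade negative), and
#' computes accuracy, precision, recall, specificity and F1 for each view.
#'
#' @param truth,pred character or factor vectors of grades.
#' @return data frame with one row per view.
#' @export
evaluate_binary_views <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  views <- list(cancer = c("low_grade", "high_grade"),
                high_grade = "high_grade")
  do.call(rbind, lapply(names(views), function(v) {
    pos <- views[[v]]
    tp <- sum(truth %in% pos & pred %in% pos)
    fn <- sum(truth %in% pos & !pred %in% pos)
    fp <- sum(!truth %in% pos & pred %in% pos)
    tn <- sum(!truth %in% pos & !pred %in% pos)
    data.frame(view = v, t(binary_metrics(tp, fn, fp, tn)),
               stringsAsFactors = FALSE)
  }))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps all unique decision scores as thresholds (score >= threshold
#' predicts positive), returns the (FPR, TPR) points anchored at (0,0) and
#' (1,1), and the trapezoid AUC.
#'
#' @param scores real-valued decision scores, larger = more positive.
#' @param labels class labels.
#' @param positive the positive class.
#' @return list with `points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_analysis <- function(scores, labels, positive) {
  pos <- labels == positive
  P <- sum(pos); Ng <- sum(!pos)
  if (P == 0 || Ng == 0)
    gb_stop("glandbam_undefined_auc", "need both classes present for a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(s, fromLast = TRUE)  # one point per distinct threshold
  tpr <- c(0, tp[last] / P, 1)
  fpr <- c(0, fp[last] / Ng, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Kruskal-Wallis rank test across grade groups
#'
#' Tie-corrected H statistic with a chi-square p-value on `length(groups) - 1`
#' degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups list of two or more numeric vectors.
#' @return list with `H` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L || any(!lengths(groups)))
    gb_stop("glandbam_invalid_input", "need >= 2 non-empty groups")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    gb_stop("glandbam_degenerate_test", "all values identical across groups")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p_value = unname(kt$p.value))
}
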