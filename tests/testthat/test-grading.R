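# synthetic, well-separated feature table used in several tests
separable_features <- function(n_per_class = 12, sep = 10, noise = 0.05, seed = 1) {
  set.seed(seed)
  centers <- list(normal = c(0, 0, 1), low_grade = c(sep, 0, 0.4),
                  high_grade = c(sep, sep, 0))
  do.call(rbind, lapply(names(centers), function(g) {
    ctr <- centers[[g]]
    data.frame(image_id = sprintf("%s_%d", g, seq_len(n_per_class)),
               mean_bam = ctr[1] + rnorm(n_per_class, 0, noise),
               bam_entropy = ctr[2] + rnorm(n_per_class, 0, noise),
               regularity_index = pmin(pmax(ctr[3] + rnorm(n_per_class, 0, noise), 0), 1),
               label = g, stringsAsFactors = FALSE)
  }))
}

test_that("a separable problem is learned perfectly and deterministically", {
  feats <- separable_features()
  cfg <- grading_config(task = "three_class", feature_set = "fs2", seed = 5)
  model <- train_grader(feats, cfg)
  expect_equal(as.character(predict(model, feats)), feats$label)
  model2 <- train_grader(feats, cfg)
  expect_identical(as.character(predict(model2, feats)),
                   as.character(predict(model, feats)))
  # two-class task merges tumour grades into one cancer class
  cfg2 <- grading_config(task = "two_class")
  m2 <- train_grader(feats, cfg2)
  expect_setequal(m2$levels, c("normal", "cancer"))
  pred2 <- predict(m2, feats)
  expect_equal(as.character(pred2[feats$label != "normal"]),
               rep("cancer", 24))
  expect_error(train_grader(feats[feats$label == "normal", ], cfg),
               class = "glandbam_invalid_input")
  expect_error(train_grader(feats[, c("image_id", "mean_bam", "label")], cfg),
               class = "glandbam_schema")
})

test_that("cross-validation reports perfect metrics on separable classes", {
  feats <- separable_features()
  rep3 <- cross_validate(feats, grading_config(repeats = 3L, seed = 2))
  expect_equal(unname(rep3$accuracy["mean"]), 1)
  expect_equal(rep3$per_class$f1_mean, rep(1, 3))
  expect_equal(sum(rep3$confusion), nrow(feats) * 3L)  # images x repeats
  expect_true(all(diag(rep3$confusion) == rowSums(rep3$confusion)))
  for (k in names(rep3$roc)) expect_equal(rep3$roc[[k]]$auc, 1)
  expect_equal(rep3$binary_views$accuracy, c(1, 1))
})

test_that("permuted labels give chance-level accuracy", {
  feats <- separable_features(n_per_class = 20)
  set.seed(99)
  feats$label <- sample(feats$label)
  rep_p <- cross_validate(feats, grading_config(repeats = 2L, seed = 3))
  # exact binomial 95% interval around chance for 3 balanced classes
  n <- nrow(feats)
  lo <- qbinom(0.025, n, 1 / 3) / n
  hi <- qbinom(0.975, n, 1 / 3) / n
  expect_gte(rep_p$accuracy[["mean"]], lo - 2 * rep_p$accuracy[["sd"]] - 0.05)
  expect_lte(rep_p$accuracy[["mean"]], hi + 2 * rep_p$accuracy[["sd"]] + 0.05)
  # a class smaller than the fold count is rejected by name
  bad <- separable_features(n_per_class = 5)[-(1:3), ]  # 2 normals left
  expect_error(cross_validate(bad, grading_config(folds = 3L)),
               class = "glandbam_invalid_configuration")
})

test_that("binary views match hand-computed collapsed tables", {
  # constructed 3x3 confusion matrix (rows truth, cols prediction):
  #            normal low high
  #   normal     8     1    1
  #   low        2     6    2
  #   high       0     1    9
  truth <- rep(c("normal", "low_grade", "high_grade"), each = 10)
  pred <- c(rep("normal", 8), "low_grade", "high_grade",
            rep("normal", 2), rep("low_grade", 6), rep("high_grade", 2),
            rep("low_grade", 1), rep("high_grade", 9))
  v <- evaluate_binary_views(truth, pred)
  # cancer view: TP = 18, FN = 2, FP = 2, TN = 8
  cv <- v[v$view == "cancer", ]
  expect_equal(cv$accuracy, 26 / 30)
  expect_equal(cv$precision, 18 / 20)
  expect_equal(cv$recall, 18 / 20)
  expect_equal(cv$specificity, 8 / 10)
  expect_equal(cv$f1, 2 * 18 / (2 * 18 + 2 + 2))
  # high-grade view: TP = 9, FN = 1, FP = 3, TN = 17
  hv <- v[v$view == "high_grade", ]
  expect_equal(hv$accuracy, 26 / 30)
  expect_equal(hv$precision, 9 / 12)
  expect_equal(hv$recall, 9 / 10)
  expect_equal(hv$specificity, 17 / 20)
  # degenerate predictor: everything called normal
  v2 <- evaluate_binary_views(truth, rep("normal", 30))
  expect_equal(v2[v2$view == "cancer", "recall"], 0)
  expect_equal(v2[v2$view == "cancer", "specificity"], 1)
  # perfect predictions are perfect in both views
  v3 <- evaluate_binary_views(truth, truth)
  expect_equal(v3$accuracy, c(1, 1))
  expect_equal(v3$f1, c(1, 1))
})

test_that("ROC analysis sweeps thresholds correctly", {
  lab <- c(rep("pos", 5), rep("neg", 5))
  perfect <- roc_analysis(c(rep(1, 5), rep(0, 5)), lab, "pos")
  expect_equal(perfect$auc, 1)
  rev <- roc_analysis(-c(rep(1, 5), rep(0, 5)), lab, "pos")
  expect_equal(rev$auc, 0)
  set.seed(17)
  lab2 <- sample(c("pos", "neg"), 500, replace = TRUE)
  r <- roc_analysis(rnorm(500), lab2, "pos")
  expect_gt(r$auc, 0.4); expect_lt(r$auc, 0.6)
  # sign reversal maps AUC to 1 - AUC
  s <- rnorm(500)
  expect_equal(roc_analysis(-s, lab2, "pos")$auc,
               1 - roc_analysis(s, lab2, "pos")$auc, tolerance = 1e-12)
  expect_error(roc_analysis(rnorm(5), rep("pos", 5), "pos"),
               class = "glandbam_undefined_auc")
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  lab <- sample(c("a", "b"), 200, replace = TRUE)
  s <- rnorm(200) + (lab == "a")
  ours <- roc_analysis(s, lab, "a")$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = s,
                                           levels = c("b", "a"), quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("Kruskal-Wallis reproduces the hand-ranked example and detects shifts", {
  kw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(rep(1, 5), rep(1, 5))),
               class = "glandbam_degenerate_test")
  expect_error(kruskal_wallis(list(1:3)), class = "glandbam_invalid_input")
  set.seed(31)
  shifted <- list(rnorm(30), rnorm(30) + 5, rnorm(30) + 10)
  expect_lt(kruskal_wallis(shifted)$p_value, 0.001)
  # same-distribution groups rarely reach p < 0.001
  hits <- 0
  for (i in 1:400) {
    p <- kruskal_wallis(list(rnorm(40), rnorm(40)))$p_value
    if (p <= 0.001) hits <- hits + 1
  }
  expect_lte(hits / 400, 0.01)
})
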