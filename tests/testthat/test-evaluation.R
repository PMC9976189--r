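test_that("stratified k-fold split partitions with balanced classes", {
  labs <- rep(c(1L, -1L), each = 100)
  folds <- kfoldSplit(labs, k = 10, seed = 3)
  expect_length(folds, 10L)
  expect_identical(lengths(folds), rep(20L, 10))
  expect_identical(sort(unlist(folds)), 1:200)
  for (f in folds)
    expect_identical(sum(labs[f] == 1L), 10L)
  # unequal classes: fold sizes and class counts within one
  labs2 <- rep(c(1L, -1L), c(53, 47))
  folds2 <- kfoldSplit(labs2, k = 10, seed = 3)
  expect_identical(sort(unlist(folds2)), 1:100)
  expect_lte(diff(range(lengths(folds2))), 1L)
  pos <- vapply(folds2, function(f) sum(labs2[f] == 1L), integer(1))
  expect_lte(diff(range(pos)), 1L)
  # determinism
  expect_identical(folds, kfoldSplit(labs, k = 10, seed = 3))
  expect_error(kfoldSplit(rep(c(1L, -1L), c(5, 95)), k = 10, seed = 1),
               "fewer members")
  # non-stratified split still partitions
  folds3 <- kfoldSplit(labs2, k = 7, stratified = FALSE, seed = 5)
  expect_identical(sort(unlist(folds3)), 1:100)
  expect_lte(diff(range(lengths(folds3))), 1L)
})

test_that("AUC is the Mann-Whitney statistic of the scores", {
  # positives (0.9, 0.4), negatives (0.5, 0.1): 3 of 4 pairs concordant
  expect_equal(aucScore(c(0.9, 0.4, 0.5, 0.1), c(1, 1, -1, -1)), 0.75)
  expect_equal(aucScore(c(1, 1, 0, 0), c(1, 1, -1, -1)), 1)
  expect_equal(aucScore(rep(0.5, 10), rep(c(1, -1), 5)), 0.5)
  # tie handling: a tied pair counts one half
  expect_equal(aucScore(c(0.7, 0.7), c(1, -1)), 0.5)
  expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")
})

test_that("metrics follow the confusion-matrix formulas", {
  m <- computeMetrics(list(TP = 99, FN = 1, FP = 0, TN = 100))
  expect_equal(m$sensitivity, 0.99)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 199 / 200)
  expect_warning(m0 <- computeMetrics(list(TP = 0, FN = 0, FP = 2, TN = 8)),
                 "sensitivity undefined")
  expect_true(is.nan(m0$sensitivity))
  # accuracy identity on pooled counts
  set.seed(50)
  for (i in 1:10) {
    cm <- as.list(setNames(sample(0:40, 4, replace = TRUE) + 1L,
                           c("TP", "FN", "FP", "TN")))
    mm <- computeMetrics(cm)
    nPos <- cm$TP + cm$FN; nNeg <- cm$TN + cm$FP
    expect_equal(mm$accuracy,
                 (mm$sensitivity * nPos + mm$specificity * nNeg) /
                   (nPos + nNeg))
  }
})

makeBlobFeatures <- function(n = 30, sep = 10, seed = 51) {
  withr::with_seed(seed, {
    vals <- rbind(matrix(rnorm(3 * n), nrow = 3),
                  matrix(rnorm(3 * n), nrow = 3))
    vals[, seq_len(n / 2)] <- vals[, seq_len(n / 2)] + sep
    rownames(vals) <- paste0("f", 1:6)
    FeatureMatrix(vals, rep(c(1L, -1L), each = n / 2),
                  sprintf("r%03d", seq_len(n)))
  })
}

test_that("cross-validation is perfect on separable features", {
  fm <- makeBlobFeatures(n = 40, sep = 10)
  rep <- runCV(fm, pipelineConfig(folds = 10), seed = 4)
  expect_equal(meanAccuracy(rep), 1)
  expect_equal(sensitivity(rep), 1)
  expect_equal(specificity(rep), 1)
  expect_equal(auc(rep), 1)
  cm <- confusionMatrix(rep)
  expect_identical(sum(cm), 40L)
  expect_identical(cm[1, 2] + cm[2, 1], 0L)
})

test_that("cross-validation reports are seed-reproducible", {
  fm <- makeBlobFeatures(n = 30, sep = 2)
  r1 <- runCV(fm, pipelineConfig(folds = 5), seed = 8)
  r2 <- runCV(fm, pipelineConfig(folds = 5), seed = 8)
  expect_identical(foldAccuracy(r1), foldAccuracy(r2))
  expect_identical(confusionMatrix(r1), confusionMatrix(r2))
  expect_identical(auc(r1), auc(r2))
  # a different seed draws different folds
  labs <- classLabels(fm)
  expect_false(identical(kfoldSplit(labs, k = 5, seed = 8),
                         kfoldSplit(labs, k = 5, seed = 9)))
})

test_that("accuracy identity holds on the pooled CV confusion matrix", {
  fm <- makeBlobFeatures(n = 30, sep = 1.2)
  rep <- runCV(fm, pipelineConfig(folds = 5), seed = 12)
  cm <- confusionMatrix(rep)
  nPos <- sum(cm[1, ]); nNeg <- sum(cm[2, ])
  pooledAcc <- (cm[1, 1] + cm[2, 2]) / sum(cm)
  expect_equal(pooledAcc,
               (sensitivity(rep) * nPos + specificity(rep) * nNeg) /
                 sum(cm))
})
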