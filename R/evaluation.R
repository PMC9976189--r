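# Cross-validation driver and performance metrics.

#' Stratified k-fold split
#'
#' Partitions sample indices into k disjoint test folds whose sizes differ
#' by at most one.  With stratification (default), each class is shuffled
#' and dealt round-robin with a rotating offset, so per-fold class ratios
#' match the overall ratio to within one sample.  Deterministic given the
#' seed.
#'
#' @param labels per-sample class labels.
#' @param k number of folds (default 10).
#' @param stratified preserve class ratios per fold.
#' @param seed integer RNG seed for the shuffles.
#' @return list of k integer index vectors (the test sets).
#' @export
kfoldSplit <- function(labels, k = 10L, stratified = TRUE, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must be between 2 and the number of samples")
  folds <- vector("list", k)
  withSeed(seed, {
    if (stratified) {
      start <- 0L
      for (cls in sort(unique(labels), decreasing = TRUE)) {
        idx <- which(labels == cls)
        if (length(idx) < k)
          stop("class ", cls, " has fewer members (", length(idx),
               ") than folds (", k, "); use fewer folds or stratified = FALSE")
        idx <- idx[sample.int(length(idx))]
        f <- (start + seq_along(idx) - 1L) %% k + 1L
        for (j in seq_len(k))
          folds[[j]] <- c(folds[[j]], idx[f == j])
        start <- (start + length(idx)) %% k
      }
    } else {
      idx <- sample.int(n)
      f <- (seq_len(n) - 1L) %% k + 1L
      for (j in seq_len(k)) folds[[j]] <- sort(idx[f == j])
    }
  })
  lapply(folds, sort)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC = P(score_pos > score_neg) + 0.5 P(score_pos = score_neg), computed
#' from midranks; identical to the trapezoidal area under the ROC curve.
#'
#' @param scores numeric classifier scores (larger = more positive).
#' @param labels class labels, +1 positive, -1 negative; both present.
#' @return AUC in \code{[0, 1]}.
#' @export
aucScore <- function(scores, labels) {
  pos <- labels == 1
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

.confusion <- function(truth, predicted) {
  m <- matrix(c(sum(truth == 1 & predicted == 1),
                sum(truth == 1 & predicted == -1),
                sum(truth == -1 & predicted == 1),
                sum(truth == -1 & predicted == -1)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(truth = c("+1", "-1"),
                              predicted = c("+1", "-1")))
  storage.mode(m) <- "integer"
  m
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity = TP/(TP+FN) (proportion of ictal records detected),
#' specificity = TN/(TN+FP) (proportion of interictal records passed),
#' accuracy = (TP+TN)/n.  When scores are supplied the Mann-Whitney AUC
#' is included.  An empty truth class yields NaN for the affected rate,
#' with a warning.
#'
#' @param cm 2x2 confusion matrix as produced by [runCV()] (rows truth
#'   +1/-1, columns prediction +1/-1), or a named vector/list with
#'   elements TP, FN, FP, TN.
#' @param scores,labels optional pooled scores and true labels for AUC.
#' @return list with accuracy, sensitivity, specificity and (optionally)
#'   auc.
#' @export
computeMetrics <- function(cm, scores = NULL, labels = NULL) {
  if (is.matrix(cm)) {
    tp <- cm[1L, 1L]; fn <- cm[1L, 2L]; fp <- cm[2L, 1L]; tn <- cm[2L, 2L]
  } else {
    cm <- as.list(cm)
    tp <- cm$TP; fn <- cm$FN; fp <- cm$FP; tn <- cm$TN
  }
  n <- tp + fn + fp + tn
  if (n < 1L) stop("empty confusion matrix")
  sens <- if (tp + fn == 0L) {
    warning("no positive samples: sensitivity undefined"); NaN
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0L) {
    warning("no negative samples: specificity undefined"); NaN
  } else tn / (tn + fp)
  out <- list(accuracy = (tp + tn) / n, sensitivity = sens,
              specificity = spec)
  if (!is.null(scores)) out$auc <- aucScore(scores, labels)
  out
}

# Core CV loop over pre-drawn folds: per fold, train the ensemble on the
# remaining samples (standardization inside trainEnsemble uses training
# data only) and predict the held-out fold.
.cvOverFolds <- function(fm, mask, folds, config) {
  vals <- t(featureValues(fm))          # records x features
  labs <- as.numeric(classLabels(fm))
  n <- nrow(vals)
  predicted <- numeric(n)
  scores <- numeric(n)
  foldAcc <- numeric(length(folds))
  for (j in seq_along(folds)) {
    test <- folds[[j]]
    train <- setdiff(seq_len(n), test)
    model <- tryCatch(
      trainEnsemble(vals[train, , drop = FALSE], labs[train],
                    featureMask = mask, gamma = config$gamma,
                    k = config$k, scoreMode = config$scoreMode),
      error = function(e)
        stop("fold ", j, " failed to train: ", conditionMessage(e)))
    p <- predict(model, vals[test, , drop = FALSE])
    predicted[test] <- p
    scores[test] <- ensembleScore(model, vals[test, , drop = FALSE])
    foldAcc[j] <- mean(p == labs[test])
  }
  list(predicted = predicted, scores = scores, foldAccuracy = foldAcc,
       labels = labs)
}

#' Cross-validated evaluation of the voting ensemble
#'
#' Runs stratified k-fold cross-validation of the LS-SVM + KNN + GNB
#' majority-vote ensemble on a feature matrix: per fold, features are
#' z-scored with training-fold statistics, the three learners are trained
#' on the selected features and the held-out fold is predicted.  Per-fold
#' accuracies, the pooled confusion matrix, pooled sensitivity/specificity
#' and the AUC of the ensemble scores are aggregated into a
#' [MetricsReport-class].  Fully reproducible from the seed.
#'
#' @param fm a [FeatureMatrix-class].
#' @param config pipeline configuration ([pipelineConfig()]); supplies
#'   folds, stratification, gamma, k and scoreMode.
#' @param selected integer indices of the features to use (default: all).
#' @param seed integer seed for the fold split.
#' @return a [MetricsReport-class].
#' @export
runCV <- function(fm, config = pipelineConfig(), selected = NULL,
                  seed = 1L) {
  stopifnot(is(fm, "FeatureMatrix"))
  mask <- logical(nrow(fm))
  if (is.null(selected)) mask[] <- TRUE else mask[selected] <- TRUE
  folds <- kfoldSplit(classLabels(fm), k = config$folds,
                      stratified = config$stratified, seed = seed)
  res <- .cvOverFolds(fm, mask, folds, config)
  cm <- .confusion(res$labels, res$predicted)
  met <- computeMetrics(cm, scores = res$scores, labels = res$labels)
  snapshot <- config
  snapshot$selectedFeatures <- which(mask)
  new("MetricsReport", foldAccuracy = res$foldAccuracy, confusion = cm,
      sensitivity = met$sensitivity, specificity = met$specificity,
      auc = met$auc, seed = as.integer(seed), config = snapshot)
}
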