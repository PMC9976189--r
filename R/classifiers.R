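# Base learners and the majority-vote ensemble.
#
# All three are intentionally small, dense, deterministic implementations:
# the LS-SVM reduces training to one linear solve, KNN is brute-force
# Euclidean search, GNB is closed-form Gaussian likelihoods.  Tie policy
# everywhere: sign(0) and exact ties map to +1 (ictal).

.asMatrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

.checkLabels <- function(y) {
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (length(unique(y)) != 2L) stop("both classes must be present")
  as.numeric(y)
}

#' Train a least-squares SVM with linear kernel
#'
#' The LS-SVM replaces the SVM's inequality constraints with equalities,
#' so training reduces to the KKT linear system
#' \deqn{\begin{pmatrix} 0 & y^\top \\ y & \Omega + I/\gamma \end{pmatrix}
#'       \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ 1 \end{pmatrix}}
#' with \eqn{\Omega_{ij} = y_i y_j \langle x_i, x_j\rangle}.  The decision
#' value is \eqn{f(x) = \sum_i \alpha_i y_i \langle x_i, x\rangle + b} and
#' the prediction is its sign, with sign(0) mapped to +1.
#'
#' @param X numeric n x p feature matrix.
#' @param y labels in \{-1, +1\}, both classes present.
#' @param gamma regularization weight (> 0); larger gamma fits the
#'   training data more tightly.  Default 10.
#' @return an [LSSVMModel-class].
#' @export
trainLSSVM <- function(X, y, gamma = 10) {
  X <- .asMatrix(X)
  y <- .checkLabels(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (nrow(X) < 2L) stop("need at least two training samples")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  n <- nrow(X)
  Omega <- tcrossprod(y) * tcrossprod(X)
  M <- rbind(c(0, y), cbind(y, Omega + diag(n) / gamma))
  sol <- tryCatch(solve(M, c(0, rep(1, n))), error = function(e)
    stop("LS-SVM system is singular (", conditionMessage(e),
         "); try a different gamma"))
  new("LSSVMModel", alpha = unname(sol[-1L]), bias = unname(sol[1L]),
      gamma = gamma, X = X, y = y)
}

#' @describeIn LSSVMModel-class decision values f(x) for new rows
#' @param object,newdata model and n x p matrix of query points.
#' @export
setMethod("decisionValues", "LSSVMModel", function(object, newdata) {
  newdata <- .asMatrix(newdata)
  if (ncol(newdata) != ncol(object@X))
    stop("feature dimensionality mismatch")
  unname(drop(newdata %*% crossprod(object@X, object@alpha * object@y))) +
    object@bias
})

#' @describeIn LSSVMModel-class predicted labels (sign of the decision
#'   value; sign(0) is +1)
#' @export
setMethod("predict", "LSSVMModel", function(object, newdata) {
  f <- decisionValues(object, newdata)
  ifelse(f >= 0, 1, -1)
})

#' Train (store) a k-nearest-neighbours classifier
#'
#' KNN has no fitting step; the model retains the training set.  k must be
#' odd so binary majority votes cannot tie; the default k = 3 with
#' Euclidean distances.
#'
#' @param X numeric n x p feature matrix.
#' @param y labels in \{-1, +1\}.
#' @param k odd neighbourhood size.
#' @return a [KNNModel-class].
#' @export
trainKNN <- function(X, y, k = 3L) {
  X <- .asMatrix(X)
  y <- .checkLabels(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  new("KNNModel", k = as.integer(k), X = X, y = y)
}

# Fractions of +1 votes among the k nearest training points, one per query
# row.  Distance ties break towards the lower training index.
.knnVoteFraction <- function(model, newdata) {
  newdata <- .asMatrix(newdata)
  if (ncol(newdata) != ncol(model@X))
    stop("feature dimensionality mismatch")
  trainSq <- rowSums(model@X^2)
  vapply(seq_len(nrow(newdata)), function(i) {
    q <- newdata[i, ]
    d2 <- trainSq - 2 * drop(model@X %*% q) + sum(q^2)
    nb <- order(d2, seq_along(d2))[seq_len(model@k)]
    mean(model@y[nb] == 1)
  }, numeric(1))
}

#' @describeIn KNNModel-class predicted labels by majority vote of the k
#'   nearest neighbours
#' @param object,newdata model and n x p matrix of query points.
#' @export
setMethod("predict", "KNNModel", function(object, newdata) {
  frac <- .knnVoteFraction(object, newdata)
  ifelse(frac >= 0.5, 1, -1)  # k odd => frac != 0.5, no tie path
})

#' Train a Gaussian naive Bayes classifier
#'
#' Per class: empirical prior, per-feature mean and variance (divisor
#' n - 1, floored at \code{varFloorCoeff} times the largest overall
#' feature variance so constant features never produce degenerate
#' densities).  Prediction maximises log prior + sum of per-feature log
#' Gaussian densities; exact ties break towards +1.
#'
#' @param X numeric n x p feature matrix.
#' @param y labels in \{-1, +1\}, each class with >= 2 members.
#' @param varFloorCoeff relative variance floor (default 1e-9).
#' @return a [GNBModel-class].
#' @export
trainGNB <- function(X, y, varFloorCoeff = 1e-9) {
  X <- .asMatrix(X)
  y <- .checkLabels(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  classes <- c(1, -1)
  if (any(vapply(classes, function(cl) sum(y == cl), numeric(1)) < 2L))
    stop("each class needs at least 2 training samples")
  means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  vars <- do.call(rbind, lapply(classes, function(cl)
    apply(X[y == cl, , drop = FALSE], 2L, stats::var)))
  overall <- apply(X, 2L, stats::var)
  floorv <- max(varFloorCoeff * max(overall, 0), .Machine$double.xmin)
  vars <- pmax(vars, floorv)
  new("GNBModel", classes = classes,
      priors = vapply(classes, function(cl) mean(y == cl), numeric(1)),
      means = means, variances = vars, varFloor = floorv)
}

# Per-class joint log likelihood + log prior, queries in rows.
.gnbLogPosterior <- function(model, newdata) {
  newdata <- .asMatrix(newdata)
  if (ncol(newdata) != ncol(model@means))
    stop("feature dimensionality mismatch")
  out <- matrix(0, nrow(newdata), length(model@classes))
  for (ci in seq_along(model@classes)) {
    mu <- model@means[ci, ]
    v <- model@variances[ci, ]
    ll <- -0.5 * sweep(sweep(newdata, 2L, mu)^2, 2L, v, "/") -
      0.5 * matrix(log(2 * pi * v), nrow(newdata), ncol(newdata),
                   byrow = TRUE)
    out[, ci] <- log(model@priors[ci]) + rowSums(ll)
  }
  colnames(out) <- as.character(model@classes)
  out
}

#' @describeIn GNBModel-class predicted labels (maximum posterior; ties to
#'   +1)
#' @param object,newdata model and n x p matrix of query points.
#' @export
setMethod("predict", "GNBModel", function(object, newdata) {
  lp <- .gnbLogPosterior(object, newdata)
  # classes are ordered (+1, -1); >= implements the tie-to-+1 rule
  unname(ifelse(lp[, 1L] >= lp[, 2L], 1, -1))
})

#' Train the LS-SVM + KNN + GNB voting ensemble
#'
#' Applies the selected-feature mask, z-scores each kept feature with the
#' training-set mean and SD (constant features get scale 1), and trains
#' the three base learners on identical transformed data.
#'
#' @param X numeric n x p feature matrix over the FULL feature set.
#' @param y labels in \{-1, +1\}.
#' @param featureMask logical length-p mask of the features to use
#'   (default: all).
#' @param gamma LS-SVM regularization weight.
#' @param k KNN neighbourhood size (odd).
#' @param scoreMode \code{"votes"} (default: score = fraction of base
#'   learners voting +1, values in \{0, 1/3, 2/3, 1\}) or
#'   \code{"calibrated"} (mean of a logistic squash of the LS-SVM decision
#'   value, the KNN +1-neighbour fraction and the GNB posterior).
#' @return an [EnsembleModel-class].
#' @export
trainEnsemble <- function(X, y, featureMask = NULL, gamma = 10, k = 3L,
                          scoreMode = c("votes", "calibrated")) {
  scoreMode <- match.arg(scoreMode)
  X <- .asMatrix(X)
  if (is.null(featureMask)) featureMask <- rep(TRUE, ncol(X))
  if (length(featureMask) != ncol(X))
    stop("featureMask length must equal the number of features")
  if (!any(featureMask)) stop("featureMask selects no features")
  Xm <- X[, featureMask, drop = FALSE]
  center <- colMeans(Xm)
  scale <- apply(Xm, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(Xm, 2L, center), 2L, scale, "/")
  new("EnsembleModel",
      lssvm = trainLSSVM(Xs, y, gamma = gamma),
      knn = trainKNN(Xs, y, k = k),
      gnb = trainGNB(Xs, y),
      featureMask = as.logical(featureMask),
      center = center, scale = scale, scoreMode = scoreMode)
}

.ensembleTransform <- function(model, newdata) {
  newdata <- .asMatrix(newdata)
  if (ncol(newdata) != length(model@featureMask))
    stop("feature dimensionality mismatch: got ", ncol(newdata),
         ", expected ", length(model@featureMask))
  Xm <- newdata[, model@featureMask, drop = FALSE]
  sweep(sweep(Xm, 2L, model@center), 2L, model@scale, "/")
}

.ensembleVotes <- function(model, newdata) {
  Xs <- .ensembleTransform(model, newdata)
  cbind(lssvm = predict(model@lssvm, Xs),
        knn = predict(model@knn, Xs),
        gnb = predict(model@gnb, Xs))
}

#' @describeIn EnsembleModel-class majority-vote label over the three base
#'   learners (three voters, binary labels: never tied)
#' @param object,newdata model and n x p matrix over the full feature set.
#' @export
setMethod("predict", "EnsembleModel", function(object, newdata) {
  votes <- .ensembleVotes(object, newdata)
  ifelse(rowSums(votes) >= 0, 1, -1)
})

#' Continuous score of the voting ensemble
#'
#' With \code{scoreMode = "votes"} (default) the score is the fraction of
#' base learners voting +1 -- the hard-vote analogue of a class
#' probability, used for the ROC/AUC.  With \code{"calibrated"} it is the
#' mean of plogis(LS-SVM decision value), the KNN +1-neighbour fraction
#' and the GNB posterior probability of +1.
#'
#' @param model an [EnsembleModel-class].
#' @param newdata n x p matrix over the full feature set.
#' @return numeric scores in \code{[0, 1]}, one per row.
#' @export
ensembleScore <- function(model, newdata) {
  stopifnot(is(model, "EnsembleModel"))
  if (model@scoreMode == "votes") {
    votes <- .ensembleVotes(model, newdata)
    return(rowMeans(votes == 1))
  }
  Xs <- .ensembleTransform(model, newdata)
  lp <- .gnbLogPosterior(model@gnb, Xs)
  post <- 1 / (1 + exp(lp[, 2L] - lp[, 1L]))
  (stats::plogis(decisionValues(model@lssvm, Xs)) +
     .knnVoteFraction(model@knn, Xs) + post) / 3
}
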