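test_that("LS-SVM solves the symmetric and separable cases", {
  # two mirrored 1-D points: zero bias, predictions sign(x)
  X <- matrix(c(-1, 1), ncol = 1)
  for (gamma in c(1, 10, 100)) {
    m <- m <- trainLSSVM(X, c(-1, 1), gamma = gamma)
    expect_equal(m@bias, 0, tolerance = 1e-12)
    expect_identical(predict(m, matrix(c(-3, -0.2, 0.4, 2))),
                     c(-1, -1, 1, 1))
  }
  # clearly separated 2-D blobs: perfect training accuracy
  set.seed(40)
  Xb <- rbind(matrix(rnorm(20, 0), ncol = 2),
              matrix(rnorm(20, 10), ncol = 2))
  yb <- rep(c(-1, 1), each = 10)
  expect_identical(predict(trainLSSVM(Xb, yb, gamma = 10), Xb), yb)
  expect_error(trainLSSVM(Xb, yb, gamma = -1), "gamma")
  expect_error(trainLSSVM(Xb, rep(1, 20), gamma = 1), "both classes")
})

test_that("LS-SVM decision values match the dense KKT oracle", {
  set.seed(41)
  for (i in 1:10) {
    n <- 6; p <- 2
    X <- matrix(rnorm(n * p), n, p)
    y <- c(rep(1, 3), rep(-1, 3))
    q <- matrix(rnorm(10 * p), 10, p)
    for (gamma in c(1, 10, 100)) {
      m <- trainLSSVM(X, y, gamma = gamma)
      expect_equal(decisionValues(m, q), oracleLSSVMDecision(X, y, gamma, q),
                   tolerance = 1e-9)
    }
  }
})

test_that("LS-SVM is invariant to training-sample permutation", {
  set.seed(42)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(1, -1), 10)
  q <- matrix(rnorm(12), 6, 2)
  f0 <- decisionValues(trainLSSVM(X, y), q)
  for (i in 1:5) {
    perm <- sample(20)
    expect_equal(decisionValues(trainLSSVM(X[perm, ], y[perm]), q), f0,
                 tolerance = 1e-9)
  }
})

test_that("KNN votes its three nearest neighbours deterministically", {
  X <- matrix(c(0, 1, 4, 5), ncol = 1)
  y <- c(-1, -1, 1, 1)
  m <- trainKNN(X, y)
  # query 1.5: neighbours at 1, 0, 4 -> majority -1
  expect_identical(predict(m, matrix(1.5)), -1)
  # query on a training point whose two nearest peers share its label
  expect_identical(predict(m, matrix(5)), 1)
  expect_error(trainKNN(X, y, k = 4), "odd")

  set.seed(43)
  Xt <- matrix(rnorm(60), 30, 2)
  yt <- rep(c(1, -1), 15)
  mt <- trainKNN(Xt, yt)
  for (i in 1:100) {
    q <- rnorm(2)
    expect_identical(predict(mt, matrix(q, 1)), oracleKNN(Xt, yt, q))
  }
})

test_that("GNB picks the closer mean and matches the density oracle", {
  X <- matrix(c(rnorm(5, -1, 0.1), rnorm(5, 1, 0.1)), ncol = 1)
  X <- matrix(c(-1.1, -1, -0.9, 1.1, 1, 0.9), ncol = 1)
  y <- rep(c(-1, 1), each = 3)
  m <- trainGNB(X, y)
  expect_identical(predict(m, matrix(0.9)), 1)
  expect_identical(predict(m, matrix(-0.9)), -1)
  # exact midpoint with symmetric classes: tie resolves to +1
  expect_identical(predict(m, matrix(0)), 1)

  set.seed(44)
  X8 <- matrix(c(0.2, 1.1, -0.3, 0.8, 2.1, 3.0, 2.4, 2.9,
                 1.0, 0.5, 1.3, 0.7, -1.2, -0.8, -1.5, -0.9), ncol = 2)
  y8 <- rep(c(-1, 1), each = 4)
  m8 <- trainGNB(X8, y8)
  for (i in 1:20) {
    q <- rnorm(2)
    lp <- episeizer:::.gnbLogPosterior(m8, matrix(q, 1))
    expect_equal(unname(lp[1, 1] - lp[1, 2]), oracleGNBLogOdds(X8, y8, q),
                 tolerance = 1e-12)
  }
  # constant feature: variance floor, no exception
  Xc <- cbind(X8[, 1], 5)
  expect_silent(pc <- predict(trainGNB(Xc, y8), matrix(c(0, 5), 1)))
  expect_true(pc %in% c(-1, 1))
})

test_that("the ensemble is the majority of its three base learners", {
  set.seed(45)
  X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 1.2), ncol = 2))
  y <- rep(c(-1, 1), each = 20)
  em <- trainEnsemble(X, y, gamma = 10, k = 3)
  q <- rbind(matrix(rnorm(30, 0.6), ncol = 2), X[c(1, 40), ])
  votes <- cbind(
    predict(em@lssvm, episeizer:::.ensembleTransform(em, q)),
    predict(em@knn, episeizer:::.ensembleTransform(em, q)),
    predict(em@gnb, episeizer:::.ensembleTransform(em, q)))
  pred <- predict(em, q)
  score <- ensembleScore(em, q)
  for (i in seq_len(nrow(q))) {
    # prediction always agrees with at least two voters
    expect_gte(sum(votes[i, ] == pred[i]), 2)
    expect_identical(score[i], mean(votes[i, ] == 1))
  }
  expect_true(all(score %in% c(0, 1/3, 2/3, 1)))
  # hard prediction is +1 exactly when at least two of three vote +1
  expect_identical(pred, ifelse(score >= 2/3, 1, -1))
  expect_error(predict(em, q[, 1, drop = FALSE]), "mismatch")
})

test_that("calibrated scores stay in [0,1] and rank like the votes", {
  set.seed(46)
  X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 3), ncol = 2))
  y <- rep(c(-1, 1), each = 20)
  em <- trainEnsemble(X, y, scoreMode = "calibrated")
  s <- ensembleScore(em, X)
  expect_true(all(s >= 0 & s <= 1))
  # clearly negative samples score below clearly positive ones
  expect_lt(max(s[1:20]), min(s[21:40]))
})

test_that("masking restricts the ensemble to the selected features", {
  set.seed(47)
  X <- cbind(c(rnorm(10, -2), rnorm(10, 2)), rnorm(20) * 100)
  y <- rep(c(-1, 1), each = 10)
  em <- trainEnsemble(X, y, featureMask = c(TRUE, FALSE))
  # feature 2 is pure noise; flipping it must not change predictions
  X2 <- X; X2[, 2] <- rev(X2[, 2])
  expect_identical(predict(em, X), predict(em, X2))
  expect_error(trainEnsemble(X, y, featureMask = c(FALSE, FALSE)),
               "no features")
})
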