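# A small labelled dataset reused across blocks (2048 samples keeps the
# d5 sub-band long enough for well-defined SampEn on irregular records).
featSet <- generateDataset(synthConfig(nPerClass = 4, nSamples = 2048,
                                       seed = 314))
featMat <- extractFeatures(featSet)

test_that("extraction yields the six named features per record", {
  expect_identical(rownames(featMat),
                   c("d3_apen", "d4_apen", "d5_apen",
                     "d3_sampen", "d4_sampen", "d5_sampen"))
  expect_identical(dim(featureValues(featMat)), c(6L, 8L))
  expect_identical(classLabels(featMat), rep(c(1L, -1L), each = 4L))
  expect_false(anyNA(featureValues(featMat)))

  # identical records give identical columns
  rec <- records(featSet)[[1]]
  twin <- EEGDataset(list(rec, rec))
  fm2 <- extractFeatures(twin)
  expect_identical(featureValues(fm2)[, 1], featureValues(fm2)[, 2])
})

test_that("features can be computed on reconstructed sub-band signals", {
  small <- EEGDataset(records(featSet)[c(1, 2, 5, 6)])
  fmRec <- extractFeatures(small, representation = "reconstructed")
  expect_identical(dim(featureValues(fmRec)), c(6L, 4L))
  # the decimated-coefficient and reconstructed representations are
  # different statistics of the same band
  fmCoef <- extractFeatures(small)
  expect_false(isTRUE(all.equal(featureValues(fmRec), featureValues(fmCoef))))
})

test_that("records that cannot be processed are excluded with a warning", {
  good <- records(featSet)[[1]]
  bad <- EEGRecord(rnorm(16), label = -1L, recordId = "short")  # < 2^5
  expect_warning(fm <- extractFeatures(EEGDataset(list(good, bad))),
                 "excluded")
  expect_identical(ncol(fm), 1L)
  expect_error(
    suppressWarnings(extractFeatures(EEGDataset(list(bad)))),
    "every record")
})

test_that("ANOVA F follows the textbook formula and the t-squared identity", {
  expect_identical(anovaF(c(1, 2, 3, 1, 2, 3), rep(c(1, -1), each = 3)), 0)
  expect_equal(anovaF(c(1, 2, 3, 6, 7, 8), rep(c(1, -1), each = 3)), 37.5)
  set.seed(30)
  for (i in 1:25) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    v <- c(rnorm(n1, 0), rnorm(n2, 0.8))
    lab <- rep(c(1, -1), c(n1, n2))
    f <- anovaF(v, lab)
    tt <- t.test(v[lab == 1], v[lab == -1], var.equal = TRUE)
    expect_equal(f, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(f, oracleAnovaF(v, lab), tolerance = 1e-12)
  }
  expect_error(anovaF(1:4, c(1, 1, 1, 1)), "two classes")
  expect_error(anovaF(1:3, c(1, 1, -1)), "at least 2")
  expect_warning(fInf <- anovaF(c(1, 1, 2, 2), c(1, 1, -1, -1)),
                 "infinite")
  expect_identical(fInf, Inf)
})

test_that("ranking orders by decreasing F with index tie-breaks", {
  set.seed(31)
  n <- 100
  labs <- rep(c(1L, -1L), each = n)
  shift <- c(3, 2, 1, 0, 0, 0)
  vals <- t(vapply(shift, function(s)
    c(rnorm(n, s), rnorm(n, 0)), numeric(2 * n)))
  rownames(vals) <- paste0("f", 1:6)
  fm <- FeatureMatrix(vals, labs, sprintf("r%03d", seq_len(2 * n)))
  rk <- rankFeatures(fm)
  # planted effect sizes 3 > 2 > 1 SDs recovered in order
  expect_identical(rk@order[1:3], 1:3)
  expect_true(all(rk@fStatistics >= 0))

  # duplicated feature rows tie exactly; lower index first
  vals2 <- vals[c(2, 2, 1, 4, 5, 6), ]
  rownames(vals2) <- paste0("g", 1:6)
  fm2 <- FeatureMatrix(vals2, labs, sprintf("r%03d", seq_len(2 * n)))
  rk2 <- rankFeatures(fm2)
  pos <- match(c(1L, 2L), rk2@order)
  expect_identical(pos[2], pos[1] + 1L)
})

test_that("forward selection stops at the first strict error increase", {
  vals <- matrix(rnorm(6 * 20), nrow = 6,
                 dimnames = list(paste0("f", 1:6), NULL))
  fm <- FeatureMatrix(vals, rep(c(1L, -1L), 10), sprintf("r%02d", 1:20))
  rk <- new("FeatureRanking",
            fStatistics = setNames(as.numeric(6:1), paste0("f", 1:6)),
            order = 1:6)
  scripted <- function(trace) {
    i <- 0L
    function(idx) { i <<- i + 1L; trace[i] }
  }
  # ties continue, strict increase rolls back
  s1 <- fsfs(fm, rk, evaluator = scripted(c(0.05, 0.02, 0.02, 0.04)))
  expect_identical(s1@selected, 1:3)
  expect_identical(s1@stoppedAt, 4L)
  expect_identical(s1@errorTrace, c(0.05, 0.02, 0.02, 0.04))
  # monotone decrease selects everything
  s2 <- fsfs(fm, rk, evaluator = scripted(seq(0.6, 0.1, by = -0.1)))
  expect_identical(s2@selected, 1:6)
  expect_true(is.na(s2@stoppedAt))
  # immediate increase keeps the single top-ranked feature
  s3 <- fsfs(fm, rk, evaluator = scripted(c(0.1, 0.2)))
  expect_identical(s3@selected, 1L)
  # selected is always a prefix of the ranking order
  for (s in list(s1, s2, s3))
    expect_identical(s@selected, rk@order[seq_along(s@selected)])
  expect_error(fsfs(fm, rk, evaluator = function(idx) 1.7), "\\[0, 1\\]")
})

test_that("the default ensemble evaluator is seed-reproducible", {
  cfg <- pipelineConfig(folds = 4)   # 4 records per class in the fixture
  s1 <- fsfs(featMat, seed = 99L, config = cfg)
  s2 <- fsfs(featMat, seed = 99L, config = cfg)
  expect_identical(s1@selected, s2@selected)
  expect_identical(s1@errorTrace, s2@errorTrace)
})

test_that("feature CSV round trip preserves the matrix", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "features.csv")
  writeFeaturesCSV(featMat, p)
  header <- strsplit(readLines(p, n = 1), ",")[[1]]
  expect_identical(header, c("record_id", "label", rownames(featMat)))
  back <- readFeaturesCSV(p)
  expect_equal(featureValues(back), featureValues(featMat),
               tolerance = 1e-12)
  expect_identical(classLabels(back), classLabels(featMat))
})
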