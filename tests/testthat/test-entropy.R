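test_that("delay embedding builds the documented templates", {
  expect_equal(embedSeries(c(1, 2, 3, 4), m = 2, t = 1),
               matrix(c(1, 2, 3, 2, 3, 4), ncol = 2))
  expect_equal(embedSeries(c(1, 2, 3, 4, 5), m = 2, t = 2),
               matrix(c(1, 2, 3, 3, 4, 5), ncol = 2))
  # template count N - (m-1)t
  expect_equal(nrow(embedSeries(rnorm(4096), m = 2, t = 1)), 4095)
  expect_error(embedSeries(1:3, m = 5, t = 2), "too short")
})

test_that("Chebyshev distance matches a per-coordinate loop oracle", {
  expect_identical(chebyshevDistance(c(5, 5), c(5, 5)), 0)
  expect_identical(chebyshevDistance(c(1, 4), c(2, 1)), 3)
  expect_error(chebyshevDistance(1:2, 1:3), "mismatch")
  set.seed(11)
  for (i in 1:20) {
    u <- rnorm(5); v <- rnorm(5)
    d <- 0
    for (k in 1:5) d <- max(d, abs(u[k] - v[k]))
    expect_identical(chebyshevDistance(u, v), d)
  }
})

test_that("ApEn analytic limits and frozen oracle value", {
  # constant sequence: every distance 0, phi_m = phi_{m+1} = 0
  expect_identical(apEn(rep(7, 100), r = 0.5), 0)
  # exactly periodic: near zero, and equal to the literal oracle
  per <- rep(c(1, 2, 3), 20)
  rp <- entropyTolerance(per)
  expect_lt(abs(apEn(per, r = rp)), 1e-4)
  expect_equal(apEn(per, r = rp), oracleApEn(per, 2L, 1L, rp),
               tolerance = 1e-12)
  # fixed digit sequence, frozen from the double-loop oracle
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3)
  rx <- entropyTolerance(x)
  expect_equal(rx, 0.53851648071345037, tolerance = 1e-15)
  expect_equal(apEn(x, r = rx), -0.068992871486951213, tolerance = 1e-12)
  expect_error(apEn(rnorm(100), r = -1), "positive")
  expect_error(apEn(rnorm(3), r = 1), "too short")
})

test_that("SampEn analytic limits and degenerate-count handling", {
  # exact periodicity: every m-match extends, A = B, SampEn = 0
  per <- rep(c(1, 2, 3), 10)
  expect_identical(sampEn(per, r = entropyTolerance(per)), 0)
  expect_identical(sampEn(rep(4.2, 50), r = 1), 0)
  # the 16-digit sequence has no matching template pairs at r = 0.2 SD:
  # B = 0 is the documented undefined-entropy error carrying the counts
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3)
  err <- tryCatch(sampEn(x, r = entropyTolerance(x)), condition = identity)
  expect_s3_class(err, "episeizer_undefined_entropy")
  expect_identical(err$B, 0)
  # A = 0 with B > 0 returns the +Inf sentinel, not an error
  y <- c(0, 0, 1, 0, 0, 2)
  expect_identical(sampEn(y, r = 0.5), Inf)
  expect_error(sampEn(rnorm(100), r = 0), "positive")
})

test_that("production entropies equal the literal double-loop oracles", {
  set.seed(202)
  for (i in 1:10) {
    n <- sample(60:150, 1)
    x <- rnorm(n) + 0.5 * sin(seq_len(n) / 3)
    r <- entropyTolerance(x)
    expect_equal(apEn(x, r = r), oracleApEn(x, 2L, 1L, r),
                 tolerance = 1e-12)
    expect_equal(sampEn(x, r = r), oracleSampEn(x, 2L, r),
                 tolerance = 1e-12)
    # a non-default parameterization too
    r3 <- entropyTolerance(x, rCoeff = 0.35)
    expect_equal(apEn(x, m = 3, t = 2, r = r3),
                 oracleApEn(x, 3L, 2L, r3), tolerance = 1e-12)
  }
})

test_that("entropy tolerance is rCoeff times the population SD", {
  expect_identical(entropyTolerance(c(0, 0, 2, 2)), 0.2)
  expect_error(entropyTolerance(rep(3, 10)),
               class = "episeizer_tolerance_zero")
  set.seed(3)
  x <- rnorm(50)
  expect_equal(entropyTolerance(x), 0.2 * sqrt(mean((x - mean(x))^2)),
               tolerance = 1e-15)
  expect_equal(entropyTolerance(x, sdType = "sample"), 0.2 * sd(x),
               tolerance = 1e-15)
})

test_that("entropy statistics are non-negative and deterministic", {
  set.seed(77)
  for (i in 1:15) {
    x <- rnorm(sample(80:200, 1))
    r <- entropyTolerance(x)
    expect_gte(sampEn(x, r = r), 0)
    expect_gte(apEn(x, r = r), 0)
    expect_identical(apEn(x, r = r), apEn(x, r = r))
    expect_identical(sampEn(x, r = r), sampEn(x, r = r))
  }
})

test_that("noisy sinusoids are more regular than white noise", {
  set.seed(42)
  n <- 300
  se <- function(x) sampEn(x, r = entropyTolerance(x))
  sine <- replicate(20, {
    s <- sin(2 * pi * 5 * (0:(n - 1)) / 173.61) + rnorm(n, sd = 0.1)
    se(s / popSdLocal(s))
  })
  noise <- replicate(20, { w <- rnorm(n); se(w / popSdLocal(w)) })
  expect_lt(mean(sine), mean(noise))
})
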