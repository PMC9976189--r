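# Independent brute-force oracles.  Each re-derives the quantity from its
# definition with naive loops and its own hard-coded constants, sharing no
# code path with the package implementation.

# ApEn by the literal definition: per-template correlation sums with the
# self-comparison included, theta(r - d) = 1 iff r - d > 0, natural logs.
oracleApEn <- function(x, m, t, r) {
  phi <- function(mm) {
    n <- length(x) - (mm - 1L) * t
    C <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n)) {
        d <- 0
        for (k in seq_len(mm))
          d <- max(d, abs(x[i + (k - 1L) * t] - x[j + (k - 1L) * t]))
        if (r - d > 0) cnt <- cnt + 1L
      }
      C[i] <- cnt / n
    }
    mean(log(C))
  }
  phi(m) - phi(m + 1L)
}

# SampEn by unordered-pair counting over the common N - m template start
# positions, self-matches excluded, strict d < r.
oracleSampEn <- function(x, m, r) {
  nT <- length(x) - m
  countPairs <- function(mm) {
    cnt <- 0L
    for (i in seq_len(nT - 1L)) for (j in (i + 1L):nT) {
      d <- 0
      for (k in seq_len(mm)) d <- max(d, abs(x[i + k - 1L] - x[j + k - 1L]))
      if (d < r) cnt <- cnt + 1L
    }
    cnt
  }
  B <- countPairs(m)
  A <- countPairs(m + 1L)
  -log(A / B)
}

# One analysis level of the db4 filter bank as explicit per-coefficient
# loops: half-sample symmetric extension, correlate, keep every second
# output.  Taps hard-coded independently of the package source.
.oracleDb4 <- c(0.230377813308855230, 0.714846570552541500,
                0.630880767929590400, -0.027983769416983850,
                -0.187034811718881140, 0.030841381835986965,
                0.032883011666982945, -0.010597401784997278)

oracleDwtStep <- function(x) {
  h <- .oracleDb4
  g <- numeric(8)
  for (k in 0:7) g[k + 1] <- (-1)^k * h[8 - k]
  n <- length(x)
  ext <- c(rev(x[1:7]), x, rev(x[(n - 6):n]))
  L <- (n + 7) %/% 2
  a <- numeric(L); d <- numeric(L)
  for (jj in seq_len(L)) for (k in 1:8) {
    a[jj] <- a[jj] + h[k] * ext[2 * jj + k - 1]
    d[jj] <- d[jj] + g[k] * ext[2 * jj + k - 1]
  }
  list(a = a, d = d)
}

# Full five-level naive decomposition.
oracleDwt5 <- function(x) {
  out <- list()
  approx <- x
  for (lev in 1:5) {
    st <- oracleDwtStep(approx)
    out[[paste0("d", lev)]] <- st$d
    approx <- st$a
  }
  out$a5 <- approx
  out
}

# LS-SVM via the bordered system with the PLAIN linear kernel:
# [[0, 1^T], [1, K + I/gamma]] (b, beta) = (0, y), f(x) = sum beta_i <x_i, x> + b.
# Equivalent to the package's class-weighted parameterization; decision
# values must agree.
oracleLSSVMDecision <- function(X, y, gamma, newdata) {
  n <- nrow(X)
  K <- X %*% t(X)
  M <- matrix(0, n + 1, n + 1)
  M[1, 2:(n + 1)] <- 1
  M[2:(n + 1), 1] <- 1
  M[2:(n + 1), 2:(n + 1)] <- K + diag(n) / gamma
  sol <- qr.solve(M, c(0, y))
  b <- sol[1]; beta <- sol[-1]
  as.numeric(newdata %*% t(X) %*% beta + b)
}

# Nearest-neighbour label by exhaustive distance enumeration.
oracleKNN <- function(X, y, q, k = 3L) {
  d <- sqrt(rowSums(sweep(X, 2, q)^2))
  ord <- order(d, seq_along(d))[seq_len(k)]
  votes <- y[ord]
  if (sum(votes == 1) > sum(votes == -1)) 1 else -1
}

# GNB posterior log odds log P(+1|x) - log P(-1|x) from explicit density
# products (no variance floor; callers use non-degenerate data).
oracleGNBLogOdds <- function(X, y, q) {
  lp <- function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    v <- apply(Xc, 2, var)
    log(mean(y == cl)) + sum(dnorm(q, mu, sqrt(v), log = TRUE))
  }
  lp(1) - lp(-1)
}

# One-way two-group ANOVA F from the textbook mean-square formulas.
oracleAnovaF <- function(values, labels) {
  g <- unique(labels)
  n1 <- sum(labels == g[1]); n2 <- sum(labels == g[2])
  m1 <- mean(values[labels == g[1]]); m2 <- mean(values[labels == g[2]])
  gm <- mean(values)
  msb <- (n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2) / 1
  msw <- (sum((values[labels == g[1]] - m1)^2) +
            sum((values[labels == g[2]] - m2)^2)) / (n1 + n2 - 2)
  msb / msw
}

# Population SD by definition, for tests that need it directly.
popSdLocal <- function(x) sqrt(mean((x - mean(x))^2))
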