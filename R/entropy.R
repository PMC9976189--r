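# Approximate entropy (ApEn) and sample entropy (SampEn).
#
# Both compare delay-embedded templates under the Chebyshev (maximum)
# metric with a strict matching inequality d < r.  ApEn keeps the
# self-comparison j = i (its per-template counts then never vanish and
# every log is defined); SampEn excludes self-matches and counts unordered
# template pairs, so SampEn >= 0 always.  Natural logarithms throughout.

#' Entropy parameter set
#'
#' Bundles the embedding dimension m, tolerance coefficient and time delay
#' used by [apEn()] and [sampEn()].  Defaults m = 2, rCoeff = 0.2, t = 1
#' are the standard choice for EEG regularity analysis; the matching
#' tolerance is r = rCoeff * SD of the analysed sequence (see
#' [entropyTolerance()]).
#'
#' @param m embedding (template) dimension, integer >= 1.
#' @param rCoeff tolerance coefficient (> 0) multiplying the SD.
#' @param t time delay between embedded coordinates, integer >= 1.
#' @return a named list of validated parameters.
#' @export
entropyParams <- function(m = 2L, rCoeff = 0.2, t = 1L) {
  m <- as.integer(m); t <- as.integer(t)
  if (m < 1L) stop("m must be >= 1")
  if (t < 1L) stop("t must be >= 1")
  if (!is.numeric(rCoeff) || rCoeff <= 0) stop("rCoeff must be > 0")
  list(m = m, rCoeff = rCoeff, t = t)
}

#' Delay embedding of a sequence
#'
#' Builds the N - (m-1)t templates x_m(i) = (x_i, x_{i+t}, ...,
#' x_{i+(m-1)t}); row i of the result starts at x[i].
#'
#' @param x numeric sequence.
#' @param m template dimension.
#' @param t time delay.
#' @return numeric matrix with N - (m-1)t rows and m columns.
#' @examples
#' embedSeries(1:4, m = 2, t = 1)  # rows (1,2), (2,3), (3,4)
#' @export
embedSeries <- function(x, m, t = 1L) {
  m <- as.integer(m); t <- as.integer(t)
  n <- length(x) - (m - 1L) * t
  if (n < 1L)
    stop("sequence too short to embed: need at least ", (m - 1L) * t + 1L,
         " samples, got ", length(x))
  out <- matrix(0, nrow = n, ncol = m)
  for (k in seq_len(m)) out[, k] <- x[seq_len(n) + (k - 1L) * t]
  out
}

#' Chebyshev (maximum-coordinate) distance
#'
#' @param u,v numeric vectors of equal length.
#' @return \code{max(abs(u - v))}.
#' @export
chebyshevDistance <- function(u, v) {
  if (length(u) != length(v))
    stop("dimension mismatch: ", length(u), " vs ", length(v))
  max(abs(u - v))
}

# Per-row counts of templates within strict Chebyshev distance r,
# including the self-comparison.  Full pairwise matrix; fine for the
# sub-band lengths this package works with (<= a few thousand).
.chebMatchCounts <- function(E, r) {
  n <- nrow(E)
  within <- matrix(TRUE, n, n)
  for (k in seq_len(ncol(E)))
    within <- within & (abs(outer(E[, k], E[, k], "-")) < r)
  rowSums(within)
}

#' Approximate entropy
#'
#' ApEn(m, r, t) = phi_m(r) - phi_{m+1}(r), where phi_m(r) is the mean log
#' fraction of templates lying within Chebyshev distance r of each
#' template (self-comparison included, so the fractions are positive and
#' the logarithm is always defined).  Matching uses the strict inequality
#' d < r.  Low values indicate a regular, repetitive signal; higher values
#' an irregular one.
#'
#' @param x numeric sequence, length >= m*t + 2.
#' @param m embedding dimension (default 2).
#' @param t time delay (default 1).
#' @param r matching tolerance (> 0), typically
#'   \code{entropyTolerance(x, 0.2)}.
#' @return the ApEn value (non-negative in practice for self-match
#'   counting).
#' @seealso [sampEn()], [entropyTolerance()]
#' @export
apEn <- function(x, m = 2L, t = 1L, r) {
  m <- as.integer(m); t <- as.integer(t)
  if (missing(r) || !is.numeric(r) || length(r) != 1L || r <= 0)
    stop("tolerance r must be a single positive number")
  if (length(x) < m * t + 2L)
    stop("sequence too short for ApEn: need at least ", m * t + 2L,
         " samples, got ", length(x))
  phi <- function(mm) {
    E <- embedSeries(x, mm, t)
    mean(log(.chebMatchCounts(E, r) / nrow(E)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy
#'
#' SampEn(m, r) = -log(A / B), where B counts unordered template pairs
#' (i < j, self-matches excluded) of length m within Chebyshev distance r,
#' and A counts pairs of length m + 1; both are counted over the same
#' N - m template start positions, so A <= B and SampEn >= 0.
#'
#' When no m-pairs match (B = 0) the statistic is undefined and an error
#' of class \code{"episeizer_undefined_entropy"} is signalled carrying the
#' counts; when B > 0 but no (m+1)-pair matches, \code{Inf} is returned as
#' a documented sentinel rather than an error.
#'
#' @param x numeric sequence, length >= m + 2.
#' @param m embedding dimension (default 2); time delay is fixed at 1.
#' @param r matching tolerance (> 0).
#' @return the SampEn value (>= 0, possibly \code{Inf}).
#' @seealso [apEn()], [entropyTolerance()]
#' @export
sampEn <- function(x, m = 2L, r) {
  m <- as.integer(m)
  if (missing(r) || !is.numeric(r) || length(r) != 1L || r <= 0)
    stop("tolerance r must be a single positive number")
  n <- length(x)
  if (n < m + 2L)
    stop("sequence too short for SampEn: need at least ", m + 2L,
         " samples, got ", n)
  nT <- n - m
  Em <- embedSeries(x, m, 1L)[seq_len(nT), , drop = FALSE]
  Em1 <- embedSeries(x, m + 1L, 1L)
  # ordered matches include the diagonal; unordered pair count excludes it
  B <- (sum(.chebMatchCounts(Em, r)) - nT) / 2
  A <- (sum(.chebMatchCounts(Em1, r)) - nT) / 2
  if (B == 0) {
    cond <- structure(
      class = c("episeizer_undefined_entropy", "error", "condition"),
      list(message = sprintf(
             "SampEn undefined: no template pairs of length m = %d match (A = %g, B = 0)",
             m, A),
           call = sys.call(-1), A = A, B = B))
    stop(cond)
  }
  if (A == 0) return(Inf)
  -log(A / B)
}

#' Matching tolerance from the signal's spread
#'
#' r = rCoeff * SD(x), by default the population SD (divisor N) of the
#' sequence the entropy is computed on.  A constant sequence has SD 0 and
#' an undefined tolerance; an error of class
#' \code{"episeizer_tolerance_zero"} is signalled so the caller can apply
#' the constant-sequence convention (entropy 0) instead.
#'
#' @param x numeric sequence, length >= 2.
#' @param rCoeff tolerance coefficient (default 0.2).
#' @param sdType \code{"population"} (divisor N, default) or
#'   \code{"sample"} (divisor N-1).
#' @return the tolerance r > 0.
#' @export
entropyTolerance <- function(x, rCoeff = 0.2,
                             sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  if (length(x) < 2L) stop("need at least two samples")
  if (!is.numeric(rCoeff) || rCoeff <= 0) stop("rCoeff must be > 0")
  s <- popSd(x, sdType)
  if (s == 0) {
    cond <- structure(
      class = c("episeizer_tolerance_zero", "error", "condition"),
      list(message = "tolerance is zero: sequence is constant (SD = 0)",
           call = sys.call(-1)))
    stop(cond)
  }
  rCoeff * s
}
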