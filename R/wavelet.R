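# Five-level DB4 discrete wavelet decomposition.
#
# Implemented as the classical pyramidal two-channel filter bank: at each
# level the signal is correlated with the orthonormal scaling (low-pass)
# and wavelet (high-pass) filters and decimated by two; the low-pass
# output feeds the next level.  Two boundary policies are supported:
# half-sample symmetric extension (default; output length
# floor((L + 7) / 2) per level for the 8-tap filter) and periodization
# (circular; length L / 2, exactly orthogonal so energy is preserved).

# Daubechies-4 (4 vanishing moments, 8 taps) orthonormal scaling filter.
.db4Lo <- c(
   0.230377813308855230,
   0.714846570552541500,
   0.630880767929590400,
  -0.027983769416983850,
  -0.187034811718881140,
   0.030841381835986965,
   0.032883011666982945,
  -0.010597401784997278
)
# Quadrature mirror: g[k] = (-1)^k h[F-1-k] (0-based).
.db4Hi <- rev(.db4Lo) * rep(c(1, -1), 4L)

.waveletFilters <- function(waveletName) {
  if (!identical(waveletName, "db4"))
    stop("unknown wavelet '", waveletName, "'; only 'db4' is supported")
  list(lo = .db4Lo, hi = .db4Hi)
}

.dwtOutLength <- function(n, flen, mode) {
  if (mode == "periodization") as.integer(ceiling(n / 2))
  else as.integer(floor((n + flen - 1) / 2))
}

# Chain of detail lengths over `levels` decimations.
.subbandLengths <- function(n, levels, mode) {
  out <- integer(levels)
  len <- n
  for (k in seq_len(levels)) {
    len <- .dwtOutLength(len, 8L, mode)
    out[k] <- len
  }
  out
}

# One analysis step: returns list(a, d).
.dwtStep <- function(x, lo, hi, mode) {
  n <- length(x)
  flen <- length(lo)
  if (mode == "periodization") {
    if (n %% 2L != 0L)
      stop("periodization mode requires an even length at every level (got ", n, ")")
    L <- n %/% 2L
    a <- numeric(L); d <- numeric(L)
    base <- 2L * (seq_len(L) - 1L)
    for (k in seq_len(flen)) {
      idx <- (base + k - 1L) %% n + 1L
      a <- a + lo[k] * x[idx]
      d <- d + hi[k] * x[idx]
    }
  } else {
    p <- flen - 1L
    if (n < p)
      stop("signal too short (", n, ") for symmetric extension; need >= ", p)
    xe <- c(rev(x[seq_len(p)]), x, rev(x[(n - p + 1L):n]))
    L <- .dwtOutLength(n, flen, mode)
    a <- numeric(L); d <- numeric(L)
    base <- 2L * seq_len(L)
    for (k in seq_len(flen)) {
      idx <- base + k - 1L
      a <- a + lo[k] * xe[idx]
      d <- d + hi[k] * xe[idx]
    }
  }
  list(a = a, d = d)
}

# One synthesis step, the adjoint of .dwtStep; exact inverse in both modes.
.idwtStep <- function(a, d, lo, hi, mode, n) {
  flen <- length(lo)
  L <- length(a)
  x <- numeric(n)
  if (mode == "periodization") {
    base <- 2L * (seq_len(L) - 1L)
    for (k in seq_len(flen)) {
      idx <- (base + k - 1L) %% n + 1L
      x[idx] <- x[idx] + lo[k] * a + hi[k] * d
    }
  } else {
    base <- 2L * seq_len(L)
    for (k in seq_len(flen)) {
      idx <- base + k - 8L
      keep <- idx >= 1L & idx <= n
      x[idx[keep]] <- x[idx[keep]] + lo[k] * a[keep] + hi[k] * d[keep]
    }
  }
  x
}

#' Discrete wavelet decomposition of an EEG record
#'
#' Decomposes a signal into detail sub-bands d1 (highest frequency) through
#' d\code{levels} and the final approximation a\code{levels} using the
#' orthonormal Daubechies-4 filter pair and the pyramidal algorithm.  With
#' the defaults (db4, 5 levels) this yields the six sub-bands a5, d1..d5;
#' at the Bonn sampling rate of 173.61 Hz the d3/d4/d5 details cover
#' roughly 3--25 Hz, the band where ictal rhythms concentrate.
#'
#' @param x an [EEGRecord-class] or a numeric vector.
#' @param waveletName wavelet identifier; only \code{"db4"} is available.
#' @param levels number of decomposition levels (default 5).
#' @param mode boundary policy: \code{"symmetric"} (half-sample signal
#'   extension, the usual EEG-denoising convention; per-level length
#'   \code{floor((L+7)/2)}) or \code{"periodization"} (circular, exactly
#'   energy-preserving, requires even lengths).
#' @return a [SubbandSet-class].
#'
#' @examples
#' rec <- EEGRecord(sin(2 * pi * 5 * (0:4095) / 173.61), label = 1)
#' sb <- dwtDecompose(rec)
#' subbandNames(sb)
#' @export
dwtDecompose <- function(x, waveletName = "db4", levels = 5L,
                         mode = c("symmetric", "periodization")) {
  mode <- match.arg(mode)
  sig <- if (is(x, "EEGRecord")) x@samples else as.numeric(x)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (length(sig) < 2^levels)
    stop("signal too short for ", levels, " levels: need at least ",
         2^levels, " samples, got ", length(sig))
  filt <- .waveletFilters(waveletName)
  coefs <- vector("list", levels + 1L)
  names(coefs) <- c(paste0("d", seq_len(levels)), paste0("a", levels))
  approx <- sig
  for (lev in seq_len(levels)) {
    st <- .dwtStep(approx, filt$lo, filt$hi, mode)
    coefs[[paste0("d", lev)]] <- st$d
    approx <- st$a
  }
  coefs[[paste0("a", levels)]] <- approx
  new("SubbandSet", coefficients = coefs, waveletName = waveletName,
      levels = levels, sourceLength = length(sig), paddingMode = mode)
}

#' @describeIn SubbandSet-class invert the decomposition back to the
#'   original signal (exact up to floating-point rounding)
#' @export
setMethod("reconstructSignal", "SubbandSet", function(x) {
  filt <- .waveletFilters(x@waveletName)
  lens <- c(x@sourceLength,
            .subbandLengths(x@sourceLength, x@levels, x@paddingMode))
  sig <- x@coefficients[[paste0("a", x@levels)]]
  for (lev in rev(seq_len(x@levels)))
    sig <- .idwtStep(sig, x@coefficients[[paste0("d", lev)]],
                     filt$lo, filt$hi, x@paddingMode, lens[lev])
  sig
})

#' @describeIn SubbandSet-class reconstruct the full-length time-domain
#'   signal carried by a single sub-band (all other coefficients zeroed)
#' @export
setMethod("reconstructSubband", "SubbandSet", function(x, name) {
  if (!name %in% names(x@coefficients))
    stop("unknown sub-band '", name, "'")
  z <- x
  for (nm in names(z@coefficients))
    if (nm != name) z@coefficients[[nm]] <- numeric(length(z@coefficients[[nm]]))
  reconstructSignal(z)
})

#' Select the seizure-band details d3, d4, d5
#'
#' Ictal EEG rhythms lie mostly within 3--25 Hz; at 173.61 Hz sampling the
#' level-3/4/5 details cover that range while d1/d2 (broadband noise) and
#' a5 (slow drift) fall outside it.  Discarding them is the pipeline's
#' denoising step -- no coefficient shrinkage is applied.
#'
#' @param subbands a [SubbandSet-class] from a 5-level decomposition.
#' @return named list with elements \code{d3}, \code{d4}, \code{d5}, in
#'   that order.
#' @export
selectFeatureSubbands <- function(subbands) {
  stopifnot(is(subbands, "SubbandSet"))
  if (subbands@levels != 5L)
    stop("feature sub-band selection requires a 5-level decomposition, got ",
         subbands@levels, " levels")
  list(d3 = subbands@coefficients[["d3"]],
       d4 = subbands@coefficients[["d4"]],
       d5 = subbands@coefficients[["d5"]])
}
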