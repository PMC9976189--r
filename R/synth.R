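# Synthetic ictal / interictal EEG generator.
#
# The generator emulates the two regimes the pipeline must separate, not
# seizure physiology: ictal-like records are high-amplitude rhythmic
# oscillations (a harmonic stack of a fundamental inside the 3-25 Hz
# seizure band, random phases, light noise) whose d3/d4/d5 sub-bands are
# regular and hence low-entropy; interictal-like records are irregular
# broadband activity (white noise through a first-order low-pass
# recursion, approximating the 1/f character of background EEG, plus a
# weak 10 Hz alpha component) with high sub-band entropy.

#' Configuration of the synthetic EEG generator
#'
#' Defaults mirror the Bonn-style recording setup the pipeline targets:
#' single-channel records of 4096 samples at 173.61 Hz (about 23.6 s),
#' two balanced classes.
#'
#' @param nPerClass records per class (default 50).
#' @param nSamples samples per record (default 4096; must be >= 32 so a
#'   5-level decomposition is possible).
#' @param samplingRate Hz (default 173.61).
#' @param seed integer RNG seed.
#' @param ictalFreq fundamental of the ictal rhythm in Hz; must lie in the
#'   3--25 Hz seizure band (default 5).
#' @param ictalAmplitude scale of the ictal oscillation relative to unit
#'   noise (default 3).
#' @param harmonicWeights relative weights of harmonics 1..H of
#'   \code{ictalFreq} (default \code{c(1, 0.4, 0.2)}).
#' @param noiseSdIctal white-noise SD added to ictal records (default 0.3).
#' @param noiseSdInterictal SD of the white noise driving interictal
#'   records (default 1).
#' @param interictalAlphaWeight amplitude of the weak 10 Hz component in
#'   interictal records (default 0.3).
#' @return validated configuration list.
#' @export
synthConfig <- function(nPerClass = 50L, nSamples = 4096L,
                        samplingRate = 173.61, seed = 42L,
                        ictalFreq = 5, ictalAmplitude = 3,
                        harmonicWeights = c(1, 0.4, 0.2),
                        noiseSdIctal = 0.3, noiseSdInterictal = 1,
                        interictalAlphaWeight = 0.3) {
  cfg <- list(nPerClass = as.integer(nPerClass),
              nSamples = as.integer(nSamples),
              samplingRate = samplingRate, seed = as.integer(seed),
              ictalFreq = ictalFreq, ictalAmplitude = ictalAmplitude,
              harmonicWeights = harmonicWeights,
              noiseSdIctal = noiseSdIctal,
              noiseSdInterictal = noiseSdInterictal,
              interictalAlphaWeight = interictalAlphaWeight)
  if (cfg$nPerClass < 1L) stop("nPerClass must be >= 1")
  if (cfg$nSamples < 32L) stop("nSamples must be >= 32 (2^5)")
  if (cfg$samplingRate <= 0) stop("samplingRate must be > 0")
  if (cfg$ictalFreq < 3 || cfg$ictalFreq > 25)
    stop("ictalFreq must lie in the 3-25 Hz seizure band")
  if (cfg$noiseSdIctal < 0 || cfg$noiseSdInterictal < 0)
    stop("noise SDs must be >= 0")
  cfg
}

#' Generate one ictal-like record
#'
#' Sum of the first harmonics of \code{ictalFreq} with per-record random
#' phases, scaled by \code{ictalAmplitude}, plus white noise of SD
#' \code{noiseSdIctal}.  Label +1.  Uses the current RNG stream; seed at
#' the dataset level via [generateDataset()].
#'
#' @param config a [synthConfig()] list.
#' @param recordId identifier for the record.
#' @return an [EEGRecord-class] labelled +1.
#' @export
generateIctal <- function(config = synthConfig(), recordId = "ictal_001") {
  tt <- (seq_len(config$nSamples) - 1L) / config$samplingRate
  w <- config$harmonicWeights
  phases <- runif(length(w), 0, 2 * pi)
  sig <- numeric(config$nSamples)
  for (h in seq_along(w))
    sig <- sig + w[h] * sin(2 * pi * h * config$ictalFreq * tt + phases[h])
  sig <- config$ictalAmplitude * sig +
    rnorm(config$nSamples, sd = config$noiseSdIctal)
  EEGRecord(sig, samplingRate = config$samplingRate, label = 1L,
            recordId = recordId)
}

#' Generate one interictal-like record
#'
#' White noise of SD \code{noiseSdInterictal} smoothed by the first-order
#' recursion y[n] = 0.9 y[n-1] + e[n] (lag-1 autocorrelation about 0.9,
#' approximating background EEG's 1/f rolloff), plus a weak 10 Hz alpha
#' component of amplitude \code{interictalAlphaWeight} with a random
#' phase.  Label -1.
#'
#' @param config a [synthConfig()] list.
#' @param recordId identifier for the record.
#' @return an [EEGRecord-class] labelled -1.
#' @export
generateInterictal <- function(config = synthConfig(),
                               recordId = "interictal_001") {
  e <- rnorm(config$nSamples, sd = config$noiseSdInterictal)
  sig <- as.numeric(stats::filter(e, 0.9, method = "recursive"))
  tt <- (seq_len(config$nSamples) - 1L) / config$samplingRate
  sig <- sig + config$interictalAlphaWeight *
    sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))
  EEGRecord(sig, samplingRate = config$samplingRate, label = -1L,
            recordId = recordId)
}

#' Generate a labelled synthetic dataset
#'
#' \code{nPerClass} ictal then \code{nPerClass} interictal records,
#' bit-reproducible from \code{config$seed}; record ids encode class and
#' index (\code{ictal_001}, ...).
#'
#' @param config a [synthConfig()] list.
#' @return an [EEGDataset-class].
#' @examples
#' ds <- generateDataset(synthConfig(nPerClass = 3, nSamples = 512))
#' classCounts(ds)
#' @export
generateDataset <- function(config = synthConfig()) {
  withSeed(config$seed, {
    ict <- lapply(seq_len(config$nPerClass), function(i)
      generateIctal(config, sprintf("ictal_%03d", i)))
    int <- lapply(seq_len(config$nPerClass), function(i)
      generateInterictal(config, sprintf("interictal_%03d", i)))
    EEGDataset(c(ict, int))
  })
}
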