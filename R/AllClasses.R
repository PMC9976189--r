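# Class definitions.  Label convention throughout: +1 = ictal (seizure,
# Bonn set S), -1 = interictal (Bonn set F), NA = unknown -- matching the
# y_i in {-1, +1} convention of the LS-SVM.

.LABEL_ICTAL <- 1L
.LABEL_INTERICTAL <- -1L

#' EEGRecord: one labelled single-channel EEG signal
#'
#' Holds the amplitude samples of a single-channel EEG record together with
#' its sampling rate, class label (+1 ictal, -1 interictal, NA unknown) and
#' an identifier.
#'
#' @slot samples numeric vector of amplitudes (arbitrary units), finite,
#'   non-empty.
#' @slot samplingRate sampling rate in Hz (> 0); Bonn records use 173.61.
#' @slot label integer, one of \code{1L}, \code{-1L}, \code{NA_integer_}.
#' @slot recordId character scalar identifier.
#'
#' @seealso [EEGRecord()] constructor, [readBonnAscii()]
#' @export
setClass("EEGRecord",
  representation(
    samples = "numeric",
    samplingRate = "numeric",
    label = "integer",
    recordId = "character"
  )
)

setValidity("EEGRecord", function(object) {
  msg <- character()
  if (length(object@samples) == 0L)
    msg <- c(msg, "samples must be non-empty")
  if (length(object@samples) > 0L && !all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite (no NA/NaN/Inf)")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@label) != 1L ||
      !(is.na(object@label) || object@label %in% c(-1L, 1L)))
    msg <- c(msg, "label must be +1 (ictal), -1 (interictal) or NA")
  if (length(object@recordId) != 1L || is.na(object@recordId))
    msg <- c(msg, "recordId must be a single string")
  if (length(msg)) msg else TRUE
})

#' @param samples,samplingRate,label,recordId see slots.
#' @rdname EEGRecord-class
#' @export
EEGRecord <- function(samples, samplingRate = 173.61, label = NA,
                      recordId = "record") {
  lab <- if (is.na(label)) NA_integer_ else as.integer(label)
  new("EEGRecord", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate),
      label = lab, recordId = as.character(recordId))
}

#' EEGDataset: an ordered collection of EEGRecord objects
#'
#' All records share one sampling rate.  Record order is deterministic and
#' meaningful (ictal before interictal when built by [loadDataset()] or
#' [generateDataset()]).
#'
#' @slot records list of [EEGRecord-class] objects.
#'
#' @seealso [loadDataset()], [generateDataset()]
#' @export
setClass("EEGDataset", representation(records = "list"))

setValidity("EEGDataset", function(object) {
  msg <- character()
  if (!all(vapply(object@records, is, logical(1), "EEGRecord")))
    msg <- c(msg, "all records must be EEGRecord objects")
  else if (length(object@records) > 1L) {
    fs <- vapply(object@records, function(r) r@samplingRate, numeric(1))
    if (length(unique(fs)) != 1L)
      msg <- c(msg, "all records must share one sampling rate")
  }
  if (length(msg)) msg else TRUE
})

#' @param records list of EEGRecord objects.
#' @rdname EEGDataset-class
#' @export
EEGDataset <- function(records) new("EEGDataset", records = records)

#' SubbandSet: DWT sub-band coefficients of one record
#'
#' The result of an L-level discrete wavelet decomposition: detail
#' coefficient sequences d1 (highest frequency) through dL and the final
#' approximation aL -- six sequences for the default five levels.
#'
#' @slot coefficients named list of numeric vectors
#'   (\code{d1..dL}, \code{aL}).
#' @slot waveletName character, currently \code{"db4"}.
#' @slot levels integer number of decomposition levels.
#' @slot sourceLength integer, length of the decomposed signal.
#' @slot paddingMode \code{"symmetric"} or \code{"periodization"}.
#'
#' @seealso [dwtDecompose()], [selectFeatureSubbands()]
#' @export
setClass("SubbandSet",
  representation(
    coefficients = "list",
    waveletName = "character",
    levels = "integer",
    sourceLength = "integer",
    paddingMode = "character"
  )
)

setValidity("SubbandSet", function(object) {
  msg <- character()
  L <- object@levels
  wanted <- c(paste0("d", seq_len(L)), paste0("a", L))
  if (!identical(names(object@coefficients), wanted))
    msg <- c(msg, sprintf("coefficients must be named %s",
                          paste(wanted, collapse = ", ")))
  else {
    exp_len <- .subbandLengths(object@sourceLength, L, object@paddingMode)
    got <- lengths(object@coefficients)
    want <- c(exp_len, exp_len[L])
    names(want) <- wanted
    if (!identical(unname(got), unname(want)))
      msg <- c(msg, "coefficient lengths do not follow the decimation recursion")
  }
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: entropy features per record
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"entropy"}:
#' rows are the six features (\code{d3_apen}, \code{d4_apen},
#' \code{d5_apen}, \code{d3_sampen}, \code{d4_sampen}, \code{d5_sampen}),
#' columns are records.  \code{colData} carries \code{label} (+1/-1) and
#' \code{record_id}.
#'
#' @seealso [extractFeatures()], [featureValues()], [classLabels()]
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!identical(assayNames(object), "entropy"))
    msg <- c(msg, "FeatureMatrix must have exactly one assay named 'entropy'")
  else {
    v <- assay(object, "entropy")
    if (anyNA(v)) msg <- c(msg, "entropy assay must not contain NA")
    if (is.null(rownames(object))) msg <- c(msg, "features must be named")
  }
  cd <- colData(object)
  if (!all(c("label", "record_id") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'label' and 'record_id'")
  else if (!all(cd$label %in% c(-1L, 1L)))
    msg <- c(msg, "labels must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' @param values numeric matrix, features x records.
#' @param labels integer vector of +1/-1 class labels, one per column.
#' @param recordIds character vector of identifiers, one per column.
#' @rdname FeatureMatrix-class
#' @export
FeatureMatrix <- function(values, labels, recordIds) {
  se <- SummarizedExperiment(
    assays = list(entropy = as.matrix(values)),
    colData = DataFrame(label = as.integer(labels),
                        record_id = as.character(recordIds))
  )
  new("FeatureMatrix", se)
}

#' FeatureRanking: ANOVA-F importance ordering
#'
#' @slot fStatistics named numeric vector of per-feature one-way ANOVA F
#'   statistics (>= 0, possibly Inf when within-class variance is zero).
#' @slot order integer permutation of feature indices, decreasing F,
#'   ties broken by lower index.
#'
#' @seealso [rankFeatures()]
#' @export
setClass("FeatureRanking",
  representation(fStatistics = "numeric", order = "integer"))

setValidity("FeatureRanking", function(object) {
  p <- length(object@fStatistics)
  if (!identical(sort(object@order), seq_len(p)))
    return("order must be a permutation of the feature indices")
  if (any(object@fStatistics < 0, na.rm = TRUE))
    return("F statistics must be non-negative")
  TRUE
})

#' SelectionResult: forward sequential feature selection outcome
#'
#' @slot selected integer indices of the selected features (a prefix of the
#'   ranking order).
#' @slot errorTrace numeric CV error after each candidate addition that was
#'   evaluated.
#' @slot stoppedAt integer index (into errorTrace) of the addition that
#'   triggered termination, or \code{NA} if no addition increased the error.
#'
#' @seealso [fsfs()]
#' @export
setClass("SelectionResult",
  representation(selected = "integer", errorTrace = "numeric",
                 stoppedAt = "integer"))

# --- classifier models -------------------------------------------------

#' LSSVMModel: trained least-squares SVM (linear kernel)
#'
#' Training solves the LS-SVM KKT linear system; prediction is
#' sign(sum_i alpha_i y_i <x_i, x> + b) with sign(0) mapped to +1.
#'
#' @slot alpha numeric per-training-sample coefficients.
#' @slot bias numeric intercept b.
#' @slot gamma numeric regularization weight (> 0).
#' @slot X training feature matrix (n x p) kept for the kernel expansion.
#' @slot y numeric training labels in {-1, +1}.
#'
#' @seealso [trainLSSVM()]
#' @export
setClass("LSSVMModel",
  representation(alpha = "numeric", bias = "numeric", gamma = "numeric",
                 X = "matrix", y = "numeric"))

#' KNNModel: k-nearest-neighbours classifier state
#'
#' @slot k odd integer neighbourhood size (default 3, so binary votes
#'   cannot tie).
#' @slot X training feature matrix (n x p); distances are Euclidean.
#' @slot y numeric training labels in {-1, +1}.
#'
#' @seealso [trainKNN()]
#' @export
setClass("KNNModel",
  representation(k = "integer", X = "matrix", y = "numeric"))

setValidity("KNNModel", function(object) {
  if (object@k %% 2L == 0L) return("k must be odd")
  if (nrow(object@X) < object@k) return("need at least k training points")
  TRUE
})

#' GNBModel: Gaussian naive Bayes parameters
#'
#' @slot classes numeric class values (+1, -1).
#' @slot priors numeric class prior probabilities.
#' @slot means numeric matrix (class x feature) of per-class means.
#' @slot variances numeric matrix (class x feature) of per-class variances,
#'   floored at \code{varFloor}.
#' @slot varFloor numeric variance floor (> 0).
#'
#' @seealso [trainGNB()]
#' @export
setClass("GNBModel",
  representation(classes = "numeric", priors = "numeric", means = "matrix",
                 variances = "matrix", varFloor = "numeric"))

#' EnsembleModel: LS-SVM + KNN + GNB majority-vote ensemble
#'
#' All three base learners are trained on the same masked, z-scored
#' features; the mask and the training-fold standardization parameters are
#' stored so new samples are transformed identically.
#'
#' @slot lssvm,knn,gnb the trained base learners.
#' @slot featureMask logical vector over the full feature set.
#' @slot center,scale numeric per-kept-feature training means and SDs.
#' @slot scoreMode \code{"votes"} (fraction of +1 votes) or
#'   \code{"calibrated"} (mean of squashed base scores).
#'
#' @seealso [trainEnsemble()], [ensembleScore()]
#' @export
setClass("EnsembleModel",
  representation(lssvm = "LSSVMModel", knn = "KNNModel", gnb = "GNBModel",
                 featureMask = "logical", center = "numeric",
                 scale = "numeric", scoreMode = "character"))

#' MetricsReport: cross-validation evaluation summary
#'
#' @slot foldAccuracy numeric per-fold accuracies.
#' @slot confusion 2x2 integer matrix, rows = truth (+1, -1), columns =
#'   prediction (+1, -1), pooled over folds.
#' @slot sensitivity,specificity,auc numeric pooled rates; sensitivity =
#'   TP/(TP+FN), specificity = TN/(TN+FP), AUC is the Mann-Whitney
#'   statistic of the ensemble scores.
#' @slot seed integer seed the run used.
#' @slot config list snapshot of the pipeline configuration.
#'
#' @seealso [runCV()], [computeMetrics()]
#' @export
setClass("MetricsReport",
  representation(foldAccuracy = "numeric", confusion = "matrix",
                 sensitivity = "numeric", specificity = "numeric",
                 auc = "numeric", seed = "integer", config = "list"))

setValidity("MetricsReport", function(object) {
  ok <- function(x) length(x) == 1L && (is.nan(x) || (x >= 0 && x <= 1))
  if (!all(dim(object@confusion) == c(2L, 2L)))
    return("confusion must be 2x2")
  if (!ok(object@sensitivity) || !ok(object@specificity) || !ok(object@auc))
    return("rates must lie in [0, 1]")
  TRUE
})
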