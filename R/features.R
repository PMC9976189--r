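# Feature extraction, ANOVA-F ranking and forward sequential selection.

.FEATURE_NAMES <- c("d3_apen", "d4_apen", "d5_apen",
                    "d3_sampen", "d4_sampen", "d5_sampen")

# Six entropy features of one record.  Constant sub-bands (zero SD, so an
# undefined tolerance) map to entropy 0: a constant sequence is perfectly
# regular.  Returns NULL with a warning if SampEn is undefined/infinite.
.recordFeatures <- function(rec, params, waveletName, levels, mode,
                            representation, toleranceSource, sdType) {
  sb <- dwtDecompose(rec, waveletName = waveletName, levels = levels,
                     mode = mode)
  bands <- selectFeatureSubbands(sb)
  if (representation == "reconstructed")
    bands <- lapply(names(bands), function(nm) reconstructSubband(sb, nm)) |>
      stats::setNames(names(bands))
  ap <- sp <- numeric(3L)
  for (i in seq_along(bands)) {
    band <- bands[[i]]
    src <- if (toleranceSource == "signal") rec@samples else band
    r <- tryCatch(entropyTolerance(src, params$rCoeff, sdType),
                  episeizer_tolerance_zero = function(e) 0)
    if (r == 0) {
      if (popSd(band) == 0) { ap[i] <- 0; sp[i] <- 0; next }
      stop("tolerance is zero (constant raw signal) but sub-band varies")
    }
    ap[i] <- apEn(band, m = params$m, t = params$t, r = r)
    sp[i] <- sampEn(band, m = params$m, r = r)
  }
  if (any(!is.finite(sp)) || any(!is.finite(ap))) {
    warning("record '", rec@recordId,
            "': undefined or infinite entropy; record excluded")
    return(NULL)
  }
  c(ap, sp)
}

#' Extract the six sub-band entropy features of every record
#'
#' For each record: 5-level db4 decomposition, selection of the d3/d4/d5
#' details, and ApEn plus SampEn per sub-band with tolerance
#' r = rCoeff * SD of the analysed sequence.  Feature order is fixed:
#' d3_apen, d4_apen, d5_apen, d3_sampen, d4_sampen, d5_sampen.  Records
#' failing decomposition or entropy computation are excluded with a
#' warning; an error is raised only if every record fails.
#'
#' @param dataset an [EEGDataset-class] with labelled records.
#' @param params entropy parameters from [entropyParams()].
#' @param waveletName,levels,mode passed to [dwtDecompose()].
#' @param representation \code{"coefficients"} (default: entropies of the
#'   decimated detail coefficient sequences) or \code{"reconstructed"}
#'   (entropies of the full-length single-sub-band reconstructions).
#' @param toleranceSource \code{"subband"} (default: r scales with the SD
#'   of each analysed sub-band, making features amplitude-invariant) or
#'   \code{"signal"} (r from the raw record's SD).
#' @param sdType passed to [entropyTolerance()].
#' @return a [FeatureMatrix-class] (6 features x kept records).
#' @export
extractFeatures <- function(dataset, params = entropyParams(),
                            waveletName = "db4", levels = 5L,
                            mode = "symmetric",
                            representation = c("coefficients", "reconstructed"),
                            toleranceSource = c("subband", "signal"),
                            sdType = "population") {
  stopifnot(is(dataset, "EEGDataset"))
  representation <- match.arg(representation)
  toleranceSource <- match.arg(toleranceSource)
  n <- length(dataset@records)
  if (n == 0L) stop("dataset is empty")
  vals <- matrix(NA_real_, nrow = 6L, ncol = n,
                 dimnames = list(.FEATURE_NAMES, NULL))
  keep <- logical(n)
  for (j in seq_len(n)) {
    rec <- dataset@records[[j]]
    fv <- tryCatch(
      .recordFeatures(rec, params, waveletName, levels, mode,
                      representation, toleranceSource, sdType),
      error = function(e) {
        warning("record '", rec@recordId, "' excluded: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(fv)) { vals[, j] <- fv; keep[j] <- TRUE }
  }
  if (!any(keep)) stop("feature extraction failed for every record")
  labs <- vapply(dataset@records, function(r) r@label, integer(1))
  if (anyNA(labs[keep]))
    stop("all records entering a FeatureMatrix must be labelled")
  FeatureMatrix(vals[, keep, drop = FALSE], labs[keep],
                vapply(dataset@records, function(r) r@recordId,
                       character(1))[keep])
}

#' One-way ANOVA F statistic for a two-class feature
#'
#' F = MS_between / MS_within with G = 2 groups:
#' numerator sum_g n_g (mean_g - grand mean)^2 / (G - 1), denominator the
#' pooled within-group sum of squares over (n - G).  For two groups this
#' equals the square of the pooled-variance two-sample t statistic.
#'
#' @param values numeric feature values.
#' @param labels class labels (+1/-1), both classes with >= 2 members.
#' @return F >= 0; \code{Inf} (with a warning) when the within-group
#'   variance is zero but the means differ.
#' @export
anovaF <- function(values, labels) {
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  groups <- unique(labels)
  if (length(groups) != 2L)
    stop("need exactly two classes, got ", length(groups))
  ns <- vapply(groups, function(g) sum(labels == g), integer(1))
  if (any(ns < 2L)) stop("each class needs at least 2 members")
  grand <- mean(values)
  mg <- vapply(groups, function(g) mean(values[labels == g]), numeric(1))
  ssb <- sum(ns * (mg - grand)^2)
  ssw <- sum(vapply(seq_along(groups), function(i)
    sum((values[labels == groups[i]] - mg[i])^2), numeric(1)))
  msb <- ssb / 1            # G - 1 = 1
  msw <- ssw / (length(values) - 2L)
  if (msw == 0) {
    if (msb == 0) return(0)
    warning("zero within-group variance: F is infinite")
    return(Inf)
  }
  msb / msw
}

#' Rank features by decreasing ANOVA F
#'
#' Computes [anovaF()] per feature row and orders features by decreasing
#' F, ties broken by lower original index.  Features with higher F
#' separate the ictal and interictal classes more strongly and are tried
#' first by [fsfs()].
#'
#' @param fm a [FeatureMatrix-class] with >= 2 records per class.
#' @return a [FeatureRanking-class].
#' @export
rankFeatures <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  vals <- featureValues(fm)
  labs <- classLabels(fm)
  f <- vapply(seq_len(nrow(vals)), function(i) anovaF(vals[i, ], labs),
              numeric(1))
  names(f) <- rownames(vals)
  ord <- order(-f, seq_along(f))
  new("FeatureRanking", fStatistics = f, order = as.integer(ord))
}

#' Forward sequential feature selection over a ranking
#'
#' Features are added one at a time in ranking order; after each addition
#' the evaluator's cross-validation error is recorded.  At the first
#' STRICT increase in error the addition is rolled back and the previous
#' subset is returned (ties continue); if the error never strictly
#' increases, all features are selected.
#'
#' @param fm a [FeatureMatrix-class].
#' @param ranking a [FeatureRanking-class] covering all features.
#' @param evaluator function(featureIdx) returning a CV error rate in
#'   \code{[0, 1]}; defaults to [makeEnsembleEvaluator()] -- the 10-fold
#'   stratified CV error of the full voting ensemble on the candidate
#'   subset.
#' @param seed integer seed forwarded to the default evaluator's folds.
#' @param config pipeline configuration for the default evaluator.
#' @return a [SelectionResult-class].
#' @export
fsfs <- function(fm, ranking = rankFeatures(fm), evaluator = NULL,
                 seed = 1L, config = pipelineConfig()) {
  stopifnot(is(fm, "FeatureMatrix"), is(ranking, "FeatureRanking"))
  if (length(ranking@order) != nrow(fm))
    stop("ranking must cover all features")
  if (is.null(evaluator))
    evaluator <- makeEnsembleEvaluator(fm, config, seed)
  trace <- numeric(0)
  stoppedAt <- NA_integer_
  nsel <- 0L
  for (step in seq_along(ranking@order)) {
    cand <- ranking@order[seq_len(step)]
    err <- tryCatch(evaluator(cand), error = function(e) {
      e$errorTrace <- trace
      stop(e)
    })
    if (!is.numeric(err) || err < 0 || err > 1)
      stop("evaluator must return an error rate in [0, 1]")
    trace <- c(trace, err)
    if (step > 1L && err > trace[step - 1L]) {
      stoppedAt <- step
      break
    }
    nsel <- step
  }
  new("SelectionResult",
      selected = as.integer(ranking@order[seq_len(nsel)]),
      errorTrace = trace, stoppedAt = stoppedAt)
}

#' Default FSFS evaluator: ensemble CV error on a feature subset
#'
#' Returns a closure computing the stratified k-fold cross-validation
#' error (1 - mean fold accuracy) of the majority-vote ensemble restricted
#' to a candidate feature subset.  Folds are drawn once from the seed so
#' every candidate subset is scored on identical folds.
#'
#' @param fm a [FeatureMatrix-class].
#' @param config pipeline configuration ([pipelineConfig()]).
#' @param seed integer fold seed.
#' @return function(featureIdx) -> error rate in \code{[0, 1]}.
#' @export
makeEnsembleEvaluator <- function(fm, config = pipelineConfig(), seed = 1L) {
  folds <- kfoldSplit(classLabels(fm), k = config$folds,
                      stratified = config$stratified, seed = seed)
  function(featureIdx) {
    mask <- logical(nrow(fm))
    mask[featureIdx] <- TRUE
    rep <- .cvOverFolds(fm, mask, folds, config)
    1 - mean(rep$foldAccuracy)
  }
}
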