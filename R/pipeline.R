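# Pipeline configuration, the end-to-end driver and report writers.

#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline.  The defaults are the
#' reference settings: db4 wavelet, 5 levels, symmetric padding, entropy
#' on the d3/d4/d5 coefficient sequences with m = 2, rCoeff = 0.2, t = 1;
#' LS-SVM gamma = 10, KNN k = 3, vote-fraction scoring; stratified
#' 10-fold cross-validation with feature selection run once on the full
#' dataset before CV (\code{selectionMode = "full"}).
#' \code{selectionMode = "nested"} instead re-runs ranking and FSFS inside
#' each training fold -- the honest generalization estimate, at the price
#' of a different protocol from the reference workflow.
#'
#' @param wavelet,levels,padding,representation wavelet stage; see
#'   [dwtDecompose()] and [extractFeatures()].
#' @param m,rCoeff,t,toleranceSource,sdType entropy stage; see
#'   [entropyParams()], [entropyTolerance()].
#' @param gamma,k,scoreMode classifier stage; see [trainEnsemble()].
#' @param folds,stratified cross-validation stage; see [kfoldSplit()].
#' @param selectionMode \code{"full"} or \code{"nested"}.
#' @return validated configuration list.
#' @export
pipelineConfig <- function(wavelet = "db4", levels = 5L,
                           padding = "symmetric",
                           representation = "coefficients",
                           m = 2L, rCoeff = 0.2, t = 1L,
                           toleranceSource = "subband",
                           sdType = "population",
                           gamma = 10, k = 3L,
                           scoreMode = "votes",
                           folds = 10L, stratified = TRUE,
                           selectionMode = "full") {
  cfg <- list(wavelet = wavelet, levels = as.integer(levels),
              padding = match.arg(padding, c("symmetric", "periodization")),
              representation = match.arg(representation,
                                         c("coefficients", "reconstructed")),
              m = as.integer(m), rCoeff = rCoeff, t = as.integer(t),
              toleranceSource = match.arg(toleranceSource,
                                          c("subband", "signal")),
              sdType = match.arg(sdType, c("population", "sample")),
              gamma = gamma, k = as.integer(k),
              scoreMode = match.arg(scoreMode, c("votes", "calibrated")),
              folds = as.integer(folds), stratified = isTRUE(stratified),
              selectionMode = match.arg(selectionMode, c("full", "nested")))
  entropyParams(cfg$m, cfg$rCoeff, cfg$t)   # validates the entropy triple
  .waveletFilters(cfg$wavelet)              # validates the wavelet name
  if (cfg$gamma <= 0) stop("gamma must be > 0")
  if (cfg$k < 1L || cfg$k %% 2L == 0L) stop("k must be a positive odd integer")
  if (cfg$folds < 2L) stop("folds must be >= 2")
  cfg
}

#' Read a pipeline configuration from a JSON file
#'
#' Keys absent from the file keep their defaults; unknown keys are an
#' error naming the offending key.
#'
#' @param path JSON file path.
#' @return configuration list as from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  raw <- read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("invalid config key(s): ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, raw)
}

.extractWithConfig <- function(dataset, config) {
  extractFeatures(dataset,
                  params = entropyParams(config$m, config$rCoeff, config$t),
                  waveletName = config$wavelet, levels = config$levels,
                  mode = config$padding,
                  representation = config$representation,
                  toleranceSource = config$toleranceSource,
                  sdType = config$sdType)
}

# Nested protocol: ranking + FSFS re-run inside each training fold.
.runNestedCV <- function(fm, config, seed) {
  folds <- kfoldSplit(classLabels(fm), k = config$folds,
                      stratified = config$stratified, seed = seed)
  vals <- t(featureValues(fm))
  labs <- as.numeric(classLabels(fm))
  n <- nrow(vals)
  predicted <- numeric(n); scores <- numeric(n)
  foldAcc <- numeric(length(folds))
  for (j in seq_along(folds)) {
    test <- folds[[j]]
    train <- setdiff(seq_len(n), test)
    fmTrain <- FeatureMatrix(t(vals[train, , drop = FALSE]), labs[train],
                             recordIds(fm)[train])
    rownames(fmTrain) <- rownames(fm)
    sel <- fsfs(fmTrain, rankFeatures(fmTrain),
                seed = deriveSeed(seed, j), config = config)
    mask <- logical(ncol(vals)); mask[sel@selected] <- TRUE
    model <- trainEnsemble(vals[train, , drop = FALSE], labs[train],
                           featureMask = mask, gamma = config$gamma,
                           k = config$k, scoreMode = config$scoreMode)
    p <- predict(model, vals[test, , drop = FALSE])
    predicted[test] <- p
    scores[test] <- ensembleScore(model, vals[test, , drop = FALSE])
    foldAcc[j] <- mean(p == labs[test])
  }
  cm <- .confusion(labs, predicted)
  met <- computeMetrics(cm, scores = scores, labels = labs)
  new("MetricsReport", foldAccuracy = foldAcc, confusion = cm,
      sensitivity = met$sensitivity, specificity = met$specificity,
      auc = met$auc, seed = as.integer(seed), config = config)
}

#' Run the full detection pipeline
#'
#' Chains the stages: entropy feature extraction (unless a
#' [FeatureMatrix-class] is supplied directly), ANOVA-F ranking, forward
#' sequential feature selection and cross-validated evaluation of the
#' voting ensemble.  With \code{selectionMode = "full"} (the reference
#' protocol) ranking and selection use the full dataset and a single CV
#' evaluates the selected subset; with \code{"nested"} selection is
#' re-run inside each training fold and the ranking/selection slots of
#' the result refer to the full data for reporting only.
#'
#' @param x an [EEGDataset-class] or a [FeatureMatrix-class].
#' @param config pipeline configuration ([pipelineConfig()]).
#' @param seed integer master seed; fold and selection seeds derive from
#'   it.
#' @return list with elements \code{features} ([FeatureMatrix-class]),
#'   \code{ranking} ([FeatureRanking-class]), \code{selection}
#'   ([SelectionResult-class]) and \code{metrics}
#'   ([MetricsReport-class]).
#' @examples
#' \donttest{
#' ds <- generateDataset(synthConfig(nPerClass = 10, nSamples = 1024))
#' res <- runPipeline(ds, seed = 42)
#' meanAccuracy(res$metrics)
#' }
#' @export
runPipeline <- function(x, config = pipelineConfig(), seed = 1L) {
  fm <- if (is(x, "FeatureMatrix")) x else .extractWithConfig(x, config)
  ranking <- rankFeatures(fm)
  selection <- fsfs(fm, ranking, seed = deriveSeed(seed, 1L),
                    config = config)
  metrics <- if (config$selectionMode == "nested")
    .runNestedCV(fm, config, seed = deriveSeed(seed, 2L))
  else
    runCV(fm, config, selected = selection@selected,
          seed = deriveSeed(seed, 2L))
  list(features = fm, ranking = ranking, selection = selection,
       metrics = metrics)
}

# --- report writers ----------------------------------------------------

#' Write a feature matrix as CSV
#'
#' One row per record: \code{record_id}, \code{label}, then the six
#' feature columns.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeaturesCSV <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  df <- data.frame(record_id = recordIds(fm), label = classLabels(fm),
                   t(featureValues(fm)), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [writeFeaturesCSV()]
#' @param path CSV path.
#' @return a [FeatureMatrix-class].
#' @export
readFeaturesCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("record_id", "label")
  if (!all(need %in% colnames(df))) stop("not a feature CSV: ", path)
  vals <- t(as.matrix(df[, setdiff(colnames(df), need), drop = FALSE]))
  FeatureMatrix(vals, df$label, df$record_id)
}

.reportPayload <- function(result) {
  met <- result$metrics
  fa <- met@foldAccuracy
  list(
    ranking = list(
      f_statistics = as.list(result$ranking@fStatistics),
      order = result$ranking@order
    ),
    selection = list(
      selected = result$selection@selected,
      selected_names = names(result$ranking@fStatistics)[result$selection@selected],
      error_trace = result$selection@errorTrace,
      stopped_at = result$selection@stoppedAt
    ),
    metrics = list(
      fold_accuracy = fa,
      mean_accuracy = mean(fa), min_accuracy = min(fa),
      max_accuracy = max(fa), sd_accuracy = stats::sd(fa),
      sensitivity = met@sensitivity, specificity = met@specificity,
      auc = met@auc,
      confusion = list(TP = met@confusion[1, 1], FN = met@confusion[1, 2],
                       FP = met@confusion[2, 1], TN = met@confusion[2, 2])
    ),
    seed = met@seed,
    config = met@config
  )
}

#' Write the pipeline result as a JSON report
#'
#' Serialises ranking, selection, metrics, the seed and the resolved
#' configuration snapshot.  The payload contains no timestamps, so two
#' runs with identical config and seed produce byte-identical files.
#'
#' @param result list returned by [runPipeline()].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeReportJSON <- function(result, path) {
  payload <- .reportPayload(result)
  writeLines(toJSON(payload, auto_unbox = TRUE, digits = NA,
                    pretty = TRUE, na = "null"), path)
  invisible(path)
}
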