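# Accessors and show methods.

#' @describeIn EEGRecord-class amplitude samples
#' @export
setMethod("samples", "EEGRecord", function(x) x@samples)

#' @describeIn EEGRecord-class sampling rate in Hz
#' @export
setMethod("samplingRate", "EEGRecord", function(x) x@samplingRate)

#' @describeIn EEGRecord-class class label (+1 ictal, -1 interictal, NA)
#' @export
setMethod("classLabel", "EEGRecord", function(x) x@label)

#' @describeIn EEGRecord-class record identifier
#' @export
setMethod("recordId", "EEGRecord", function(x) x@recordId)

setMethod("length", "EEGRecord", function(x) length(x@samples))

setMethod("show", "EEGRecord", function(object) {
  lab <- if (is.na(object@label)) "unknown"
         else if (object@label > 0) "ictal (+1)" else "interictal (-1)"
  cat(sprintf("EEGRecord '%s': %d samples @ %.2f Hz (%.1f s), label %s\n",
              object@recordId, length(object@samples), object@samplingRate,
              length(object@samples) / object@samplingRate, lab))
})

#' @describeIn EEGDataset-class list of records
#' @export
setMethod("records", "EEGDataset", function(x) x@records)

#' @describeIn EEGDataset-class sampling rate shared by all records
#' @export
setMethod("samplingRate", "EEGDataset", function(x) {
  if (length(x@records) == 0L) return(NA_real_)
  x@records[[1L]]@samplingRate
})

#' @describeIn EEGDataset-class table of record counts per class label
#' @export
setMethod("classCounts", "EEGDataset", function(x) {
  labs <- vapply(x@records, function(r) r@label, integer(1))
  c(ictal = sum(labs == 1L, na.rm = TRUE),
    interictal = sum(labs == -1L, na.rm = TRUE),
    unknown = sum(is.na(labs)))
})

#' @describeIn EEGDataset-class per-record class labels
#' @export
setMethod("classLabels", "EEGDataset", function(x)
  vapply(x@records, function(r) r@label, integer(1)))

setMethod("length", "EEGDataset", function(x) length(x@records))

setMethod("[[", "EEGDataset", function(x, i) x@records[[i]])

setMethod("show", "EEGDataset", function(object) {
  cc <- classCounts(object)
  cat(sprintf("EEGDataset: %d records @ %.2f Hz (%d ictal, %d interictal, %d unknown)\n",
              length(object@records), samplingRate(object),
              cc[["ictal"]], cc[["interictal"]], cc[["unknown"]]))
})

#' @describeIn SubbandSet-class one coefficient sequence by name (e.g. "d3")
#' @export
setMethod("subband", "SubbandSet", function(x, name) {
  if (!name %in% names(x@coefficients))
    stop("unknown sub-band '", name, "'; available: ",
         paste(names(x@coefficients), collapse = ", "))
  x@coefficients[[name]]
})

#' @describeIn SubbandSet-class sub-band names, d1..dL then aL
#' @export
setMethod("subbandNames", "SubbandSet", function(x) names(x@coefficients))

#' @describeIn SubbandSet-class wavelet used for the decomposition
#' @export
setMethod("waveletName", "SubbandSet", function(x) x@waveletName)

setMethod("show", "SubbandSet", function(object) {
  cat(sprintf("SubbandSet: %s, %d levels, source length %d, %s padding\n",
              object@waveletName, object@levels, object@sourceLength,
              object@paddingMode))
  cat("  lengths:",
      paste(sprintf("%s=%d", names(object@coefficients),
                    lengths(object@coefficients)), collapse = " "), "\n")
})

#' @describeIn FeatureMatrix-class the entropy feature matrix (features x records)
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) assay(x, "entropy"))

#' @describeIn FeatureMatrix-class per-record class labels
#' @export
setMethod("classLabels", "FeatureMatrix", function(x) colData(x)$label)

#' @describeIn FeatureMatrix-class per-record identifiers
#' @export
setMethod("recordIds", "FeatureMatrix", function(x) colData(x)$record_id)

setMethod("show", "FeatureRanking", function(object) {
  cat("FeatureRanking (decreasing ANOVA F):\n")
  nm <- names(object@fStatistics)
  for (i in object@order)
    cat(sprintf("  %-10s F = %.4g\n", nm[i], object@fStatistics[i]))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d feature(s) selected [%s]\n",
              length(object@selected),
              paste(object@selected, collapse = ", ")))
  cat("  error trace:", paste(sprintf("%.4f", object@errorTrace),
                              collapse = " -> "), "\n")
  if (!is.na(object@stoppedAt))
    cat(sprintf("  stopped at addition %d (strict error increase)\n",
                object@stoppedAt))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: LS-SVM (gamma=%g) + %d-NN + GNB, %d/%d features, '%s' scoring\n",
              object@lssvm@gamma, object@knn@k, sum(object@featureMask),
              length(object@featureMask), object@scoreMode))
})

#' @describeIn MetricsReport-class per-fold accuracies
#' @export
setMethod("foldAccuracy", "MetricsReport", function(x) x@foldAccuracy)

#' @describeIn MetricsReport-class mean of the per-fold accuracies
#' @export
setMethod("meanAccuracy", "MetricsReport", function(x) mean(x@foldAccuracy))

#' @describeIn MetricsReport-class pooled sensitivity TP/(TP+FN)
#' @export
setMethod("sensitivity", "MetricsReport", function(x) x@sensitivity)

#' @describeIn MetricsReport-class pooled specificity TN/(TN+FP)
#' @export
setMethod("specificity", "MetricsReport", function(x) x@specificity)

#' @describeIn MetricsReport-class area under the ROC curve
#' @export
setMethod("auc", "MetricsReport", function(x) x@auc)

#' @describeIn MetricsReport-class pooled 2x2 confusion matrix
#' @export
setMethod("confusionMatrix", "MetricsReport", function(x) x@confusion)

setMethod("show", "MetricsReport", function(object) {
  fa <- object@foldAccuracy
  cat("MetricsReport (stratified k-fold cross-validation)\n")
  cat(sprintf("  accuracy: mean %.4f  min %.4f  max %.4f  sd %.4f  (%d folds)\n",
              mean(fa), min(fa), max(fa), stats::sd(fa), length(fa)))
  cat(sprintf("  sensitivity %.4f   specificity %.4f   AUC %.4f\n",
              object@sensitivity, object@specificity, object@auc))
  cat("  confusion (rows truth +1/-1, cols predicted +1/-1):\n")
  print(object@confusion)
})
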