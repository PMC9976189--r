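#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @export
setGeneric("subband", function(x, name) standardGeneric("subband"))

#' @export
setGeneric("subbandNames", function(x) standardGeneric("subbandNames"))

#' @export
setGeneric("waveletName", function(x) standardGeneric("waveletName"))

#' @export
setGeneric("reconstructSignal", function(x) standardGeneric("reconstructSignal"))

#' @export
setGeneric("reconstructSubband", function(x, name) standardGeneric("reconstructSubband"))

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @export
setGeneric("decisionValues", function(object, newdata) standardGeneric("decisionValues"))

#' @export
setGeneric("foldAccuracy", function(x) standardGeneric("foldAccuracy"))

#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
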