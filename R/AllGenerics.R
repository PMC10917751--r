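#' @rdname PeptideSet-accessors
#' @export
setGeneric("pepSeqs", function(x) standardGeneric("pepSeqs"))
#' @rdname PeptideSet-accessors
#' @export
setGeneric("pepAlleles", function(x) standardGeneric("pepAlleles"))
#' @rdname PeptideSet-accessors
#' @export
setGeneric("pepLabels", function(x) standardGeneric("pepLabels"))
#' @rdname PeptideSet-accessors
#' @export
setGeneric("pepScores", function(x) standardGeneric("pepScores"))
#' @rdname PeptideSet-accessors
#' @export
setGeneric("datasetName", function(x) standardGeneric("datasetName"))
#' @rdname PeptideSet-accessors
#' @export
setGeneric("datasetMetadata", function(x) standardGeneric("datasetMetadata"))

#' @rdname PSSM-accessors
#' @export
setGeneric("pssmProb", function(x) standardGeneric("pssmProb"))
#' @rdname PSSM-accessors
#' @export
setGeneric("pssmBackground", function(x) standardGeneric("pssmBackground"))
#' @rdname PSSM-accessors
#' @export
setGeneric("pssmLength", function(x) standardGeneric("pssmLength"))
#' @rdname PSSM-accessors
#' @export
setGeneric("logOdds", function(x, base = 2) standardGeneric("logOdds"))
#' @rdname PSSM-accessors
#' @export
setGeneric("consensusPeptide", function(x) standardGeneric("consensusPeptide"))

#' @rdname AttributionVector-accessors
#' @export
setGeneric("attrValues", function(x) standardGeneric("attrValues"))
#' @rdname AttributionVector-accessors
#' @export
setGeneric("attrMeta", function(x) standardGeneric("attrMeta"))
#' @rdname AttributionVector-accessors
#' @export
setGeneric("attrBaseline", function(x) standardGeneric("attrBaseline"))

#' @rdname DdgProfile-class
#' @export
setGeneric("ddgValues", function(x) standardGeneric("ddgValues"))
#' @rdname DdgProfile-class
#' @export
setGeneric("ddgWildtype", function(x) standardGeneric("ddgWildtype"))

#' @rdname PredictorHandle-accessors
#' @export
setGeneric("predictorId", function(x) standardGeneric("predictorId"))
#' @rdname PredictorHandle-accessors
#' @export
setGeneric("callCount", function(x) standardGeneric("callCount"))
#' @rdname PredictorHandle-accessors
#' @export
setGeneric("resetCallCount", function(x) standardGeneric("resetCallCount"))

#' @rdname BackgroundSet-accessors
#' @export
setGeneric("bgPeptides", function(x) standardGeneric("bgPeptides"))
#' @rdname BackgroundSet-accessors
#' @export
setGeneric("bgWeights", function(x) standardGeneric("bgWeights"))

#' @rdname ClusterAssignment-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname ClusterAssignment-accessors
#' @export
setGeneric("clusterPssms", function(x) standardGeneric("clusterPssms"))
#' @rdname ClusterAssignment-accessors
#' @export
setGeneric("averageKld", function(x) standardGeneric("averageKld"))
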