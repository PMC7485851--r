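#' Number of samples in an object
#'
#' @param x a RIPRecord, MetricSet, PatternSequence or SyntheticRecord.
#' @return integer sample count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Sampling rate in Hz
#'
#' @param x a RIPRecord, MetricSet or SyntheticRecord.
#' @return numeric(1), Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname ripChannels
#' @export
setGeneric("rcg", function(x) standardGeneric("rcg"))

#' Channel accessors for RIP records
#'
#' @param x a RIPRecord or SyntheticRecord.
#' @return numeric vector of belt samples.
#' @name ripChannels
#' @export
setGeneric("abd", function(x) standardGeneric("abd"))

#' Pattern labels of a sequence
#'
#' @param x a PatternSequence or SyntheticRecord.
#' @return character vector of labels.
#' @export
setGeneric("patternLabels", function(x) standardGeneric("patternLabels"))

#' Compute the AUREA metric set from a RIP record
#'
#' @param record a [RIPRecord-class].
#' @param cfg an [AnalysisConfig-class]; defaults to [analysisConfig()].
#' @return A [MetricSet-class] aligned with the record.
#' @seealso [trainAurea()], [classify()]
#' @export
setGeneric("computeMetrics",
           function(record, cfg = analysisConfig())
             standardGeneric("computeMetrics"))

#' Classify every sample of a metric set with a trained cascade
#'
#' @param metrics a [MetricSet-class].
#' @param model a trained [AureaModel-class].
#' @return A [PatternSequence-class] over PAU, MVT, SYB, ASB, UNK.
#' @export
setGeneric("classify",
           function(metrics, model) standardGeneric("classify"))

#' Merge reference categories into the 4-pattern vocabulary
#'
#' SIH, MVT and UNK map to the single category UNKNOWN; PAU, SYB and ASB are
#' unchanged.  Idempotent.
#'
#' @param pseq a [PatternSequence-class].
#' @return A merged [PatternSequence-class] over PAU, SYB, ASB, UNKNOWN.
#' @export
setGeneric("mergePatterns", function(pseq) standardGeneric("mergePatterns"))

#' Maximal-run segmentation of a pattern sequence
#'
#' @param pseq a [PatternSequence-class].
#' @param fs sampling rate in Hz (for durations).
#' @return data.frame with columns `label`, `start` (0-based), `length`
#'   (samples) and `duration` (seconds); segments tile the sequence.
#' @export
setGeneric("segmentEvents",
           function(pseq, fs) standardGeneric("segmentEvents"))
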