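# Accessors and show methods.

#' @describeIn nSamples samples in a record.
setMethod("nSamples", "RIPRecord", function(x) length(x@rcg))
#' @describeIn nSamples samples in a metric set.
setMethod("nSamples", "MetricSet", function(x) length(x@nvRcg))
#' @describeIn nSamples samples in a pattern sequence.
setMethod("nSamples", "PatternSequence", function(x) length(x@labels))
#' @describeIn nSamples samples in a synthetic record.
setMethod("nSamples", "SyntheticRecord", function(x) length(x@record@rcg))

#' @describeIn samplingRate of a record.
setMethod("samplingRate", "RIPRecord", function(x) x@fs)
#' @describeIn samplingRate of a metric set.
setMethod("samplingRate", "MetricSet", function(x) x@fs)
#' @describeIn samplingRate of a synthetic record.
setMethod("samplingRate", "SyntheticRecord", function(x) x@record@fs)

#' @describeIn ripChannels ribcage channel of a record.
setMethod("rcg", "RIPRecord", function(x) x@rcg)
#' @describeIn ripChannels abdomen channel of a record.
setMethod("abd", "RIPRecord", function(x) x@abd)
#' @describeIn ripChannels ribcage channel of a synthetic record.
setMethod("rcg", "SyntheticRecord", function(x) x@record@rcg)
#' @describeIn ripChannels abdomen channel of a synthetic record.
setMethod("abd", "SyntheticRecord", function(x) x@record@abd)

#' @describeIn patternLabels labels of a sequence.
setMethod("patternLabels", "PatternSequence", function(x) x@labels)
#' @describeIn patternLabels ground-truth labels of a synthetic record.
setMethod("patternLabels", "SyntheticRecord", function(x) x@truth@labels)

#' Coerce a MetricSet to a data.frame
#'
#' @param x a [MetricSet-class].
#' @param row.names,optional,... ignored.
#' @return data.frame with one row per sample.
#' @export
setMethod("as.data.frame", "MetricSet",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(nvRcg = x@nvRcg, nvAbd = x@nvAbd, nppRcg = x@nppRcg,
             nppAbd = x@nppAbd, bPlus = x@bPlus, bMinus = x@bMinus,
             fResp = x@fResp, phi = x@phi, valid = x@validMask)
})

setMethod("show", "RIPRecord", function(object) {
  cat(sprintf("RIPRecord: %d samples (%.1f s) at %g Hz\n",
              length(object@rcg), length(object@rcg) / object@fs,
              object@fs))
})

setMethod("show", "MetricSet", function(object) {
  n <- length(object@nvRcg)
  cat(sprintf("MetricSet: %d samples at %g Hz (%d valid)\n",
              n, object@fs, sum(object@validMask)))
  cat(sprintf("  nvRcg [%.2f, %.2f]  nppRcg [%.2f, %.2f]  b+ med %.3g  b- med %.3g\n",
              min(object@nvRcg), max(object@nvRcg),
              min(object@nppRcg), max(object@nppRcg),
              stats::median(object@bPlus), stats::median(object@bMinus)))
})

setMethod("show", "KMeansStage", function(object) {
  cat(sprintf("KMeansStage %s on {%s}: cJ=(%s) cM=(%s) nJ=%d nM=%d w=%.3f\n",
              object@name, paste(object@features, collapse = ", "),
              paste(sprintf("%.3g", object@cJ), collapse = ", "),
              paste(sprintf("%.3g", object@cM), collapse = ", "),
              object@nJ, object@nM, object@wJM))
})

setMethod("show", "AureaModel", function(object) {
  cat(sprintf("AureaModel (fs = %g Hz, seed = %d)\n", object@fs,
              object@seed))
  for (s in object@stages) show(s)
})

setMethod("show", "PatternSequence", function(object) {
  tab <- table(object@labels)
  cat(sprintf("PatternSequence: %d samples | %s\n", length(object@labels),
              paste(sprintf("%s %.1f%%", names(tab),
                            100 * as.numeric(tab) / length(object@labels)),
                    collapse = ", ")))
})

setMethod("show", "RespConfusion", function(object) {
  cat("RespConfusion (rows = reference, columns = predicted):\n")
  print(object@counts)
})

setMethod("show", "SyntheticRecord", function(object) {
  cat(sprintf("SyntheticRecord (seed %d): ", object@seed))
  show(object@record)
  show(object@truth)
})
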