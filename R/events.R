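# Pattern-event analysis: maximal-run segmentation, fragmentation
# histograms, and event-level pattern matching between a reference and a
# predicted sequence.

#' @describeIn segmentEvents run-length segmentation; start indices are
#'   0-based and the segments tile the sequence without gaps or overlaps.
setMethod("segmentEvents", "PatternSequence", function(pseq, fs) {
  r <- rle(pseq@labels)
  len <- r$lengths
  data.frame(label = r$values,
             start = cumsum(c(0L, len[-length(len)])),
             length = len,
             duration = len / fs,
             stringsAsFactors = FALSE)
})

#' Rebuild a PatternSequence from its event segments
#'
#' Inverse of [segmentEvents()]; used for round-trip checks.
#'
#' @param segments data.frame as returned by [segmentEvents()].
#' @return A [PatternSequence-class].
#' @export
segmentsToSequence <- function(segments) {
  PatternSequence(rep(segments$label, segments$length))
}

#' Fragmentation histogram of event lengths
#'
#' Counts pattern events by length bin, per pattern.  Sample-wise
#' classification noise shows up as a proliferation of very short events
#' (below ~2 s / 100 samples at 50 Hz).
#'
#' @param segments data.frame from [segmentEvents()].
#' @param breaks right-closed length-bin breaks in samples; defaults to
#'   half-decade style bins up to the longest event.
#' @return data.frame with columns `label`, `bin` (factor), `count` and
#'   `samples` (count x summed lengths); `sum(samples)` equals the total
#'   sample count of the sequence.
#' @export
fragmentationHistogram <- function(segments, breaks = NULL) {
  if (is.null(breaks)) {
    top <- max(segments$length)
    breaks <- unique(c(0, 10, 25, 50, 100, 250, 500, 1000,
                       2^ceiling(log2(top + 1))))
    breaks <- breaks[breaks <= max(top, 1)]
    if (max(breaks) < top) breaks <- c(breaks, top)
  }
  bin <- cut(segments$length, breaks = breaks, include.lowest = FALSE)
  agg <- stats::aggregate(
    cbind(count = rep(1L, nrow(segments)), samples = segments$length),
    by = list(label = segments$label, bin = bin), FUN = sum)
  agg[order(agg$label, agg$bin), , drop = FALSE]
}

#' Event-level pattern matching between reference and prediction
#'
#' For every reference event lasting at least `minDurationS` seconds
#' (inclusive), computes the fraction of its samples that the prediction
#' labels identically, and reports, per pattern and overall, the fraction of
#' such events whose overlap strictly exceeds `overlapThreshold`.
#'
#' @param refSegments reference events from [segmentEvents()].
#' @param pred predicted [PatternSequence-class] on the same sample axis.
#' @param fs sampling rate in Hz.
#' @param minDurationS minimum event duration in seconds (default 2).
#' @param overlapThreshold overlap fraction an event must exceed to count as
#'   matched (default 0.5, strict).
#' @return list with `perPattern` (data.frame: pattern, nEvents, matched
#'   fraction), `overall` (fraction over all qualifying events) and
#'   `overlaps` (per-event overlap fractions).
#' @export
patternMatching <- function(refSegments, pred, fs, minDurationS = 2,
                            overlapThreshold = 0.5) {
  n <- sum(refSegments$length)
  if (n != length(pred@labels))
    aureaValidationError(
      "reference events cover %d samples but prediction has %d", n,
      length(pred@labels))
  keep <- refSegments$duration >= minDurationS
  ev <- refSegments[keep, , drop = FALSE]
  if (nrow(ev) == 0L)
    return(list(perPattern = data.frame(pattern = character(),
                                        nEvents = integer(),
                                        matched = numeric()),
                overall = NaN, overlaps = numeric()))
  overlaps <- vapply(seq_len(nrow(ev)), function(i) {
    idx <- (ev$start[i] + 1L):(ev$start[i] + ev$length[i])
    mean(pred@labels[idx] == ev$label[i])
  }, numeric(1))
  matched <- overlaps > overlapThreshold
  per <- stats::aggregate(matched, by = list(pattern = ev$label), FUN = mean)
  names(per)[2L] <- "matched"
  per$nEvents <- as.integer(table(ev$label)[per$pattern])
  list(perPattern = per[, c("pattern", "nEvents", "matched")],
       overall = mean(matched), overlaps = overlaps)
}
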