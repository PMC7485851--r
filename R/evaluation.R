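# Evaluation of a predicted pattern sequence against a reference:
# category merging, confusion matrix, accuracy / precision / recall /
# F-score, and pattern-specific confusion.
#
# Orientation note: the published AUREA performance indices normalise
# "precision" over the REFERENCE row and "recall" over the predicted column
# of the confusion matrix (with rows = reference), which is the transpose of
# the textbook convention.  The default `orientation = "published"`
# reproduces the printed tables; `orientation = "conventional"` exposes the
# standard definitions.

#' @describeIn mergePatterns map SIH, MVT and UNK to UNKNOWN.
setMethod("mergePatterns", "PatternSequence", function(pseq) {
  lab <- pseq@labels
  lab[lab %in% c("SIH", "MVT", "UNK")] <- "UNKNOWN"
  PatternSequence(lab)
})

#' Sample-by-sample confusion matrix
#'
#' @param ref reference [PatternSequence-class] (rows).
#' @param pred predicted [PatternSequence-class] (columns).
#' @param labels ordered pattern labels; defaults to [MERGED_LEVELS].
#' @return A [RespConfusion-class] whose total equals the number of samples.
#' @export
confusionMatrix <- function(ref, pred, labels = MERGED_LEVELS) {
  if (length(ref@labels) != length(pred@labels))
    aureaValidationError(
      "reference (%d) and prediction (%d) differ in length",
      length(ref@labels), length(pred@labels))
  bad <- unique(c(ref@labels, pred@labels))
  bad <- bad[!bad %in% labels]
  if (length(bad))
    aureaValidationError("label(s) outside the comparison vocabulary: %s",
                         paste(bad, collapse = ", "))
  counts <- table(factor(ref@labels, levels = labels),
                  factor(pred@labels, levels = labels))
  m <- matrix(as.numeric(counts), nrow = length(labels),
              dimnames = list(reference = labels, predicted = labels))
  new("RespConfusion", counts = m, labels = labels)
}

#' Build a RespConfusion from pre-tabulated counts
#'
#' Convenience for evaluating published count tables.
#'
#' @param counts K x K numeric matrix, rows = reference.
#' @param labels ordered pattern labels.
#' @return A [RespConfusion-class].
#' @export
respConfusion <- function(counts, labels = MERGED_LEVELS) {
  m <- as.matrix(counts)
  dimnames(m) <- list(reference = labels, predicted = labels)
  new("RespConfusion", counts = m, labels = labels)
}

#' Overall classification accuracy
#'
#' Fraction of samples on the confusion-matrix diagonal,
#' `sum(M[i,i]) / sum(M)`.
#'
#' @param cm a [RespConfusion-class].
#' @return fraction in [0, 1].
#' @export
overallAccuracy <- function(cm) {
  total <- sum(cm@counts)
  if (total <= 0) aureaValidationError("empty confusion matrix")
  sum(diag(cm@counts)) / total
}

.rowFraction <- function(cm, i) {
  rs <- sum(cm@counts[i, ])
  if (rs == 0) return(NaN)
  cm@counts[i, i] / rs
}

.colFraction <- function(cm, i) {
  cs <- sum(cm@counts[, i])
  if (cs == 0) return(NaN)
  cm@counts[i, i] / cs
}

.patternIndex <- function(cm, pattern) {
  i <- match(pattern, cm@labels)
  if (is.na(i))
    aureaValidationError("pattern '%s' not among matrix labels", pattern)
  i
}

#' Pattern-specific precision
#'
#' @param cm a [RespConfusion-class].
#' @param pattern pattern label.
#' @param orientation `"published"` (row-normalised over the reference row,
#'   reproducing the published AUREA tables) or `"conventional"`
#'   (column-normalised, the textbook definition).
#' @return fraction in [0, 1], or NaN if the normalising margin is empty.
#' @export
patternPrecision <- function(cm, pattern,
                             orientation = c("published", "conventional")) {
  orientation <- match.arg(orientation)
  i <- .patternIndex(cm, pattern)
  if (orientation == "published") .rowFraction(cm, i) else .colFraction(cm, i)
}

#' Pattern-specific recall
#'
#' @inheritParams patternPrecision
#' @return fraction in [0, 1], or NaN if the normalising margin is empty.
#' @export
patternRecall <- function(cm, pattern,
                          orientation = c("published", "conventional")) {
  orientation <- match.arg(orientation)
  i <- .patternIndex(cm, pattern)
  if (orientation == "published") .colFraction(cm, i) else .rowFraction(cm, i)
}

#' F-score (harmonic mean of precision and recall)
#'
#' @param p,r precision and recall, fractions in [0, 1].
#' @return `2 p r / (p + r)`; 0 by convention when both are 0.
#' @export
fScore <- function(p, r) {
  if (any(c(p, r) < 0 | c(p, r) > 1, na.rm = TRUE))
    aureaValidationError("precision and recall must lie in [0, 1]")
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Pattern-specific confusion
#'
#' Fraction of the reference samples of a pattern that the prediction
#' assigned to any other pattern (one minus the diagonal row fraction),
#' as a percentage.
#'
#' @inheritParams patternPrecision
#' @return percentage in [0, 100].
#' @export
patternConfusion <- function(cm, pattern) {
  i <- .patternIndex(cm, pattern)
  100 * (1 - .rowFraction(cm, i))
}

#' Summarise all performance indices of a confusion matrix
#'
#' @inheritParams patternPrecision
#' @return data.frame with one row per pattern: precision, recall, F-score
#'   and pattern-specific confusion (%), plus the overall accuracy as an
#'   attribute `"accuracy"`.
#' @export
performanceIndices <- function(cm,
                               orientation = c("published", "conventional")) {
  orientation <- match.arg(orientation)
  out <- data.frame(
    pattern = cm@labels,
    precision = vapply(cm@labels, patternPrecision, numeric(1), cm = cm,
                       orientation = orientation),
    recall = vapply(cm@labels, patternRecall, numeric(1), cm = cm,
                    orientation = orientation),
    row.names = NULL)
  out$fScore <- mapply(fScore, out$precision, out$recall)
  out$confusionPct <- vapply(cm@labels, patternConfusion, numeric(1), cm = cm)
  attr(out, "accuracy") <- overallAccuracy(cm)
  out
}
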