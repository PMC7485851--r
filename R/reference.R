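# Published reference tables from the original clinical evaluation of AUREA
# (21 infant records, 22,515,980 samples, EM consensus reference), shipped
# as plain text so the evaluation module can be exercised against known
# counts without any recording data.

#' Published reference confusion matrix
#'
#' The 4x4 sample-count confusion matrix from the original clinical
#' evaluation of AUREA against an expectation-maximization consensus of
#' manual scorings (rows = consensus reference, columns = AUREA), on the
#' merged vocabulary PAU, SYB, ASB, UNKNOWN.
#'
#' @return A [RespConfusion-class] totalling 22,515,980 samples.
#' @examples
#' overallAccuracy(referenceConfusion())  # ~0.80
#' @export
referenceConfusion <- function() {
  path <- system.file("extdata", "reference_confusion_counts.csv",
                      package = "aurea", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  respConfusion(as.matrix(df[, -1L]), labels = df$reference)
}

#' Published reference pattern-count table
#'
#' Six-pattern sample counts from the original clinical evaluation: one row
#' for the EM consensus reference and one for AUREA (which does not score
#' SIH).
#'
#' @return data.frame with columns scorer, PAU, SYB, ASB, MVT, UNK, SIH.
#' @export
referencePatternCounts <- function() {
  path <- system.file("extdata", "reference_pattern_counts.csv",
                      package = "aurea", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Merge a six-pattern count row to the four-pattern vocabulary
#'
#' Sums the MVT, UNK and SIH counts into UNKNOWN, conserving the total.
#'
#' @param counts named numeric vector with entries PAU, SYB, ASB, MVT, UNK,
#'   SIH.
#' @return named numeric vector over PAU, SYB, ASB, UNKNOWN.
#' @export
mergePatternCounts <- function(counts) {
  need <- c("PAU", "SYB", "ASB", "MVT", "UNK", "SIH")
  if (!all(need %in% names(counts)))
    aureaValidationError("counts must be named over %s",
                         paste(need, collapse = ", "))
  c(PAU = unname(counts["PAU"]), SYB = unname(counts["SYB"]),
    ASB = unname(counts["ASB"]),
    UNKNOWN = unname(counts["MVT"] + counts["UNK"] + counts["SIH"]))
}
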