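# Delimited-text I/O.  Dialect: comma-separated, UTF-8, one header row;
# the sample index is implicit in row order and 0-based wherever written.

#' Read a two-channel RIP record from delimited text
#'
#' Expects a header row with columns `time`, `rcg`, `abd` (extra columns are
#' ignored).  The sampling rate is taken from the `time` column spacing
#' unless overridden.
#'
#' @param path file path.
#' @param fs optional sampling rate in Hz, overriding the time column.
#' @return A [RIPRecord-class].
#' @export
readRipCsv <- function(path, fs = NULL) {
  if (!file.exists(path)) aureaIOError("file not found: %s", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) aureaIOError(
                   "cannot parse %s: %s", path, conditionMessage(e)))
  for (col in c("rcg", "abd"))
    if (!col %in% names(df))
      aureaIOError("missing channel column '%s' in %s", col, path)
  if (is.null(fs)) {
    if (!"time" %in% names(df) || nrow(df) < 2L)
      aureaIOError("no 'time' column to infer the sampling rate; supply fs")
    dt <- diff(df$time)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt))
      aureaIOError("time column of %s is not uniformly spaced", path)
    fs <- 1 / stats::median(dt)
  }
  RIPRecord(df$rcg, df$abd, fs)
}

#' Write a RIP record to delimited text
#'
#' @param record a [RIPRecord-class].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeRipCsv <- function(record, path) {
  n <- length(record@rcg)
  df <- data.frame(time = (seq_len(n) - 1L) / record@fs,
                   rcg = record@rcg, abd = record@abd)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pattern sequence from delimited text
#'
#' Columns `sample_index` (0-based) and `label`; labels must come from the
#' closed vocabulary ([PATTERN_LEVELS]).
#'
#' @param path file path.
#' @return A [PatternSequence-class].
#' @export
readPseq <- function(path) {
  if (!file.exists(path)) aureaIOError("file not found: %s", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) aureaIOError(
                   "cannot parse %s: %s", path, conditionMessage(e)))
  if (nrow(df) == 0L) aureaIOError("empty pattern sequence in %s", path)
  if (!all(c("sample_index", "label") %in% names(df)))
    aureaIOError("%s must have columns sample_index, label", path)
  bad <- which(!(df$label %in% PATTERN_LEVELS))
  if (length(bad))
    aureaIOError("unknown label '%s' at line %d of %s",
                 df$label[bad[1L]], bad[1L] + 1L, path)  # +1: header row
  df <- df[order(df$sample_index), , drop = FALSE]
  PatternSequence(df$label)
}

#' Write a pattern sequence to delimited text
#'
#' @param pseq a [PatternSequence-class].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writePseq <- function(pseq, path) {
  df <- data.frame(sample_index = seq_along(pseq@labels) - 1L,
                   label = pseq@labels)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metric set to delimited text
#'
#' One row per sample with columns nv_rcg, nv_abd, npp_rcg, npp_abd, b_plus,
#' b_minus, f_resp, phi, valid.
#'
#' @param metrics a [MetricSet-class].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeMetricsCsv <- function(metrics, path) {
  df <- data.frame(nv_rcg = metrics@nvRcg, nv_abd = metrics@nvAbd,
                   npp_rcg = metrics@nppRcg, npp_abd = metrics@nppAbd,
                   b_plus = metrics@bPlus, b_minus = metrics@bMinus,
                   f_resp = metrics@fResp, phi = metrics@phi,
                   valid = as.integer(metrics@validMask))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a trained model as versioned JSON
#'
#' Full-precision numbers, so load -> classify reproduces the saved model's
#' output bit for bit.
#'
#' @param model an [AureaModel-class].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  cfg <- model@cfg
  obj <- list(
    schema = "aurea-model",
    version = 1L,
    seed = model@seed,
    fs = model@fs,
    cfg = list(nLF = cfg@nLF, nQV = cfg@nQV, nV = cfg@nV,
               nDTPauMvt = cfg@nDTPauMvt, nDTSybAsb = cfg@nDTSybAsb,
               nMA = cfg@nMA, nQRMS = cfg@nQRMS, nRMS = cfg@nRMS,
               nSMO = cfg@nSMO, nB = cfg@nB, nBPhase = cfg@nBPhase,
               qVar = cfg@qVar, qRMS = cfg@qRMS, hpCutoff = cfg@hpCutoff),
    stages = lapply(model@stages, function(s) list(
      name = s@name, features = as.list(s@features),
      cJ = s@cJ, cM = s@cM, nJ = s@nJ, nM = s@nM, wJM = s@wJM)))
  # I(17) significant digits: doubles survive the text round-trip exactly
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE), path)
  invisible(path)
}

#' Load a trained model saved by [saveModel()]
#'
#' @param path file path.
#' @return An [AureaModel-class].
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) aureaIOError("file not found: %s", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) aureaIOError(
                    "cannot parse model file %s: %s", path,
                    conditionMessage(e)))
  if (!identical(obj$schema, "aurea-model"))
    aureaIOError("%s is not an aurea model file", path)
  cfg <- do.call(analysisConfig, lapply(obj$cfg, as.numeric))
  stages <- lapply(obj$stages, function(s)
    new("KMeansStage", name = s$name,
        features = unlist(s$features),
        cJ = as.numeric(unlist(s$cJ)), cM = as.numeric(unlist(s$cM)),
        nJ = as.numeric(s$nJ), nM = as.numeric(s$nM),
        wJM = as.numeric(s$wJM)))
  new("AureaModel", stages = stages, cfg = cfg,
      fs = as.numeric(obj$fs), seed = as.integer(obj$seed))
}
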