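#' @useDynLib aurea, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats kmeans quantile rnorm runif density median sd
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' Breathing-pattern vocabulary
#'
#' The closed label vocabulary used throughout the package: respiratory pause
#' (PAU), movement artifact (MVT), synchronous breathing (SYB), asynchronous
#' breathing (ASB), unknown (UNK), sigh (SIH, reference scorings only), and
#' the merged category UNKNOWN (= MVT + UNK + SIH).
#'
#' @format Character vectors.
#' @export
PATTERN_LEVELS <- c("PAU", "MVT", "SYB", "ASB", "UNK", "SIH", "UNKNOWN")

#' @rdname PATTERN_LEVELS
#' @export
MERGED_LEVELS <- c("PAU", "SYB", "ASB", "UNKNOWN")

#' RIPRecord: a two-channel respiratory inductance plethysmography record
#'
#' Holds aligned ribcage (RCG) and abdomen (ABD) belt signals sampled at a
#' common fixed rate.  RIP is uncalibrated, so amplitudes are in arbitrary
#' units; every downstream metric is scale-invariant.
#'
#' @slot rcg numeric, ribcage excursion signal.
#' @slot abd numeric, abdomen excursion signal (same length as `rcg`).
#' @slot fs numeric(1), sampling rate in Hz.
#' @export
setClass("RIPRecord",
  representation(rcg = "numeric", abd = "numeric", fs = "numeric"))

setValidity("RIPRecord", function(object) {
  msg <- character()
  if (length(object@rcg) != length(object@abd))
    msg <- c(msg, "rcg and abd must have identical length")
  if (length(object@rcg) < 1L)
    msg <- c(msg, "record must contain at least one sample")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyNA(object@rcg) || any(!is.finite(object@rcg)))
    msg <- c(msg, "rcg contains non-finite samples")
  if (anyNA(object@abd) || any(!is.finite(object@abd)))
    msg <- c(msg, "abd contains non-finite samples")
  if (length(msg)) msg else TRUE
})

#' Construct a RIPRecord
#'
#' @param rcg,abd numeric vectors of equal length (ribcage, abdomen).
#' @param fs sampling rate in Hz.
#' @return A [RIPRecord-class] object.
#' @examples
#' rec <- RIPRecord(sin(2 * pi * 0.7 * (0:499) / 50),
#'                  sin(2 * pi * 0.7 * (0:499) / 50), fs = 50)
#' nSamples(rec)
#' @export
RIPRecord <- function(rcg, abd, fs) {
  new("RIPRecord", rcg = as.numeric(rcg), abd = as.numeric(abd),
      fs = as.numeric(fs))
}

#' AnalysisConfig: analysis-window configuration for the AUREA metrics
#'
#' All widths are in seconds unless noted; centred windows are converted to
#' the nearest odd sample count so the half-width (N-1)/2 is integral.
#'
#' @slot nLF preprocessing detrend window (s).
#' @slot nQV trailing window for the variance-normalising quantile (s).
#' @slot nV variance estimation window (s).
#' @slot nDTPauMvt detrend window for the PAU/MVT metric chains (s).
#' @slot nDTSybAsb detrend window for the SYB/ASB metric chain (s).
#' @slot nMA moving-average notch filter window (s).
#' @slot nQRMS trailing window for the RMS-normalising quantile (s).
#' @slot nRMS RMS estimation window (s).
#' @slot nSMO smoothing window before binarisation (s).
#' @slot nB power estimation window for the SUM/DIF signals (s).
#' @slot nBPhase phase moving-average window, in samples.
#' @slot qVar quantile used to normalise the variance, in (0,1).
#' @slot qRMS quantile used to normalise the RMS, in (0,1).
#' @slot hpCutoff high-pass cutoff applied to SUM/DIF (Hz).
#' @export
setClass("AnalysisConfig",
  representation(nLF = "numeric", nQV = "numeric", nV = "numeric",
                 nDTPauMvt = "numeric", nDTSybAsb = "numeric",
                 nMA = "numeric", nQRMS = "numeric", nRMS = "numeric",
                 nSMO = "numeric", nB = "numeric", nBPhase = "numeric",
                 qVar = "numeric", qRMS = "numeric", hpCutoff = "numeric"))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  widths <- c(nLF = object@nLF, nQV = object@nQV, nV = object@nV,
              nDTPauMvt = object@nDTPauMvt, nDTSybAsb = object@nDTSybAsb,
              nMA = object@nMA, nQRMS = object@nQRMS, nRMS = object@nRMS,
              nSMO = object@nSMO, nB = object@nB, nBPhase = object@nBPhase)
  if (any(!is.finite(widths)) || any(widths <= 0))
    msg <- c(msg, "all window widths must be positive and finite")
  for (q in c(object@qVar, object@qRMS))
    if (!is.finite(q) || q <= 0 || q >= 1)
      msg <- c(msg, "quantiles must lie strictly in (0, 1)")
  if (!is.finite(object@hpCutoff) || object@hpCutoff <= 0)
    msg <- c(msg, "hpCutoff must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#'
#' Defaults are the window widths of the published AUREA configuration at
#' 50 Hz: 5 s detrending, 1 s variance / 120 s quantile windows (PAU chain),
#' a 1.42 s moving-average notch (first null at ~0.7 Hz for fs = 50 Hz) with
#' 5 s RMS / 600 s quantile windows (MVT chain), and 0.42 s smoothing with
#' 2 s power windows and a 101-sample phase window (SYB/ASB chain).
#'
#' @param nLF,nQV,nV,nDTPauMvt,nDTSybAsb,nMA,nQRMS,nRMS,nSMO,nB window widths
#'   in seconds (see [AnalysisConfig-class]).
#' @param nBPhase phase moving-average window, in samples.
#' @param qVar,qRMS normalising quantiles in (0,1).
#' @param hpCutoff high-pass cutoff in Hz for the SUM/DIF signals.
#' @return An [AnalysisConfig-class] object.
#' @export
analysisConfig <- function(nLF = 5, nQV = 120, nV = 1, nDTPauMvt = 5,
                           nDTSybAsb = 2, nMA = 1.42, nQRMS = 600, nRMS = 5,
                           nSMO = 0.42, nB = 2, nBPhase = 101,
                           qVar = 0.5, qRMS = 0.5, hpCutoff = 0.5) {
  new("AnalysisConfig", nLF = nLF, nQV = nQV, nV = nV,
      nDTPauMvt = nDTPauMvt, nDTSybAsb = nDTSybAsb, nMA = nMA,
      nQRMS = nQRMS, nRMS = nRMS, nSMO = nSMO, nB = nB, nBPhase = nBPhase,
      qVar = qVar, qRMS = qRMS, hpCutoff = hpCutoff)
}

#' MetricSet: per-sample AUREA metrics aligned to a record
#'
#' Six classifier metrics (normalized variance and nonperiodic power per
#' channel, synchronous power b+, asynchronous power b-) plus the descriptive
#' respiratory frequency and thoracoabdominal phase, all index-aligned with
#' the source record.
#'
#' @slot nvRcg,nvAbd log normalized variance (dimensionless).
#' @slot nppRcg,nppAbd log normalized nonperiodic power (dimensionless).
#' @slot bPlus,bMinus synchronous / asynchronous breathing power (>= 0).
#' @slot fResp instantaneous respiratory frequency (Hz; NaN where undefined).
#' @slot phi fraction of thoracoabdominal asynchrony in [0,1] (x180 = degrees).
#' @slot validMask logical, TRUE where every analysis window (including the
#'   longest trailing normalisation window) is fully supported.
#' @slot fs sampling rate in Hz of the source record.
#' @export
setClass("MetricSet",
  representation(nvRcg = "numeric", nvAbd = "numeric",
                 nppRcg = "numeric", nppAbd = "numeric",
                 bPlus = "numeric", bMinus = "numeric",
                 fResp = "numeric", phi = "numeric",
                 validMask = "logical", fs = "numeric"))

setValidity("MetricSet", function(object) {
  n <- length(object@nvRcg)
  lens <- c(length(object@nvAbd), length(object@nppRcg),
            length(object@nppAbd), length(object@bPlus),
            length(object@bMinus), length(object@fResp),
            length(object@phi), length(object@validMask))
  msg <- character()
  if (any(lens != n))
    msg <- c(msg, "all metric series must have identical length")
  if (any(object@bPlus < 0, na.rm = TRUE) ||
      any(object@bMinus < 0, na.rm = TRUE))
    msg <- c(msg, "b+ and b- must be non-negative")
  ph <- object@phi[is.finite(object@phi)]
  if (length(ph) && (min(ph) < 0 || max(ph) > 1))
    msg <- c(msg, "phi must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' KMeansStage: one trained binary detector of the cascade
#'
#' A two-cluster k-means split of one or two metrics, with the decision
#' hyperplane re-anchored by the unbalanced-data boundary weighting factor
#' w = n_target / (n_target + n_anti).
#'
#' @slot name pattern the stage detects ("PAU", "MVT", "SYB" or "ASB").
#' @slot features metric names the stage consumes, in order.
#' @slot cJ target-class centroid.
#' @slot cM anti-class centroid.
#' @slot nJ,nM training sample counts of the target / anti cluster.
#' @slot wJM boundary weighting factor in (0, 1); 0.5 is the conventional
#'   midpoint.
#' @export
setClass("KMeansStage",
  representation(name = "character", features = "character",
                 cJ = "numeric", cM = "numeric",
                 nJ = "numeric", nM = "numeric", wJM = "numeric"))

setValidity("KMeansStage", function(object) {
  msg <- character()
  if (length(object@cJ) != length(object@features) ||
      length(object@cM) != length(object@features))
    msg <- c(msg, "centroid dimensionality must match the feature list")
  if (isTRUE(all(object@cJ == object@cM)))
    msg <- c(msg, "degenerate stage: target and anti centroids coincide")
  if (length(object@wJM) != 1L || !is.finite(object@wJM) ||
      object@wJM <= 0 || object@wJM >= 1)
    msg <- c(msg, "wJM must lie strictly in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' AureaModel: the frozen four-stage cascade
#'
#' @slot stages list of [KMeansStage-class] in fixed order PAU, MVT, SYB, ASB.
#' @slot cfg the [AnalysisConfig-class] used when the training metrics were
#'   computed.
#' @slot fs sampling rate (Hz) of the training records.
#' @slot seed integer seed used for k-means initialisation.
#' @export
setClass("AureaModel",
  representation(stages = "list", cfg = "AnalysisConfig",
                 fs = "numeric", seed = "integer"))

setValidity("AureaModel", function(object) {
  msg <- character()
  nms <- vapply(object@stages, function(s) s@name, character(1))
  if (!identical(nms, c("PAU", "MVT", "SYB", "ASB")))
    msg <- c(msg, "stage order must be PAU, MVT, SYB, ASB")
  if (length(msg)) msg else TRUE
})

#' PatternSequence: one categorical breathing-pattern label per sample
#'
#' @slot labels character vector over the closed vocabulary
#'   ([PATTERN_LEVELS]).
#' @export
setClass("PatternSequence", representation(labels = "character"))

setValidity("PatternSequence", function(object) {
  bad <- !(object@labels %in% PATTERN_LEVELS)
  if (any(bad)) {
    sprintf("unknown pattern label(s): %s",
            paste(unique(object@labels[bad]), collapse = ", "))
  } else if (length(object@labels) < 1L) {
    "pattern sequence must contain at least one sample"
  } else TRUE
})

#' Construct a PatternSequence
#'
#' @param labels character (or factor) vector of pattern labels.
#' @return A [PatternSequence-class].
#' @export
PatternSequence <- function(labels) {
  new("PatternSequence", labels = as.character(labels))
}

#' RespConfusion: a K x K sample-count confusion matrix
#'
#' Rows are the reference (ground-truth) pattern, columns the predicted
#' pattern; entry (i, j) counts samples with reference pattern i that the
#' classifier assigned to pattern j.
#'
#' @slot counts integer-valued matrix of sample counts.
#' @slot labels ordered pattern labels (rows and columns).
#' @export
setClass("RespConfusion",
  representation(counts = "matrix", labels = "character"))

setValidity("RespConfusion", function(object) {
  msg <- character()
  k <- length(object@labels)
  if (!all(dim(object@counts) == c(k, k)))
    msg <- c(msg, "counts must be a K x K matrix matching labels")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' PatternSpec: one synthetic-segment specification
#'
#' @slot label pattern the segment represents.
#' @slot durationS segment duration in seconds.
#' @slot breathFreqHz breathing frequency in Hz (breathing-type segments).
#' @slot phaseDeg thoracoabdominal phase in degrees, abdomen lagging ribcage.
#' @slot amplitude breathing amplitude, arbitrary RIP units.
#' @slot noiseSd additive sensor-noise SD relative to unit amplitude.
#' @export
setClass("PatternSpec",
  representation(label = "character", durationS = "numeric",
                 breathFreqHz = "numeric", phaseDeg = "numeric",
                 amplitude = "numeric", noiseSd = "numeric"))

setValidity("PatternSpec", function(object) {
  msg <- character()
  if (!object@label %in% c("SYB", "ASB", "PAU", "MVT", "SIH", "UNK"))
    msg <- c(msg, sprintf("unsupported segment label '%s'", object@label))
  if (object@durationS <= 0) msg <- c(msg, "duration must be positive")
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@phaseDeg < 0 || object@phaseDeg > 180)
    msg <- c(msg, "phase must lie in [0, 180] degrees")
  if (length(msg)) msg else TRUE
})

#' Construct a PatternSpec
#'
#' @param label one of SYB, ASB, PAU, MVT, SIH, UNK.
#' @param durationS duration in seconds.
#' @param breathFreqHz breathing frequency (Hz); defaults follow the pattern
#'   (SYB 0.76, ASB 0.71).
#' @param phaseDeg abdomen-lag phase in degrees (SYB default 4, ASB 100).
#' @param amplitude relative amplitude (default 1).
#' @param noiseSd sensor noise SD relative to unit amplitude (default 0.05).
#' @return A [PatternSpec-class].
#' @export
patternSpec <- function(label, durationS,
                        breathFreqHz = switch(label, ASB = 0.71, 0.76),
                        phaseDeg = switch(label, ASB = 100, 4),
                        amplitude = 1, noiseSd = 0.05) {
  new("PatternSpec", label = label, durationS = durationS,
      breathFreqHz = breathFreqHz, phaseDeg = phaseDeg,
      amplitude = amplitude, noiseSd = noiseSd)
}

#' SyntheticRecord: a simulated record with ground-truth labels
#'
#' @slot record the simulated [RIPRecord-class].
#' @slot truth the ground-truth [PatternSequence-class].
#' @slot specs list of the [PatternSpec-class] segments realised, in order.
#' @slot seed integer seed that generated the record.
#' @export
setClass("SyntheticRecord",
  representation(record = "RIPRecord", truth = "PatternSequence",
                 specs = "list", seed = "integer"))

setValidity("SyntheticRecord", function(object) {
  if (length(object@truth@labels) != length(object@record@rcg))
    "truth must have one label per record sample" else TRUE
})
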