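# The AUREA per-sample metrics.
#
# Two metric chains run off the same raw channels:
#   PAU/MVT chain  — 5 s detrend -> normalized variance (1 s window,
#                    120 s trailing median) and nonperiodic power (1.42 s
#                    notch, 5 s RMS, 600 s trailing median);
#   SYB/ASB chain  — 2 s detrend -> 0.42 s smoothing -> binarisation ->
#                    SUM/DIF power after a 0.5 Hz zero-phase high-pass,
#                    plus zero-crossing frequency and XOR phase.
# Log-ratio denominators are floored at .EPS_POWER (squared-signal units) so
# an all-zero calibration stretch yields a finite, strongly negative metric
# instead of -Inf.

.EPS_POWER <- 1e-12

#' Preprocess a raw RIP channel
#'
#' Removes the mean and low-frequency components by subtracting a centred
#' moving average: `ripLf` is the local baseline, `rip = raw - ripLf` the
#' detrended signal.
#'
#' @param raw numeric vector of raw belt samples, all finite.
#' @param fs sampling rate in Hz.
#' @param windowS detrend window width in seconds.
#' @return list with components `rip` and `ripLf`, both the length of `raw`.
#' @export
preprocessRip <- function(raw, fs, windowS) {
  if (anyNA(raw) || any(!is.finite(raw)))
    aureaValidationError("raw signal contains non-finite samples")
  w <- secondsToOddSamples(windowS, fs)
  ripLf <- runMeanCentered(raw, w)
  list(rip = raw - ripLf, ripLf = ripLf)
}

#' Log normalized variance metric
#'
#' Instantaneous variance (windowed mean square of the detrended signal)
#' normalized by its trailing quantile and log-transformed:
#' `NV(n) = ln(V(n) / Vq(n))` with `Vq` the `qVar`-quantile of the most
#' recent `nQV` seconds of `V`.  Very low values are discriminatory for the
#' respiratory pause pattern, mirroring the AASM amplitude rule for
#' pediatric apnea (excursions below 10% of the preceding baseline).
#'
#' @param rip detrended signal from [preprocessRip()].
#' @param fs sampling rate in Hz.
#' @param cfg an [AnalysisConfig-class].
#' @return numeric vector of NV values, same length as `rip`.
#' @export
normalizedVariance <- function(rip, fs, cfg = analysisConfig()) {
  plan <- windowPlan(cfg, fs)
  v <- runMeanSquareCentered(rip, plan$v)
  vq <- rollQuantileTrailing(v, plan$qv, cfg@qVar)
  log(pmax(v, .EPS_POWER) / pmax(vq, .EPS_POWER))
}

#' Log normalized nonperiodic power metric
#'
#' The detrended signal is passed through the moving-average notch (nulls at
#' fs/N_MA and harmonics, i.e. on the respiratory fundamental), its RMS is
#' estimated over a centred window, and the result is normalized by the
#' trailing `qRMS`-quantile and log-transformed.  Elevated values mark
#' movement: broadband low-frequency power that survives the notch.
#'
#' @inheritParams normalizedVariance
#' @return numeric vector of npp values, same length as `rip`.
#' @export
nonperiodicPower <- function(rip, fs, cfg = analysisConfig()) {
  plan <- windowPlan(cfg, fs)
  ripMa <- runMeanCentered(rip, plan$ma)
  rms <- sqrt(runMeanSquareCentered(ripMa, plan$rms))
  rmsq <- rollQuantileTrailing(rms, plan$qrms, cfg@qRMS)
  eps <- sqrt(.EPS_POWER)
  log(pmax(rms, eps) / pmax(rmsq, eps))
}

#' Smooth a detrended channel and convert it to binary
#'
#' The detrended signal is smoothed with a short centred mean to reject
#' additive sensor noise, then thresholded at its local baseline: since the
#' signal is already detrended, the baseline is zero and
#' `ripB = 1` iff the smoothed signal is strictly positive.
#'
#' @inheritParams normalizedVariance
#' @return integer vector of 0/1, same length as `rip`.
#' @export
smoothAndBinarize <- function(rip, fs, cfg = analysisConfig()) {
  plan <- windowPlan(cfg, fs)
  smo <- runMeanCentered(rip, plan$smo)
  as.integer(smo > 0)
}

.checkBinary <- function(x, what) {
  if (!all(x %in% c(0L, 1L)))
    aureaValidationError("%s must be a binary (0/1) series", what)
}

#' Synchronous and asynchronous breathing power metrics
#'
#' From the binary channels, `SUM = (RCG_B + ABD_B)/2` and
#' `DIF = (RCG_B - ABD_B)/2`.  In-phase breathing makes SUM oscillate
#' between 0 and 1 at the respiratory frequency while DIF stays at 0;
#' paradoxical breathing does the reverse.  Both are high-pass filtered at
#' `hpCutoff` (zero phase) to remove the sub-0.5 Hz power associated with
#' pause and movement, and the windowed power of each filtered signal gives
#' `b+` (synchrony) and `b-` (asynchrony).
#'
#' @param rcgB,abdB binary (0/1) channel series of equal length.
#' @param fs sampling rate in Hz.
#' @param cfg an [AnalysisConfig-class].
#' @return list with non-negative components `bPlus` and `bMinus`.
#' @export
sybAsbMetrics <- function(rcgB, abdB, fs, cfg = analysisConfig()) {
  .checkBinary(rcgB, "rcgB"); .checkBinary(abdB, "abdB")
  if (length(rcgB) != length(abdB))
    aureaValidationError("binary channels must have equal length")
  plan <- windowPlan(cfg, fs)
  sum_ <- (rcgB + abdB) / 2
  dif <- (rcgB - abdB) / 2
  sumHp <- highpassZeroPhase(sum_, cfg@hpCutoff, fs)
  difHp <- highpassZeroPhase(dif, cfg@hpCutoff, fs)
  list(bPlus = runMeanSquareCentered(sumHp, plan$b),
       bMinus = runMeanSquareCentered(difHp, plan$b))
}

#' Instantaneous respiratory frequency from binary transitions
#'
#' Approximate frequency demodulation from zero crossings: consecutive
#' transitions of the binary signal delimit half-periods, and every sample
#' between transitions k and k+1 receives `f = 1 / (2 * dt)` with `dt` the
#' elapsed time between them.  Samples before the first (after the last)
#' transition carry the first (last) defined value; a series with fewer than
#' two transitions is undefined (NaN) everywhere.
#'
#' @param ripB binary (0/1) series from [smoothAndBinarize()].
#' @param fs sampling rate in Hz.
#' @return numeric vector of frequencies in Hz (NaN where undefined).
#' @export
respiratoryFrequency <- function(ripB, fs) {
  .checkBinary(ripB, "ripB")
  n <- length(ripB)
  tr <- which(diff(ripB) != 0) + 1L   # first sample of each new level
  if (length(tr) < 2L) return(rep(NaN, n))
  halfPeriods <- diff(tr) / fs
  fVals <- 1 / (2 * halfPeriods)
  # sample n in [tr[k], tr[k+1]-1] gets fVals[k]; edges take nearest value
  k <- findInterval(seq_len(n), tr)
  k[k < 1L] <- 1L
  k[k > length(fVals)] <- length(fVals)
  fVals[k]
}

#' Thoracoabdominal phase metric
#'
#' The XOR of the two binary channels marks samples where the belts disagree;
#' its centred moving average over `nBPhase` samples estimates the fraction
#' of asynchrony, a value in [0, 1] mapping linearly to [0, 180] degrees.
#'
#' @inheritParams sybAsbMetrics
#' @return numeric vector in [0, 1], same length as the inputs.
#' @export
phaseMetric <- function(rcgB, abdB, cfg = analysisConfig()) {
  .checkBinary(rcgB, "rcgB"); .checkBinary(abdB, "abdB")
  if (length(rcgB) != length(abdB))
    aureaValidationError("binary channels must have equal length")
  w <- as.integer(cfg@nBPhase)
  if (w %% 2 == 0) w <- w + 1L
  phiB <- as.integer(xor(rcgB == 1L, abdB == 1L))
  runMeanCentered(phiB, w)
}

#' @describeIn computeMetrics Compute all metrics from a two-channel record.
#'   The PAU/MVT chains use the 5 s detrend window, the SYB/ASB chain the
#'   2 s window; frequency and phase derive from the SYB/ASB-chain binaries
#'   (frequency from the abdomen channel).
setMethod("computeMetrics", "RIPRecord", function(record, cfg) {
  validObject(record); validObject(cfg)
  fs <- record@fs
  plan <- windowPlan(cfg, fs)
  n <- length(record@rcg)

  ppPau <- list(rcg = preprocessRip(record@rcg, fs, cfg@nDTPauMvt),
                abd = preprocessRip(record@abd, fs, cfg@nDTPauMvt))
  ppSyb <- list(rcg = preprocessRip(record@rcg, fs, cfg@nDTSybAsb),
                abd = preprocessRip(record@abd, fs, cfg@nDTSybAsb))

  nvRcg <- normalizedVariance(ppPau$rcg$rip, fs, cfg)
  nvAbd <- normalizedVariance(ppPau$abd$rip, fs, cfg)
  nppRcg <- nonperiodicPower(ppPau$rcg$rip, fs, cfg)
  nppAbd <- nonperiodicPower(ppPau$abd$rip, fs, cfg)

  rcgB <- smoothAndBinarize(ppSyb$rcg$rip, fs, cfg)
  abdB <- smoothAndBinarize(ppSyb$abd$rip, fs, cfg)
  b <- sybAsbMetrics(rcgB, abdB, fs, cfg)
  fResp <- respiratoryFrequency(abdB, fs)
  phi <- phaseMetric(rcgB, abdB, cfg)

  # valid where the longest trailing window is complete and all centred
  # windows fit without edge shrink
  hMax <- max((plan$lf - 1L) / 2L, (plan$rms - 1L) / 2L,
              (plan$b - 1L) / 2L, (plan$bPhase - 1L) / 2L)
  idx <- seq_len(n)
  valid <- idx >= max(plan$qrms, plan$qv, hMax + 1L) & idx <= n - hMax

  new("MetricSet", nvRcg = nvRcg, nvAbd = nvAbd,
      nppRcg = nppRcg, nppAbd = nppAbd,
      bPlus = b$bPlus, bMinus = b$bMinus,
      fResp = fResp, phi = phi, validMask = valid, fs = fs)
})
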