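# Sliding-window primitives.
#
# Centred windows shrink symmetrically at the record edges (the effective
# half-width at sample n of an N-sample series is min(h, n-1, N-n)), so every
# output is the mean over a window that remains centred on n.  Trailing
# windows expand from the start of the record.  Both conventions keep output
# length equal to input length, which the sample-wise pattern-sequence
# contract requires.

#' Convert a window width in seconds to an odd sample count
#'
#' Centred windows need an integral half-width (N-1)/2, so the width is
#' rounded to the nearest sample count and bumped up to the next odd integer
#' when even.
#'
#' @param widthS window width in seconds.
#' @param fs sampling rate in Hz.
#' @return odd integer sample count, >= 1.
#' @examples
#' secondsToOddSamples(1.42, 50)  # 71
#' @export
secondsToOddSamples <- function(widthS, fs) {
  n <- round(widthS * fs)
  if (n %% 2 == 0) n <- n + 1
  max(1L, as.integer(n))
}

# samples for a trailing window (no odd constraint)
secondsToSamples <- function(widthS, fs) max(1L, as.integer(round(widthS * fs)))

#' Centred running mean with symmetric edge shrink
#'
#' @param x numeric vector.
#' @param width odd integer window width in samples.
#' @return numeric vector, same length as `x`.
#' @export
runMeanCentered <- function(x, width) {
  n <- length(x)
  if (width %% 2 == 0)
    aureaValidationError("centered window width must be odd (got %d)", width)
  if (width > n)
    aureaValidationError(
      "series of %d samples is shorter than one %d-sample window", n, width)
  h <- (width - 1L) / 2L
  hEff <- pmin(h, seq_len(n) - 1L, n - seq_len(n))
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  (cs[idx + hEff + 1L] - cs[idx - hEff]) / (2 * hEff + 1)
}

#' Centred running mean square with symmetric edge shrink
#'
#' @inheritParams runMeanCentered
#' @return numeric vector of windowed mean squares.
#' @export
runMeanSquareCentered <- function(x, width) runMeanCentered(x * x, width)

#' Trailing rolling quantile
#'
#' At sample n, the quantile (type 7) of the most recent `width` samples,
#' current sample included; the window expands while fewer than `width`
#' samples are available.
#'
#' @param x numeric vector, all finite.
#' @param width trailing window width in samples.
#' @param q quantile in (0, 1).
#' @return numeric vector, same length as `x`.
#' @export
rollQuantileTrailing <- function(x, width, q) {
  .roll_quantile_trailing(as.numeric(x), as.integer(width), as.numeric(q))
}

# Resolved per-record window plan: every cfg width in samples, with the
# invariants that only make sense after conversion checked here.
windowPlan <- function(cfg, fs) {
  plan <- list(
    lf    = secondsToOddSamples(cfg@nLF, fs),
    qv    = secondsToSamples(cfg@nQV, fs),
    v     = secondsToOddSamples(cfg@nV, fs),
    dtPau = secondsToOddSamples(cfg@nDTPauMvt, fs),
    dtSyb = secondsToOddSamples(cfg@nDTSybAsb, fs),
    ma    = secondsToOddSamples(cfg@nMA, fs),
    qrms  = secondsToSamples(cfg@nQRMS, fs),
    rms   = secondsToOddSamples(cfg@nRMS, fs),
    smo   = secondsToOddSamples(cfg@nSMO, fs),
    b     = secondsToOddSamples(cfg@nB, fs),
    bPhase = {
      w <- as.integer(cfg@nBPhase)          # already samples
      if (w %% 2 == 0) w + 1L else w
    })
  if (plan$smo >= plan$dtSyb)
    aureaValidationError("smoothing window (%d) must be narrower than the SYB/ASB detrend window (%d)",
                         plan$smo, plan$dtSyb)
  if (plan$v >= plan$lf)
    aureaValidationError("variance window (%d) must be narrower than the detrend window (%d)",
                         plan$v, plan$lf)
  if (plan$rms >= plan$qrms)
    aureaValidationError("RMS window (%d) must be narrower than its quantile window (%d)",
                         plan$rms, plan$qrms)
  plan
}
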