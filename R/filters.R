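# Frequency-domain helpers: the moving-average notch response and the
# zero-phase high-pass used on the SUM/DIF signals.

#' Magnitude response of the centred moving-average filter
#'
#' The N-sample moving average is a comb filter with deep nulls at integer
#' multiples of fs/N; the notch window is chosen so that its first null sits
#' on the modal respiratory frequency (1.42 s at 50 Hz gives 50/71 ~ 0.70 Hz),
#' removing the breathing fundamental and harmonics while passing the
#' lower-frequency movement band.
#'
#' @param f frequency (Hz), scalar or vector.
#' @param width window width in samples.
#' @param fs sampling rate in Hz.
#' @return |H(f)| relative to unit DC gain.
#' @export
maFilterResponse <- function(f, width, fs) {
  x <- pi * f / fs
  num <- sin(width * x)
  den <- width * sin(x)
  r <- ifelse(abs(den) < 1e-300, 1, abs(num / den))
  r[f == 0] <- 1
  r
}

#' First spectral null of the moving-average notch
#'
#' @param widthS window width in seconds (converted to the nearest odd sample
#'   count, as used by the filter itself).
#' @param fs sampling rate in Hz.
#' @return frequency of the first null, Hz ( = fs / N).
#' @examples
#' maFirstNull(1.42, 50)  # ~0.704 Hz
#' @export
maFirstNull <- function(widthS, fs) {
  fs / secondsToOddSamples(widthS, fs)
}

# Linear-phase FIR high-pass taps (Hamming window via signal::fir1).  The
# design cutoff sits slightly below the nominal -3 dB point because the
# window method puts -6 dB at the specified edge; taps are cached per
# (cutoff, fs) since the design is deterministic.
.hpCache <- new.env(parent = emptyenv())

highpassTaps <- function(cutoffHz, fs) {
  key <- sprintf("%g@%g", cutoffHz, fs)
  if (!is.null(.hpCache[[key]])) return(.hpCache[[key]])
  # transition band ~0.4*cutoff wide; odd tap count for exact zero phase
  ntaps <- as.integer(round(3.3 * fs / (0.4 * cutoffHz)))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1L
  wc <- (cutoffHz * 0.995) / (fs / 2)  # shift so |H| ~ -3 dB at cutoffHz
  taps <- signal::fir1(ntaps - 1L, wc, type = "high")
  .hpCache[[key]] <- as.numeric(taps)
  .hpCache[[key]]
}

#' Zero-phase high-pass filter
#'
#' A single pass of an odd-length linear-phase FIR applied as a centred
#' convolution: symmetric taps make the phase exactly zero without
#' forward-backward filtering, preserving temporal alignment with the
#' sample-wise pattern sequence.  Edges are handled by even reflection.
#'
#' @param x numeric vector.
#' @param cutoffHz nominal -3 dB cutoff in Hz.
#' @param fs sampling rate in Hz.
#' @return filtered vector, same length as `x`.
#' @export
highpassZeroPhase <- function(x, cutoffHz, fs) {
  taps <- highpassTaps(cutoffHz, fs)
  h <- (length(taps) - 1L) %/% 2L
  n <- length(x)
  xx <- x[reflectIndex((1L - h):(n + h), n)]
  y <- stats::filter(xx, taps, method = "convolution", sides = 2)
  as.numeric(y[(h + 1L):(h + n)])
}

# map any integer index onto 1..n by even (mirror) reflection at both ends
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  ifelse(j < n, j + 1L, p - j + 1L)
}
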