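# Synthetic dual-belt RIP simulator with ground-truth labels.
#
# Emulates the statistical structure the classifier assumes: quasi-sinusoidal
# breathing with slow amplitude/frequency jitter and a fixed inter-belt phase
# (SYB ~4 deg, ASB ~100 deg), near-silent pauses bounded at 10% of the
# preceding breathing amplitude, band-limited (<0.5 Hz) high-amplitude
# stochastic movement, sighs as a single large breath on a synchronous
# baseline, and an UNK-like filler of irregular low-amplitude breathing with
# drifting phase.  Amplitudes are arbitrary units (RIP is uncalibrated); the
# classifier must be scale-invariant, and the property suite checks that it
# is.  All randomness flows through the caller's seed; no global state is
# left behind.

# bounded random walk, reflected at +/- clip
.randomWalk <- function(n, step, clip) {
  w <- cumsum(rnorm(n, 0, step))
  # reflect into [-clip, clip]
  p <- 4 * clip
  w <- (w + clip) %% p
  w <- ifelse(w > 2 * clip, p - w, w)
  w - clip
}

.breathingPair <- function(n, fs, f0, phaseRad, amp, freqClip = 0.03,
                           ampClip = 0.2, theta0 = 0) {
  f <- f0 * (1 + .randomWalk(n, 0.002, freqClip))
  a <- amp * (1 + .randomWalk(n, 0.003, ampClip))
  theta <- theta0 + 2 * pi * cumsum(f) / fs
  list(rcg = a * sin(theta), abd = a * sin(theta - phaseRad),
       thetaEnd = theta[n])
}

.bandlimitedNoise <- function(n, fs) {
  w <- secondsToOddSamples(2.5, fs)   # first null ~0.4 Hz at 50 Hz
  pad <- w
  x <- rnorm(n + 2 * pad)
  x <- runMeanCentered(runMeanCentered(x, w), w)
  x[(pad + 1):(pad + n)]
}

#' Generate one labeled synthetic segment
#'
#' @param spec a [PatternSpec-class].
#' @param fs sampling rate in Hz.
#' @param state generator state carried across segments: a list with
#'   `lastBreathAmp` (reference amplitude for pauses and movement) and
#'   `theta` (breathing phase, for continuity).  Omit for a standalone
#'   segment.
#' @param seed optional integer seed; when supplied the segment is generated
#'   under a local RNG scope, making the call deterministic.
#' @return list with numeric `rcg`, `abd`, character `labels` (all of length
#'   `round(durationS * fs)`), and the updated `state`.
#' @export
generateSegment <- function(spec, fs, state = list(lastBreathAmp = 1,
                                                   theta = 0),
                            seed = NULL) {
  validObject(spec)
  if (!is.null(seed))
    return(withLocalSeed(seed, generateSegment(spec, fs, state)))
  n <- max(1L, as.integer(round(spec@durationS * fs)))
  lab <- spec@label
  noise <- function() rnorm(n, 0, spec@noiseSd)
  out <- switch(lab,
    SYB = , ASB = {
      bp <- .breathingPair(n, fs, spec@breathFreqHz,
                           spec@phaseDeg * pi / 180, spec@amplitude,
                           theta0 = state$theta)
      state$theta <- bp$thetaEnd
      state$lastBreathAmp <- spec@amplitude
      list(rcg = bp$rcg + noise(), abd = bp$abd + noise())
    },
    SIH = {
      bp <- .breathingPair(n, fs, spec@breathFreqHz,
                           spec@phaseDeg * pi / 180, spec@amplitude,
                           theta0 = state$theta)
      state$theta <- bp$thetaEnd
      state$lastBreathAmp <- spec@amplitude
      # one breath at >= 2.5x amplitude, centred in the segment
      tc <- n / 2
      sigma <- 0.35 * fs / spec@breathFreqHz
      env <- 1 + 2.5 * exp(-((seq_len(n) - tc)^2) / (2 * sigma^2))
      list(rcg = bp$rcg * env + noise(), abd = bp$abd * env + noise())
    },
    PAU = {
      ref <- state$lastBreathAmp
      f <- if (is.finite(spec@breathFreqHz)) spec@breathFreqHz else 0.7
      theta <- 2 * pi * f * seq_len(n) / fs
      rcg <- 0.04 * ref * sin(theta) + rnorm(n, 0, spec@noiseSd * ref)
      abd <- 0.04 * ref * sin(theta) + rnorm(n, 0, spec@noiseSd * ref)
      # enforce the apnea amplitude rule: segment RMS <= 10% of the
      # preceding breathing RMS
      refRms <- ref / sqrt(2)
      capAt <- function(v) {
        r <- sqrt(mean(v^2))
        if (r > 0.1 * refRms) v * (0.095 * refRms / r) else v
      }
      list(rcg = capAt(rcg), abd = capAt(abd))
    },
    MVT = {
      ref <- state$lastBreathAmp
      common <- .bandlimitedNoise(n, fs)
      m1 <- 0.75 * common + 0.65 * .bandlimitedNoise(n, fs)
      m2 <- 0.75 * common + 0.65 * .bandlimitedNoise(n, fs)
      target <- 2.5 * ref / sqrt(2)   # movement RMS >= 2x breathing RMS
      sc <- function(v) v * target / max(sqrt(mean(v^2)), 1e-12)
      list(rcg = sc(m1) + noise(), abd = sc(m2) + noise())
    },
    UNK = {
      # irregular shallow breathing, slower than the scoreable band
      # (0.25-0.5 Hz) with drifting inter-belt phase: too slow for the
      # SYB/ASB detectors, too large for PAU, residual by construction
      ref <- state$lastBreathAmp
      amp <- 0.55 * ref
      f <- 0.375 + .randomWalk(n, 0.004, 0.125)      # 0.25..0.5 Hz drift
      phase <- pi / 2 + .randomWalk(n, 0.01, pi / 2) # drifts over 0..180 deg
      theta <- state$theta + 2 * pi * cumsum(f) / fs
      a <- amp * (1 + .randomWalk(n, 0.004, 0.4))
      state$theta <- theta[n]
      list(rcg = a * sin(theta) + noise(),
           abd = a * sin(theta - phase) + noise())
    },
    aureaValidationError("unsupported segment label '%s'", lab))
  list(rcg = out$rcg, abd = out$abd, labels = rep(lab, n), state = state)
}

#' Generate a labeled synthetic RIP record
#'
#' Concatenates segments with short raised-cosine cross-fades (0.1 s) at the
#' junctions to avoid discontinuity artifacts; cross-fade samples carry the
#' incoming segment's label.
#'
#' @param specs non-empty list of [PatternSpec-class] objects, in order.
#' @param fs sampling rate in Hz (default 50).
#' @param seed integer seed; the same seed reproduces the record exactly.
#' @return A [SyntheticRecord-class].
#' @export
generateRecord <- function(specs, fs = 50, seed = 1L) {
  if (length(specs) == 0L)
    aureaValidationError("specs must be a non-empty list")
  L <- as.integer(round(0.1 * fs))
  withLocalSeed(seed, {
    state <- list(lastBreathAmp = 1, theta = 0)
    rcg <- numeric(0); abd <- numeric(0); labels <- character(0)
    for (k in seq_along(specs)) {
      spec <- specs[[k]]
      if (k > 1L && L > 0L) {
        # generate L extra leading samples to overlap into the previous tail
        spec <- new("PatternSpec", label = spec@label,
                    durationS = spec@durationS + L / fs,
                    breathFreqHz = spec@breathFreqHz,
                    phaseDeg = spec@phaseDeg, amplitude = spec@amplitude,
                    noiseSd = spec@noiseSd)
      }
      seg <- generateSegment(spec, fs, state)
      state <- seg$state
      if (length(rcg) >= L && L > 0 && length(seg$rcg) > L) {
        w <- 0.5 * (1 - cos(pi * seq_len(L) / (L + 1)))  # 0 -> 1
        tail_ <- (length(rcg) - L + 1L):length(rcg)
        rcg[tail_] <- (1 - w) * rcg[tail_] + w * seg$rcg[seq_len(L)]
        abd[tail_] <- (1 - w) * abd[tail_] + w * seg$abd[seq_len(L)]
        labels[tail_] <- seg$labels[1L]
        rcg <- c(rcg, seg$rcg[-seq_len(L)])
        abd <- c(abd, seg$abd[-seq_len(L)])
        labels <- c(labels, seg$labels[-seq_len(L)])
      } else {
        rcg <- c(rcg, seg$rcg); abd <- c(abd, seg$abd)
        labels <- c(labels, seg$labels)
      }
    }
    new("SyntheticRecord",
        record = RIPRecord(rcg, abd, fs),
        truth = PatternSequence(labels),
        specs = specs, seed = as.integer(seed))
  })
}

#' Study-like scenario: the default segment mix
#'
#' Builds a list of segment specs whose label proportions mirror the
#' published distribution of infant breathing patterns (about 60% SYB,
#' 15% MVT, 11% UNK, 7% ASB, 5% PAU, 2% SIH), with every non-synchronous
#' segment preceded by a synchronous one so pauses always have a breathing
#' baseline.  Segment durations: SYB fills the gaps; ASB ~26 s, PAU ~8 s,
#' MVT ~15 s, UNK ~16 s, SIH ~4 s.
#'
#' Asynchronous-breathing phases are drawn per segment from a right-skewed
#' distribution with mode 100 degrees (100 + exponential with mean 15,
#' capped at 175), mirroring the skew of reported infant
#' thoracoabdominal-asynchrony distributions; synchronous segments sit at
#' 4 degrees.
#'
#' @param durationS total record duration in seconds (default 1500; long
#'   enough that the 600 s trailing normalisation window is fully supported
#'   for most of the record).
#' @param seed integer seed controlling segment ordering and phase draws.
#' @param mix named proportions over SYB, MVT, UNK, ASB, PAU, SIH.
#' @return list of [PatternSpec-class], suitable for [generateRecord()].
#' @export
studyScenario <- function(durationS = 1500, seed = 1L,
                          mix = c(SYB = 0.60, MVT = 0.15, UNK = 0.11,
                                  ASB = 0.07, PAU = 0.05, SIH = 0.02)) {
  mix <- mix / sum(mix)
  typ <- c(ASB = 15, PAU = 8, MVT = 15, UNK = 16, SIH = 4)
  withLocalSeed(seed, {
    nonSyb <- unlist(lapply(names(typ), function(p) {
      budget <- mix[[p]] * durationS
      k <- max(1L, as.integer(round(budget / typ[[p]])))
      lapply(seq_len(k), function(i) {
        if (p == "ASB")
          patternSpec(p, durationS = budget / k,
                      phaseDeg = min(175, 100 + stats::rexp(1, 1 / 15)))
        else patternSpec(p, durationS = budget / k)
      })
    }), recursive = FALSE)
    nonSyb <- nonSyb[sample.int(length(nonSyb))]
  })
  sybEach <- mix[["SYB"]] * durationS / (length(nonSyb) + 1L)
  specs <- list(patternSpec("SYB", durationS = sybEach))
  for (sp in nonSyb)
    specs <- c(specs, list(sp), list(patternSpec("SYB", durationS = sybEach)))
  specs
}
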