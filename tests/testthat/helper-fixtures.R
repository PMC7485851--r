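# Shared fixtures, computed once per test run.
#
# The "study" fixture is the generator's default scenario (1500 s at 50 Hz,
# seed 1) taken end to end: record -> metrics -> trained cascade ->
# prediction.  The "small" fixture is a 200 s scenario used where only the
# metric pipeline (not the 600 s normalisation warm-up) matters.

.fixtures <- new.env(parent = emptyenv())

studyFixture <- function() {
  if (is.null(.fixtures$study)) {
    specs <- studyScenario(durationS = 1500, seed = 1)
    syn <- generateRecord(specs, fs = 50, seed = 1)
    ms <- computeMetrics(syn@record)
    model <- trainAurea(ms, seed = 1)
    pred <- classify(ms, model)
    .fixtures$study <- list(syn = syn, ms = ms, model = model, pred = pred)
  }
  .fixtures$study
}

smallFixture <- function() {
  if (is.null(.fixtures$small)) {
    specs <- studyScenario(durationS = 200, seed = 3)
    syn <- generateRecord(specs, fs = 50, seed = 3)
    .fixtures$small <- list(syn = syn, ms = computeMetrics(syn@record))
  }
  .fixtures$small
}

# ideal 0/1 square wave at frequency f (Hz), duty 0.5, optional shift in
# fractions of a period
squareWave <- function(n, f, fs, shift = 0) {
  as.integer((((seq_len(n) - 1) / fs * f + shift) %% 1) < 0.5)
}

# brute-force centred mean with symmetric edge shrink (oracle)
bruteCenteredMean <- function(x, width) {
  n <- length(x); h <- (width - 1) / 2
  vapply(seq_len(n), function(i) {
    he <- min(h, i - 1, n - i)
    mean(x[(i - he):(i + he)])
  }, numeric(1))
}

# brute-force trailing quantile (oracle)
bruteTrailingQuantile <- function(x, width, q) {
  vapply(seq_along(x), function(i)
    unname(quantile(x[max(1, i - width + 1):i], q, type = 7)),
    numeric(1))
}
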