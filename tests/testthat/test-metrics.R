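cfg <- analysisConfig()
fs <- 50

test_that("preprocessing removes the mean and local trend", {
  # constant: baseline is the constant, residual zero
  pp <- preprocessRip(rep(3.7, 500), fs, 5)
  expect_equal(pp$rip, rep(0, 500), tolerance = 1e-12)
  expect_equal(pp$ripLf, rep(3.7, 500), tolerance = 1e-12)

  # linear ramp: a centred symmetric mean equals the centre value everywhere
  ramp <- 0.02 * (0:999)
  pp <- preprocessRip(ramp, fs, 5)
  expect_equal(pp$rip, rep(0, 1000), tolerance = 1e-9)

  # sinusoid: baseline equals direct convolution, residual attenuated by the
  # moving-average response at the sinusoid frequency
  x <- sin(2 * pi * 1 * (0:2499) / fs)
  pp <- preprocessRip(x, fs, 5)
  expect_equal(pp$ripLf, bruteCenteredMean(x, 251L), tolerance = 1e-9)
  interior <- 300:2200
  gain <- maFilterResponse(1, 251, fs)
  expect_lt(max(abs(pp$ripLf[interior])), gain * 1.01)
  expect_equal(pp$rip[interior], x[interior] - pp$ripLf[interior],
               tolerance = 1e-12)

  expect_error(preprocessRip(rnorm(100), fs, 5), "shorter")
  expect_error(preprocessRip(c(1, Inf, 3), fs, 0.02), "finite")
})

test_that("normalized variance centres on zero for stationary noise and is
           scale invariant", {
  set.seed(5)
  rip <- preprocessRip(rnorm(10000), fs, 5)$rip
  nv <- normalizedVariance(rip, fs, cfg)
  # with q = 0.5 the variance sits at its own running median -> NV ~ ln(1)
  expect_lt(abs(median(nv[6000:10000])), 0.1)
  # power-of-two scaling is exact in floating point, so the ratio metric is
  # reproduced bit for bit away from the epsilon floor
  nv2 <- normalizedVariance(32 * rip, fs, cfg)
  ok <- abs(nv) < 20 & abs(nv2) < 20
  expect_identical(nv2[ok], nv[ok])
})

test_that("normalized variance drops sharply in a silent stretch", {
  set.seed(6)
  breath <- function(n) sin(2 * pi * 0.7 * seq_len(n) / fs) +
    rnorm(n, 0, 0.03)
  x <- c(breath(3000), rnorm(500, 0, 0.03), breath(3000))
  nv <- normalizedVariance(preprocessRip(x, fs, 5)$rip, fs, cfg)
  inPause <- 3100:3400
  inBreath <- c(500:2900, 3700:6300)
  expect_lt(mean(nv[inPause]),
            mean(nv[inBreath]) - 2 * sd(nv[inBreath]))
})

test_that("the moving-average notch annihilates its null frequency", {
  w <- secondsToOddSamples(cfg@nMA, fs)          # 71 samples
  probe <- sin(2 * pi * (fs / w) * (0:4999) / fs)
  ma <- runMeanCentered(probe, w)
  expect_lt(max(abs(ma[500:4500])), 1e-6)        # < 1e-6 of unit DC gain
  # and the analytic response agrees
  expect_lt(maFilterResponse(fs / w, w, fs), 1e-9)
})

test_that("nonperiodic power stays finite on degenerate input", {
  npp <- nonperiodicPower(rep(0, 2000), fs, cfg)
  expect_true(all(is.finite(npp)))
  expect_equal(npp, rep(0, 2000))   # floor / floor -> ln(1)
})

test_that("binarisation yields a half-duty square wave from a sinusoid", {
  x <- sin(2 * pi * 0.7 * (0:4999) / fs)
  b <- smoothAndBinarize(x, fs, cfg)
  expect_true(all(b %in% c(0L, 1L)))
  expect_equal(mean(b), 0.5, tolerance = 0.02)
  transitions <- sum(diff(b) != 0)
  expect_equal(transitions / (5000 / fs), 2 * 0.7, tolerance = 0.05)
  expect_equal(smoothAndBinarize(rep(0, 1000), fs, cfg), rep(0L, 1000))
})

test_that("noise barely inflates the binary transition rate after smoothing", {
  set.seed(8)
  clean <- sin(2 * pi * 0.7 * (0:9999) / fs)
  noisy <- clean + rnorm(10000, 0, 0.1)
  rate <- function(x) sum(diff(smoothAndBinarize(x, fs, cfg)) != 0)
  expect_lt(abs(rate(noisy) - rate(clean)) / rate(clean), 0.2)
})

test_that("b+/b- behave at the synchronous, paradoxical and quarter-phase
           limits", {
  n <- 6000
  a <- squareWave(n, 0.7, fs)
  # identical in-phase: DIF identically zero -> b- = 0, b+ positive
  b <- sybAsbMetrics(a, a, fs, cfg)
  expect_equal(b$bMinus, rep(0, n))
  expect_gt(median(b$bPlus), 0.1)
  # exact anti-phase: SUM constant 0.5 -> b+ ~ 0, b- positive
  b <- sybAsbMetrics(a, 1L - a, fs, cfg)
  expect_lt(median(b$bPlus), 1e-6)
  expect_gt(median(b$bMinus), 0.1)
  # quarter-cycle shift: SUM and DIF carry the same power
  b <- sybAsbMetrics(a, squareWave(n, 0.7, fs, shift = 0.25), fs, cfg)
  int <- 500:5500
  expect_gt(median(b$bPlus[int]), 0.01)
  expect_equal(median(b$bPlus[int]), median(b$bMinus[int]),
               tolerance = 0.1)
  expect_true(all(b$bPlus >= 0) && all(b$bMinus >= 0))
  expect_error(sybAsbMetrics(a, a[-1], fs, cfg), "equal length")
  expect_error(sybAsbMetrics(a + 2L, a, fs, cfg), "binary")
})

test_that("zero-crossing frequency demodulation recovers square-wave rates", {
  b <- squareWave(5000, 0.5, fs)
  f <- respiratoryFrequency(b, fs)
  expect_equal(f[100:4900], rep(0.5, 4801), tolerance = 1e-9)
  # fewer than two transitions: undefined everywhere
  expect_true(all(is.nan(respiratoryFrequency(rep(1L, 100), fs))))
  expect_error(respiratoryFrequency(c(0L, 2L), fs), "binary")
})

test_that("frequency tracks a mid-record rate step", {
  b <- c(squareWave(5000, 0.5, fs), squareWave(5000, 1, fs))
  f <- respiratoryFrequency(b, fs)
  truth <- rep(c(0.5, 1), each = 5000)
  zone <- 2 * fs / 0.5    # two slow cycles around the step
  outside <- abs(seq_along(b) - 5000) > zone
  ok <- abs(f[outside] - truth[outside]) / truth[outside] < 0.05
  expect_gte(mean(ok), 0.9)
})

test_that("XOR phase metric maps agreement to [0, 1]", {
  a <- squareWave(4000, 0.7, fs)
  expect_equal(phaseMetric(a, a, cfg), rep(0, 4000))
  expect_equal(phaseMetric(a, 1L - a, cfg), rep(1, 4000))
  phi <- phaseMetric(a, squareWave(4000, 0.7, fs, shift = 0.25), cfg)
  expect_equal(median(phi[200:3800]), 0.5, tolerance = 0.02)
  expect_error(phaseMetric(a, a * 3L, cfg), "binary")
})

test_that("computeMetrics aligns every series with the record", {
  fx <- smallFixture()
  ms <- fx$ms
  n <- nSamples(fx$syn)
  for (s in c("nvRcg", "nvAbd", "nppRcg", "nppAbd", "bPlus", "bMinus",
              "fResp", "phi"))
    expect_length(slot(ms, s), n)
  expect_length(ms@validMask, n)
  expect_true(all(ms@phi >= 0 & ms@phi <= 1))
  expect_true(all(ms@bPlus >= 0) && all(ms@bMinus >= 0))
})

test_that("metric chains recover the generator's frequency and phase", {
  fx <- studyFixture()
  ms <- fx$ms
  tr <- patternLabels(fx$syn@truth)
  v <- ms@validMask
  expect_equal(median(ms@fResp[v & tr == "SYB"], na.rm = TRUE), 0.76,
               tolerance = 0.05 / 0.76)
  modeOf <- function(x) { d <- density(x, bw = 3); d$x[which.max(d$y)] }
  expect_lt(abs(modeOf(180 * ms@phi[v & tr == "ASB"]) - 100), 15)
})

test_that("all metrics are invariant to a common positive rescaling", {
  fx <- smallFixture()
  rec <- fx$syn@record
  k <- 32   # power of two: scaling commutes exactly with every windowed sum
  ms1 <- fx$ms
  ms2 <- computeMetrics(RIPRecord(k * rcg(rec), k * abd(rec), 50))
  # binary-based metrics reproduce bit for bit
  for (s in c("bPlus", "bMinus", "phi", "fResp"))
    expect_identical(slot(ms2, s), slot(ms1, s))
  # log-ratio metrics agree except at edge samples whose shrunken windows
  # leave an exact-zero residual at the mercy of the epsilon floor
  n <- nSamples(ms1)
  interior <- 150:(n - 150)
  for (s in c("nvRcg", "nvAbd", "nppRcg", "nppAbd")) {
    a <- slot(ms1, s)[interior]; b <- slot(ms2, s)[interior]
    ok <- abs(a) < 20 & abs(b) < 20
    expect_gt(mean(ok), 0.999)
    expect_identical(b[ok], a[ok])
  }
})
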