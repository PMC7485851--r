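test_that("category merging maps SIH/MVT/UNK to UNKNOWN and is idempotent", {
  p <- PatternSequence(c("PAU", "SIH", "MVT", "UNK", "SYB"))
  m <- mergePatterns(p)
  expect_identical(patternLabels(m),
                   c("PAU", "UNKNOWN", "UNKNOWN", "UNKNOWN", "SYB"))
  expect_identical(patternLabels(mergePatterns(m)), patternLabels(m))
  expect_error(PatternSequence(c("PAU", "FOO")), "unknown")
})

test_that("count-level merging conserves totals", {
  x <- c(PAU = 10, SYB = 50, ASB = 7, MVT = 20, UNK = 12, SIH = 1)
  m <- mergePatternCounts(x)
  expect_identical(m[["UNKNOWN"]], 33)
  expect_identical(sum(m), sum(x))
})

test_that("confusion matrix counts agree with a brute-force oracle", {
  ref <- PatternSequence(c("PAU", "PAU", "SYB", "SYB", "ASB", "UNKNOWN"))
  pred <- PatternSequence(c("PAU", "SYB", "SYB", "SYB", "UNKNOWN",
                            "UNKNOWN"))
  cm <- confusionMatrix(ref, pred)
  brute <- matrix(0, 4, 4, dimnames = list(MERGED_LEVELS, MERGED_LEVELS))
  for (i in 1:6)
    brute[ref@labels[i], pred@labels[i]] <-
      brute[ref@labels[i], pred@labels[i]] + 1
  expect_equal(unname(cm@counts), unname(brute))
  # marginals
  expect_equal(rowSums(cm@counts),
               c(PAU = 2, SYB = 2, ASB = 1, UNKNOWN = 1))
  expect_equal(colSums(cm@counts),
               c(PAU = 1, SYB = 3, ASB = 0, UNKNOWN = 2))
  expect_equal(sum(cm@counts), 6)
  # perfect agreement -> diagonal
  cmd <- confusionMatrix(ref, ref)
  expect_equal(sum(diag(cmd@counts)), 6)
  expect_error(confusionMatrix(ref, PatternSequence("PAU")), "length")
})

test_that("accuracy and F-score behave at the exact limits", {
  idm <- respConfusion(diag(c(3, 4, 5, 6)))
  expect_equal(overallAccuracy(idm), 1)
  for (p in MERGED_LEVELS) {
    expect_equal(patternPrecision(idm, p), 1)
    expect_equal(patternRecall(idm, p), 1)
  }
  anti <- respConfusion(matrix(c(0, 2, 3, 0), 2, 2),
                        labels = c("PAU", "SYB"))
  expect_equal(overallAccuracy(anti), 0)
  expect_equal(fScore(0.6, 0.6), 0.6)
  expect_equal(fScore(0, 0), 0)
  expect_error(fScore(1.2, 0.5), "\\[0, 1\\]")
})

test_that("precision/recall orientation switch transposes the definitions", {
  m <- matrix(c(8, 2, 0, 1,
                1, 9, 1, 2,
                0, 1, 7, 1,
                3, 2, 2, 10), 4, 4, byrow = TRUE)
  cm <- respConfusion(m)
  for (i in seq_along(MERGED_LEVELS)) {
    p <- MERGED_LEVELS[i]
    expect_equal(patternPrecision(cm, p), m[i, i] / sum(m[i, ]))
    expect_equal(patternRecall(cm, p), m[i, i] / sum(m[, i]))
    expect_equal(patternPrecision(cm, p, orientation = "conventional"),
                 patternRecall(cm, p))
    expect_equal(patternConfusion(cm, p),
                 100 * (1 - m[i, i] / sum(m[i, ])))
  }
})

test_that("accuracy from the matrix equals the direct match fraction", {
  set.seed(31)
  ref <- PatternSequence(sample(MERGED_LEVELS, 500, replace = TRUE))
  pred <- PatternSequence(sample(MERGED_LEVELS, 500, replace = TRUE))
  cm <- confusionMatrix(ref, pred)
  expect_equal(overallAccuracy(cm), mean(ref@labels == pred@labels))
})

test_that("event segmentation is an exact run-length tiling", {
  p <- PatternSequence(c("ASB", "ASB", "MVT", "ASB"))
  seg <- segmentEvents(p, 50)
  expect_equal(seg$label, c("ASB", "MVT", "ASB"))
  expect_equal(seg$start, c(0, 2, 3))
  expect_equal(seg$length, c(2, 1, 1))
  expect_equal(seg$duration, c(0.04, 0.02, 0.02))
  # uniform sequence -> one full-length segment
  u <- segmentEvents(PatternSequence(rep("SYB", 99)), 50)
  expect_equal(nrow(u), 1L)
  expect_equal(u$length, 99)
  # random sequence round-trips through its segments
  set.seed(32)
  r <- PatternSequence(sample(c("PAU", "SYB"), 300, replace = TRUE))
  seg <- segmentEvents(r, 50)
  expect_identical(patternLabels(segmentsToSequence(seg)), r@labels)
  expect_equal(sum(seg$length), 300)
})

test_that("fragmentation histogram conserves samples and exposes noise", {
  alt <- PatternSequence(rep(c("PAU", "SYB"), 100))
  seg <- segmentEvents(alt, 50)
  expect_true(all(seg$length == 1))
  h <- fragmentationHistogram(seg)
  expect_equal(sum(h$samples), 200)
  # a noisy prediction fragments into many more short events than the
  # smooth reference it was derived from
  set.seed(33)
  smooth <- rep(c("SYB", "ASB"), each = 2500)
  noisy <- smooth
  flip <- sample(5000, 300)
  noisy[flip] <- ifelse(smooth[flip] == "SYB", "UNKNOWN", "PAU")
  nShort <- function(lab) {
    s <- segmentEvents(PatternSequence(lab), 50)
    sum(s$length < 50)
  }
  expect_gt(nShort(noisy), nShort(smooth))
})

test_that("pattern matching scores reference events against a prediction", {
  fs <- 50
  ref <- PatternSequence(rep(c("SYB", "PAU", "SYB"), c(300, 200, 300)))
  refSeg <- segmentEvents(ref, fs)
  # perfect prediction: everything matches
  pm <- patternMatching(refSeg, ref, fs)
  expect_equal(pm$overall, 1)
  expect_true(all(pm$perPattern$matched == 1))
  # 120 of the 200 PAU samples recovered: overlap 0.6 passes at 0.5, fails
  # at 0.75
  pred <- ref@labels
  pred[301:380] <- "UNKNOWN"          # 80 PAU samples lost
  pred <- PatternSequence(pred)
  pm50 <- patternMatching(refSeg, pred, fs, overlapThreshold = 0.5)
  pm75 <- patternMatching(refSeg, pred, fs, overlapThreshold = 0.75)
  pauRow <- pm50$perPattern$pattern == "PAU"
  expect_equal(pm50$perPattern$matched[pauRow], 1)
  expect_equal(pm75$perPattern$matched[pm75$perPattern$pattern == "PAU"], 0)
  # monotonicity in the threshold
  expect_lte(pm75$overall, pm50$overall)
  # events shorter than the duration floor are excluded
  shortRef <- PatternSequence(rep(c("SYB", "PAU", "SYB"),
                                  c(300, 50, 300)))
  pmS <- patternMatching(segmentEvents(shortRef, fs), shortRef, fs)
  expect_false("PAU" %in% pmS$perPattern$pattern)
  expect_error(patternMatching(refSeg, PatternSequence("PAU"), fs),
               "samples")
})
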