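mkStage <- function(cJ, cM, nJ, nM, name = "PAU",
                    features = rep("nvRcg", length(cJ))) {
  adjustBoundary(new("KMeansStage", name = name, features = features,
                     cJ = cJ, cM = cM, nJ = nJ, nM = nM, wJM = 0.5))
}

test_that("assignment follows the weighted hyperplane rule", {
  # balanced 1-D: boundary at the midpoint, boundary point goes to anti
  s <- mkStage(0, 2, 10, 10)
  expect_true(assignStage(0.9, s))
  expect_false(assignStage(1.1, s))
  expect_false(assignStage(1.0, s))        # strict inequality
  # unbalanced 1-D: w = 0.75 puts the boundary at 1.5
  s <- mkStage(0, 2, 3, 1)
  expect_equal(s@wJM, 0.75)
  expect_true(assignStage(1.4, s))
  expect_false(assignStage(1.6, s))
  # 2-D: the boundary is a hyperplane orthogonal to the centroid axis
  s <- mkStage(c(0, 0), c(2, 0), 5, 5, features = c("nvRcg", "nvAbd"))
  expect_true(assignStage(c(0.999, 100), s))
  expect_false(assignStage(c(1.001, -100), s))
  expect_error(assignStage(c(1, 2, 3), s), "feature")
})

test_that("boundary adjustment reflects cluster sizes and only moves the
           boundary outward for the larger cluster", {
  expect_equal(mkStage(0, 2, 500, 500)@wJM, 0.5)
  expect_equal(mkStage(0, 2, 900, 100)@wJM, 0.9)
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(rnorm(400, sd = 2), ncol = 2)
    cJ <- rnorm(2); cM <- rnorm(2) + 3
    balanced <- new("KMeansStage", name = "PAU",
                    features = c("nvRcg", "nvAbd"), cJ = cJ, cM = cM,
                    nJ = 10, nM = 10, wJM = 0.5)
    bigger <- mkStage(cJ, cM, 800, 200, features = c("nvRcg", "nvAbd"))
    nBal <- sum(assignStage(x, balanced))
    nAdj <- sum(assignStage(x, bigger))
    expect_gte(nAdj, nBal)
    # and every balanced-target point stays target after the shift
    expect_true(all(assignStage(x, bigger)[assignStage(x, balanced)]))
  }
})

test_that("balanced assignment equals nearest-centroid classification", {
  set.seed(22)
  for (d in c(1L, 2L, 4L)) {
    x <- matrix(rnorm(200 * d), ncol = d)
    cJ <- rnorm(d); cM <- rnorm(d)
    s <- new("KMeansStage", name = "SYB",
             features = paste0(rep("bPlus", d)), cJ = cJ, cM = cM,
             nJ = 1, nM = 1, wJM = 0.5)
    nearer <- apply(x, 1, function(p)
      sum((p - cJ)^2) < sum((p - cM)^2))
    expect_identical(assignStage(x, s), nearer)
  }
})

test_that("stage training recovers well-separated clouds with the right
           polarity", {
  set.seed(23)
  x <- matrix(c(rnorm(500, -4, 0.3), rnorm(500, 0, 0.3)), ncol = 1)
  s <- trainStage(x, "nvRcg", polarity = "low", name = "PAU")
  expect_equal(s@cJ, -4, tolerance = 0.1)
  expect_equal(s@cM, 0, tolerance = 0.1)
  expect_equal(s@wJM, 0.5, tolerance = 0.05)
  # mirror image under the same polarity: target and anti swap
  s2 <- trainStage(-x, "nvRcg", polarity = "low", name = "PAU")
  expect_equal(s2@cJ, -s@cM, tolerance = 0.1)
  expect_equal(s2@cM, -s@cJ, tolerance = 0.1)
  # a single outlier forms its own cluster; w collapses accordingly
  set.seed(24)
  x <- matrix(c(rnorm(200, 0, 0.01), 10), ncol = 1)
  s3 <- trainStage(x, "bPlus", polarity = "high", name = "SYB")
  expect_equal(s3@nJ, 1)
  expect_equal(s3@wJM, 1 / 201, tolerance = 1e-9)
  expect_error(trainStage(matrix(1, 50, 1), "bPlus", "high", "SYB"),
               "degenerate")
})

test_that("cascade training is deterministic and oriented correctly", {
  fx <- studyFixture()
  model <- fx$model
  # polarity of every stage: PAU lower NV, MVT higher npp, SYB higher b+,
  # ASB higher b-
  expect_lt(mean(model@stages[[1]]@cJ), mean(model@stages[[1]]@cM))
  expect_gt(mean(model@stages[[2]]@cJ), mean(model@stages[[2]]@cM))
  expect_gt(model@stages[[3]]@cJ, model@stages[[3]]@cM)
  expect_gt(model@stages[[4]]@cJ, model@stages[[4]]@cM)
  # same data, same seed -> identical parameters
  model2 <- trainAurea(fx$ms, seed = 1)
  for (i in 1:4) {
    expect_identical(model2@stages[[i]]@cJ, model@stages[[i]]@cJ)
    expect_identical(model2@stages[[i]]@wJM, model@stages[[i]]@wJM)
  }
})

test_that("training survives data without pause-like samples", {
  set.seed(25)
  specs <- list(patternSpec("SYB", 120), patternSpec("ASB", 30),
                patternSpec("SYB", 60))
  syn <- generateRecord(specs, fs = 50, seed = 9)
  ms <- computeMetrics(syn@record)
  model <- trainAurea(ms, seed = 9, includeInvalid = TRUE)
  expect_s4_class(model, "AureaModel")
  expect_false(isTRUE(all.equal(model@stages[[1]]@cJ,
                                model@stages[[1]]@cM)))
})

test_that("classification is a deterministic partition honouring stage
           precedence", {
  fx <- studyFixture()
  pred <- fx$pred
  n <- nSamples(fx$ms)
  expect_length(patternLabels(pred), n)
  expect_true(all(patternLabels(pred) %in%
                    c("PAU", "MVT", "SYB", "ASB", "UNK")))
  # determinism
  expect_identical(patternLabels(classify(fx$ms, fx$model)),
                   patternLabels(pred))
  # precedence: every PAU-labeled sample is claimed by stage A, and every
  # stage-A target is labeled PAU no matter its other metrics
  stageA <- fx$model@stages[[1]]
  hitA <- assignStage(metricMatrix(fx$ms, stageA@features), stageA)
  expect_identical(patternLabels(pred) == "PAU", hitA)
  # SYB-labeled samples were rejected by PAU and MVT and claimed by SYB
  stageC <- fx$model@stages[[3]]
  hitC <- assignStage(metricMatrix(fx$ms, stageC@features), stageC)
  syb <- patternLabels(pred) == "SYB"
  expect_true(all(hitC[syb]))
  expect_true(!any(hitA[syb]))
})

test_that("model serialization round-trips to a bit-identical PSEQ", {
  fx <- studyFixture()
  path <- tempfile(fileext = ".json")
  saveModel(fx$model, path)
  model2 <- loadModel(path)
  expect_identical(patternLabels(classify(fx$ms, model2)),
                   patternLabels(fx$pred))
  for (i in 1:4)
    expect_identical(model2@stages[[i]]@cJ, fx$model@stages[[i]]@cJ)
  unlink(path)
})
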