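# Four-stage cascade of binary k-means detectors.
#
# Each stage splits its feature space into a target and an anti cluster with
# two-cluster k-means (k-means++ seeding, best of 10 restarts), orients the
# pair with a polarity rule (PAU: lower normalized variance; MVT: higher
# nonperiodic power; SYB: higher b+; ASB: higher b-), and re-anchors the
# decision hyperplane with the unbalanced-data boundary weighting factor
# w = n_target / (n_target + n_anti), so the more populous cluster covers
# more of the space.

.STAGE_DEF <- list(
  PAU = list(features = c("nvRcg", "nvAbd"), polarity = "low"),
  MVT = list(features = c("nppRcg", "nppAbd"), polarity = "high"),
  SYB = list(features = "bPlus", polarity = "high"),
  ASB = list(features = "bMinus", polarity = "high"))

#' Extract a feature matrix from a MetricSet
#'
#' @param metrics a [MetricSet-class].
#' @param features metric slot names, e.g. `c("nvRcg", "nvAbd")`.
#' @return numeric matrix, one column per feature.
#' @export
metricMatrix <- function(metrics, features) {
  ok <- features %in% c("nvRcg", "nvAbd", "nppRcg", "nppAbd",
                        "bPlus", "bMinus", "fResp", "phi")
  if (!all(ok))
    aureaValidationError("unknown metric feature(s): %s",
                         paste(features[!ok], collapse = ", "))
  m <- vapply(features, function(f) slot(metrics, f),
              numeric(length(metrics@nvRcg)))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(features))
  colnames(m) <- features
  m
}

# k-means++ seeding for k = 2 (draws through the active RNG stream)
kmeansPPInit <- function(x, k = 2L) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  for (j in 2:k) {
    d2 <- rep(Inf, n)
    for (i in seq_len(j - 1L))
      d2 <- pmin(d2, rowSums((x - rep(centers[i, ], each = n))^2))
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
  }
  centers
}

#' Train one binary k-means stage
#'
#' Runs two-cluster k-means on the named features (k-means++ seeding, 10
#' restarts, best within-cluster sum of squares), orients the clusters by the
#' polarity rule, and applies the boundary adjustment.
#'
#' @param x numeric matrix of training points (rows = samples).
#' @param features feature names labelling the columns.
#' @param polarity `"low"` or `"high"`: the target cluster is the one whose
#'   centroid mean is lower / higher.
#' @param name pattern label the stage detects.
#' @param nRestarts number of k-means++ restarts (default 10).
#' @return A [KMeansStage-class] with adjusted boundary.
#' @export
trainStage <- function(x, features, polarity = c("high", "low"), name,
                       nRestarts = 10L) {
  polarity <- match.arg(polarity)
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    aureaValidationError("stage %s: need at least 2 training points", name)
  if (nrow(unique(x)) < 2L)
    aureaValidationError(
      "stage %s: degenerate training data (all points identical)", name)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    init <- kmeansPPInit(x)
    km <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = 300L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  km <- best
  ord <- order(rowMeans(km$centers))
  target <- if (polarity == "low") ord[1L] else ord[2L]
  anti <- setdiff(1:2, target)
  stage <- new("KMeansStage", name = name, features = features,
               cJ = as.numeric(km$centers[target, ]),
               cM = as.numeric(km$centers[anti, ]),
               nJ = as.numeric(km$size[target]),
               nM = as.numeric(km$size[anti]),
               wJM = 0.5)
  adjustBoundary(stage)
}

#' Adjust a stage's decision boundary for unbalanced clusters
#'
#' Sets the boundary weighting factor to `w = nJ / (nJ + nM)` (the relative
#' size of the target cluster at k-means convergence), leaving the centroids
#' unchanged.  With balanced clusters this reduces to the conventional
#' midpoint (w = 0.5).
#'
#' @param stage a [KMeansStage-class].
#' @return The stage with updated `wJM`.
#' @export
adjustBoundary <- function(stage) {
  if (stage@nJ + stage@nM <= 0)
    aureaValidationError("stage %s: empty clusters", stage@name)
  stage@wJM <- stage@nJ / (stage@nJ + stage@nM)
  validObject(stage)
  stage
}

#' Assign points to a stage's target or anti class
#'
#' The decision hyperplane has normal `v = cM - cJ` and anchor
#' `g = w * v + cJ`; a point `x` is assigned to the target class iff
#' `v . (x - g) < 0` (strict, so boundary points go to the anti class).
#'
#' @param x numeric matrix of points (rows = samples) in the stage's feature
#'   space, or a vector for a single point.
#' @param stage a [KMeansStage-class].
#' @return logical vector, TRUE where the point is assigned to the target.
#' @export
assignStage <- function(x, stage) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(stage@features))
    aureaValidationError(
      "stage %s expects %d feature(s), got %d columns",
      stage@name, length(stage@features), ncol(x))
  if (any(!is.finite(x)))
    aureaValidationError("stage %s: non-finite feature values", stage@name)
  v <- stage@cM - stage@cJ
  g <- stage@wJM * v + stage@cJ
  drop((x - rep(g, each = nrow(x))) %*% v) < 0
}

#' Train the full AUREA cascade
#'
#' Pools the (valid) samples of one or more metric sets and trains the four
#' stages sequentially: PAU on the normalized-variance features over all
#' samples, MVT on the nonperiodic-power features over the remainder, SYB on
#' b+ and ASB on b- over successive reductions; whatever survives all four
#' stages is UNK.  Each stage's reduction removes the samples its adjusted
#' boundary assigns to the target class, so training mirrors classification.
#'
#' @param metrics a [MetricSet-class] or a list of them (pooled).
#' @param cfg the [AnalysisConfig-class] the metrics were computed with
#'   (recorded in the model).
#' @param seed integer seed for k-means initialisation (recorded in the
#'   model).
#' @param includeInvalid logical; include samples whose normalisation
#'   windows are not fully supported (default FALSE).
#' @return A frozen [AureaModel-class].
#' @export
trainAurea <- function(metrics, cfg = analysisConfig(), seed = 1L,
                       includeInvalid = FALSE) {
  if (is(metrics, "MetricSet")) metrics <- list(metrics)
  fs <- metrics[[1L]]@fs
  pool <- do.call(rbind, lapply(metrics, function(ms) {
    m <- metricMatrix(ms, c("nvRcg", "nvAbd", "nppRcg", "nppAbd",
                            "bPlus", "bMinus"))
    if (!includeInvalid) m <- m[ms@validMask, , drop = FALSE]
    m
  }))
  pool <- pool[stats::complete.cases(pool) & is.finite(rowSums(pool)), ,
               drop = FALSE]
  if (nrow(pool) < 8L)
    aureaValidationError("too few training samples (%d) after filtering",
                         nrow(pool))
  stages <- vector("list", 4L)
  names(stages) <- names(.STAGE_DEF)
  remaining <- pool
  withLocalSeed(seed, {
    for (nm in names(.STAGE_DEF)) {
      def <- .STAGE_DEF[[nm]]
      if (nrow(remaining) < 2L)
        aureaValidationError(
          "stage %s: no samples left to train on (earlier stages consumed all data)",
          nm)
      xs <- remaining[, def$features, drop = FALSE]
      stage <- trainStage(xs, def$features, def$polarity, nm)
      stages[[nm]] <- stage
      keep <- !assignStage(xs, stage)
      if (!any(keep))
        aureaValidationError("stage %s consumed all remaining samples", nm)
      remaining <- remaining[keep, , drop = FALSE]
    }
  })
  new("AureaModel", stages = unname(stages),
      cfg = cfg, fs = fs, seed = as.integer(seed))
}

#' @describeIn classify Pass each sample down the PAU -> MVT -> SYB -> ASB
#'   decision tree; the first stage that claims it sets the label, and
#'   samples rejected by all four stages are UNK.  Deterministic given the
#'   model.
setMethod("classify", signature("MetricSet", "AureaModel"),
  function(metrics, model) {
    n <- length(metrics@nvRcg)
    labels <- rep("UNK", n)
    open <- rep(TRUE, n)
    for (stage in model@stages) {
      if (!any(open)) break
      x <- metricMatrix(metrics, stage@features)
      xo <- x[open, , drop = FALSE]
      finite <- is.finite(rowSums(xo))
      hit <- rep(FALSE, nrow(xo))
      if (any(finite))
        hit[finite] <- assignStage(xo[finite, , drop = FALSE], stage)
      idx <- which(open)[hit]
      labels[idx] <- stage@name
      open[idx] <- FALSE
    }
    PatternSequence(labels)
  })
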