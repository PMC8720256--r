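#' Preprocessing configuration
#'
#' Bundles the cleaning and resampling parameters applied to every raw cloud
#' before it reaches the network.
#'
#' @param outlierK Neighbor count for the outlier statistic.
#' @param outlierStdRatio Threshold multiplier: points whose mean k-neighbor
#'   distance exceeds mu + ratio * sigma are dropped.
#' @param smoothK Neighborhood size for Gaussian smoothing.
#' @param smoothSigma Kernel bandwidth as a fraction of the bounding-box
#'   diagonal.
#' @param targetN Output point count (network input size, default 2048).
#' @param seed Integer seed for the farthest-point-sampling start.
#' @return A validated list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(outlierK = 16L, outlierStdRatio = 2.0,
                             smoothK = 8L, smoothSigma = 0.01,
                             targetN = 2048L, seed = 1L) {
  stopifnot(outlierK >= 1L, targetN >= 1L, smoothSigma > 0, smoothK >= 1L)
  structure(list(outlierK = as.integer(outlierK),
                 outlierStdRatio = outlierStdRatio,
                 smoothK = as.integer(smoothK), smoothSigma = smoothSigma,
                 targetN = as.integer(targetN), seed = as.integer(seed)),
            class = "PreprocessConfig")
}

#' Remove statistical outliers
#'
#' Classic statistical outlier removal: each point's mean distance to its
#' `k` nearest neighbors (self excluded) is compared to the cloud-wide mean
#' and standard deviation of that statistic; points above
#' mu + stdRatio * sigma are discarded. Labels follow their points.
#'
#' @param cloud A [LabeledCloud-class].
#' @param k Neighbor count for the statistic.
#' @param stdRatio Threshold multiplier.
#' @return The filtered [LabeledCloud-class].
#' @export
removeStatisticalOutliers <- function(cloud, k = 16L, stdRatio = 2.0) {
  n <- nPoints(cloud)
  if (n <= k) stop("cloud must have more than k points")
  nn <- knnIndices(cloudCoords(cloud), cloudCoords(cloud), k + 1L)
  stat <- rowMeans(nn$dist[, -1L, drop = FALSE])
  keep <- stat <= mean(stat) + stdRatio * stats::sd(stat)
  if (!any(keep))
    stop("all points classified as outliers; increase stdRatio")
  subsetCloud(cloud, which(keep))
}

#' Gaussian neighborhood smoothing
#'
#' Replaces each coordinate by the Gaussian-weighted mean of its
#' k-neighborhood (self included), weights exp(-d^2 / 2 sigma^2) normalized
#' to sum to one. Point count and labels are unchanged; only positions move.
#'
#' @param cloud A [LabeledCloud-class].
#' @param k Neighborhood size (self excluded from the count).
#' @param sigma Kernel bandwidth, in coordinate units.
#' @return The smoothed [LabeledCloud-class].
#' @export
gaussianSmooth <- function(cloud, k = 8L, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  n <- nPoints(cloud)
  if (n <= k) stop("cloud must have more than k points")
  co <- cloudCoords(cloud)
  nn <- knnIndices(co, co, k + 1L)  # first neighbor is the point itself
  w <- exp(-nn$dist^2 / (2 * sigma^2))
  w <- w / rowSums(w)
  out <- matrix(0, n, 3L)
  for (j in seq_len(ncol(w))) {
    out <- out + w[, j] * co[nn$idx[, j], , drop = FALSE]
  }
  replaceCoords(cloud, out)
}

#' Farthest point sampling
#'
#' Greedy subsampling that yields spatially uniform coverage: the first
#' index is a seeded draw; each subsequent index maximizes the minimum
#' Euclidean distance to all previously selected points, ties broken by the
#' smallest index.
#'
#' @param cloud A [LabeledCloud-class] (or N x 3 matrix).
#' @param n Number of points to select, `1 <= n <= N`.
#' @param seed Seed for the initial draw.
#' @return Integer vector of `n` distinct 1-based indices.
#' @export
farthestPointSample <- function(cloud, n, seed = 1L) {
  co <- if (is(cloud, "LabeledCloud")) cloudCoords(cloud)
        else asCoordMatrix(cloud)
  start <- withSeed(seed, sample.int(nrow(co), 1L))
  fpsIndices(co, n, start)
}

# Core greedy loop; `start` is the (deterministic) first index.
fpsIndices <- function(co, n, start) {
  N <- nrow(co)
  n <- as.integer(n)
  if (n < 1L || n > N) stop("n must be in [1, N]; got n=", n, ", N=", N)
  sel <- integer(n)
  sel[1L] <- start
  mind <- crossDist2(co[start, , drop = FALSE], co)[1L, ]
  if (n > 1L) for (i in 2:n) {
    nxt <- which.max(mind)  # which.max returns the first (smallest) index
    sel[i] <- nxt
    d2 <- crossDist2(co[nxt, , drop = FALSE], co)[1L, ]
    mind <- pmin(mind, d2)
  }
  sel
}

# Permutation-invariant FPS start used inside the network: the point
# farthest from the cloud centroid.
fpsGeometricStart <- function(co) {
  ctr <- colMeans(co)
  which.max(crossDist2(matrix(ctr, 1L, 3L), co)[1L, ])
}

#' Normalize a cloud into the unit cube
#'
#' Isotropic min-max normalization: subtract the per-axis minimum and divide
#' all three axes by the largest axis extent, so shape (all distance ratios)
#' is preserved and the longest axis spans exactly [0, 1].
#'
#' @param cloud A [LabeledCloud-class].
#' @return The normalized [LabeledCloud-class].
#' @export
normalizeUnitCube <- function(cloud) {
  co <- cloudCoords(cloud)
  mins <- apply(co, 2L, min)
  ext <- apply(co, 2L, max) - mins
  scale <- max(ext)
  if (scale <= 0) stop("cloud has zero extent on all axes")
  replaceCoords(cloud, sweep(co, 2L, mins) / scale)
}

#' Full preprocessing pipeline
#'
#' Statistical outlier removal, Gaussian smoothing, farthest point sampling
#' down to the fixed network input size, then unit-cube normalization.
#'
#' @param cloud A [LabeledCloud-class] with at least `cfg$targetN` points
#'   surviving the filters.
#' @param cfg A [preprocessConfig()] bundle.
#' @return A [LabeledCloud-class] with exactly `cfg$targetN` points in the
#'   unit cube.
#' @export
preprocessPipeline <- function(cloud, cfg = preprocessConfig()) {
  cl <- removeStatisticalOutliers(cloud, cfg$outlierK, cfg$outlierStdRatio)
  diag <- sqrt(sum((apply(cloudCoords(cl), 2L, max) -
                    apply(cloudCoords(cl), 2L, min))^2))
  cl <- gaussianSmooth(cl, cfg$smoothK, cfg$smoothSigma * diag)
  if (nPoints(cl) < cfg$targetN)
    stop("only ", nPoints(cl), " points survive filtering; targetN=",
         cfg$targetN)
  idx <- farthestPointSample(cl, cfg$targetN, cfg$seed)
  normalizeUnitCube(subsetCloud(cl, idx))
}
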