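#' k-nearest-neighbor index table
#'
#' For each query point, finds the `k` reference points with smallest
#' Euclidean distance. Rows are sorted by ascending distance; exact distance
#' ties are broken by the smaller reference index. This table is the local
#' neighborhood over which the continuous convolution integrates.
#'
#' @param query Q x 3 matrix of query (centroid) coordinates.
#' @param reference N x 3 matrix of reference coordinates.
#' @param k Neighborhood size, `k <= N`.
#' @return A list of class `NeighborhoodIndex` with elements `idx` (Q x k
#'   integer matrix of 1-based reference indices) and `dist` (Q x k matrix of
#'   distances).
#' @examples
#' ref <- matrix(runif(60), 20, 3)
#' nn <- knnIndices(ref[1:5, ], ref, k = 4)
#' nn$idx[, 1]  # each query point is its own nearest neighbor: 1..5
#' @export
knnIndices <- function(query, reference, k) {
  query <- asCoordMatrix(query, "query")
  reference <- asCoordMatrix(reference, "reference")
  n <- nrow(reference)
  if (k > n) stop("k (", k, ") exceeds reference size (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  q <- nrow(query)
  idx <- matrix(0L, q, k)
  dst <- matrix(0, q, k)
  # chunk queries to bound the distance-matrix memory footprint
  chunk <- max(1L, min(q, as.integer(2e6 / n)))
  at <- 1L
  while (at <= q) {
    rows <- at:min(q, at + chunk - 1L)
    d2 <- crossDist2(query[rows, , drop = FALSE], reference)
    for (r in seq_along(rows)) {
      o <- order(d2[r, ], seq_len(n))[seq_len(k)]
      idx[rows[r], ] <- o
      dst[rows[r], ] <- sqrt(d2[r, o])
    }
    at <- rows[length(rows)] + 1L
  }
  structure(list(idx = idx, dist = dst, k = k, n = n),
            class = "NeighborhoodIndex")
}

#' Inverse point density
#'
#' Kernel density estimate at each point over its `kDensity` nearest
#' neighbors (the point itself included, so the estimate is always positive),
#' inverted to give the per-point weight S that compensates the non-uniform
#' sampling of scanned surfaces: sparse regions receive larger weights.
#' density_i = mean_j exp(-d_ij^2 / (2 bw^2)), s_i = 1 / density_i.
#'
#' @param points N x 3 coordinate matrix.
#' @param kDensity Number of neighbors in the estimate (self included).
#' @param bandwidth Gaussian kernel bandwidth, in the units of `points`
#'   (unit-cube units after normalization).
#' @return Numeric vector of length N of positive inverse densities.
#' @export
inverseDensity <- function(points, kDensity = 16L, bandwidth = 0.05) {
  points <- asCoordMatrix(points, "points")
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  kDensity <- min(as.integer(kDensity), nrow(points))
  nn <- knnIndices(points, points, kDensity)
  dens <- rowMeans(exp(-nn$dist^2 / (2 * bandwidth^2)))
  1 / dens
}

#' Relative neighbor offsets
#'
#' The displacement (delta_x, delta_y, delta_z) of each neighbor from its
#' centroid; the continuous kernel W is evaluated on these offsets.
#'
#' @param centroids Q x 3 matrix.
#' @param reference N x 3 matrix.
#' @param nbr `NeighborhoodIndex` over `reference` with Q rows.
#' @return Q x k x 3 array of offsets (neighbor minus centroid).
#' @export
groupRelative <- function(centroids, reference, nbr) {
  centroids <- asCoordMatrix(centroids, "centroids")
  reference <- asCoordMatrix(reference, "reference")
  idx <- nbr$idx
  if (any(idx < 1L) || any(idx > nrow(reference)))
    stop("neighborhood index out of range for the reference set")
  k <- ncol(idx)
  q <- nrow(idx)
  out <- array(0, dim = c(q, k, 3L))
  for (a in 1:3) {
    out[, , a] <- matrix(reference[idx, a], q, k) - centroids[, a]
  }
  out
}

#' Interpolate features from a sparse onto a dense point set
#'
#' Inverse-distance weighting over the `kInterp` nearest sparse points:
#' w_j = 1/(d_j + eps) normalized to sum to one. When a dense point
#' coincides with a sparse point its weight approaches 1 and the feature is
#' copied. This is the upsampling step of the decoder.
#'
#' @param dense M x 3 matrix of target coordinates.
#' @param sparse P x 3 matrix of source coordinates.
#' @param features P x C feature matrix over `sparse`.
#' @param kInterp Number of source neighbors (default 3, the feature
#'   propagation convention).
#' @param eps Distance regularizer.
#' @return M x C interpolated feature matrix.
#' @export
interpolateFeatures <- function(dense, sparse, features, kInterp = 3L,
                                eps = 1e-8) {
  features <- as.matrix(features)
  if (nrow(features) != nrow(sparse))
    stop("features must have one row per sparse point")
  iw <- interpWeights(dense, sparse, kInterp, eps)
  applyInterp(iw, features)
}

# Precompute interpolation indices and normalized weights (geometry-static).
interpWeights <- function(dense, sparse, kInterp = 3L, eps = 1e-8) {
  kInterp <- min(as.integer(kInterp), nrow(as.matrix(sparse)))
  nn <- knnIndices(dense, sparse, kInterp)
  w <- 1 / (nn$dist + eps)
  w <- w / rowSums(w)
  list(idx = nn$idx, w = w, k = kInterp)
}

applyInterp <- function(iw, features) {
  out <- matrix(0, nrow(iw$idx), ncol(features))
  for (j in seq_len(iw$k)) {
    out <- out + iw$w[, j] * features[iw$idx[, j], , drop = FALSE]
  }
  out
}

# Backward of applyInterp: scatter-accumulate gradients onto sparse rows.
applyInterpBackward <- function(iw, dOut, nSparse) {
  dF <- matrix(0, nSparse, ncol(dOut))
  for (j in seq_len(iw$k)) {
    contrib <- iw$w[, j] * dOut
    acc <- rowsum(contrib, group = iw$idx[, j])
    rows <- as.integer(rownames(acc))
    dF[rows, ] <- dF[rows, ] + acc
  }
  dF
}
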