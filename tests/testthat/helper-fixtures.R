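# Shared fixture builders; all randomness is locally seeded.

randomCloud <- function(n = 50, seed = 1, labeled = TRUE, name = "fix") {
  withr::with_seed(seed, {
    labs <- if (labeled) sample(0:1, n, replace = TRUE) else NULL
    LabeledCloud(matrix(runif(3 * n), n, 3), labs, name)
  })
}

randomDataset <- function(nClouds = 5, n = 40, seed = 1, splits = NULL) {
  clouds <- lapply(seq_len(nClouds), function(i) {
    randomCloud(n, seed + i, name = sprintf("c%02d", i))
  })
  CloudDataset(clouds, splits)
}

# A toy full-network architecture small enough for brute-force checks.
toySpec <- function(...) {
  args <- list(nPoints = c(64L, 32L, 16L, 12L, 8L),
               channels = c(3L, 4L, 4L, 6L, 6L),
               decoderChannels = c(6L, 6L, 4L, 4L),
               k1 = 4L, k2 = 8L, kDecoder = 6L)
  override <- list(...)
  args[names(override)] <- override
  do.call(architectureSpec, args)
}

# Brute-force k-nearest-neighbors: full sort per query.
bruteKnn <- function(query, reference, k) {
  out <- matrix(0L, nrow(query), k)
  for (q in seq_len(nrow(query))) {
    d <- sqrt(colSums((t(reference) - query[q, ])^2))
    out[q, ] <- order(d, seq_along(d))[seq_len(k)]
  }
  out
}

# Explicit per-centroid triple-sum discretization of the continuous
# convolution: loops over centroids, neighbors and channels only.
pointconvOracle <- function(centroids, reference, feat, s, p, k,
                            activation = "linear") {
  nnIdx <- bruteKnn(centroids, reference, k)
  cout <- ncol(p$Wm)
  out <- matrix(0, nrow(centroids), cout)
  for (q in seq_len(nrow(centroids))) {
    acc <- rep(0, ncol(feat))
    for (j in seq_len(k)) {
      r <- nnIdx[q, j]
      off <- reference[r, ] - centroids[q, ]
      h <- pmax(as.vector(off %*% p$W1) + p$b1, 0)
      w <- as.vector(h %*% p$W2) + p$b2      # one kernel value per channel
      acc <- acc + w * s[r] * feat[r, ]
    }
    pre <- as.vector(acc %*% p$Wm) + p$bm
    out[q, ] <- if (activation == "relu") pmax(pre, 0) else pre
  }
  out
}

expect_cloud_equal <- function(a, b, tol = 1e-12) {
  expect_equal(cloudCoords(a), cloudCoords(b), tolerance = tol)
  expect_equal(cloudLabels(a), cloudLabels(b))
}
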