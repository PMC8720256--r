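test_that("statistical outlier removal drops a distant point and keeps the
           sphere", {
  withr::with_seed(21, {
    u <- matrix(rnorm(300), 100, 3)
    sphere <- u / sqrt(rowSums(u^2))
    cl <- LabeledCloud(rbind(sphere, c(50, 0, 0)),
                       c(rep(0L, 100), 1L))
    # brute-force confirmation that the outlier exceeds mu + 2 sd
    d <- as.matrix(dist(cloudCoords(cl)))
    stat <- apply(d, 1, function(r) mean(sort(r)[2:9]))
    expect_gt(stat[101], mean(stat) + 2 * stats::sd(stat))

    out <- removeStatisticalOutliers(cl, k = 8, stdRatio = 2)
    expect_equal(nPoints(out), 100L)
    expect_true(all(cloudLabels(out) == 0L))
  })
})

test_that("outlier removal keeps identical points and never grows a cloud", {
  same <- LabeledCloud(matrix(0.5, 20, 3), rep(1L, 20))
  expect_equal(nPoints(removeStatisticalOutliers(same, 5, 2)), 20L)
  withr::with_seed(22, {
    cl <- randomCloud(60)
    out <- removeStatisticalOutliers(cl, 6, 1.0)
    expect_lte(nPoints(out), 60L)
  })
})

test_that("Gaussian smoothing preserves lines, reduces planar noise, and
           vanishes as sigma shrinks", {
  t <- seq(0, 1, length.out = 30)
  line <- LabeledCloud(cbind(t, 2 * t, -t), rep(0L, 30))
  sm <- gaussianSmooth(line, k = 5, sigma = 0.1)
  co <- cloudCoords(sm)
  expect_equal(co[, 2], 2 * co[, 1], tolerance = 1e-9)
  expect_equal(co[, 3], -co[, 1], tolerance = 1e-9)

  cl <- randomCloud(40, seed = 23)
  tiny <- gaussianSmooth(cl, k = 5, sigma = 1e-8)
  expect_equal(cloudCoords(tiny), cloudCoords(cl), tolerance = 1e-9)
  expect_error(gaussianSmooth(cl, 5, 0), "sigma")

  withr::with_seed(24, {
    xy <- matrix(runif(100), 50, 2)
    z <- rnorm(50, 0, 0.05)
    noisy <- LabeledCloud(cbind(xy, z), rep(1L, 50))
    smoothed <- gaussianSmooth(noisy, k = 10, sigma = 0.3)
    expect_lt(mean(abs(cloudCoords(smoothed)[, 3])), mean(abs(z)))
    expect_equal(nPoints(smoothed), 50L)
    expect_equal(cloudLabels(smoothed), rep(1L, 50))
  })
})

test_that("farthest point sampling is greedy, exhaustive at n = N, and
           seed-deterministic", {
  # unit square corners + center: starting from a corner picks all corners
  sq <- matrix(c(0, 1, 0, 1, 0.5,
                 0, 0, 1, 1, 0.5,
                 0, 0, 0, 0, 0), 5, 3)
  cl <- LabeledCloud(sq, rep(0L, 5))
  for (seed in 1:10) {
    idx <- farthestPointSample(cl, 4, seed)
    if (idx[1] %in% 1:4) expect_setequal(idx, 1:4)
  }

  full <- farthestPointSample(cl, 5, 3)
  expect_setequal(full, 1:5)

  cl2 <- randomCloud(30, seed = 25)
  expect_identical(farthestPointSample(cl2, 10, 7),
                   farthestPointSample(cl2, 10, 7))
  expect_error(farthestPointSample(cl2, 31, 1), "n must be")
})

test_that("every FPS pick attains the max-min distance at its step", {
  withr::with_seed(26, {
    for (rep in 1:20) {
      n <- sample(8:50, 1)
      m <- sample(2:min(10, n), 1)
      co <- matrix(runif(3 * n), n, 3)
      idx <- farthestPointSample(LabeledCloud(co, rep(0L, n)), m, rep)
      d <- as.matrix(dist(co))
      for (step in 2:m) {
        sel <- idx[seq_len(step - 1)]
        mind <- unname(apply(d[, sel, drop = FALSE], 1, min))
        expect_equal(mind[idx[step]], max(mind))
      }
    }
  })
})

test_that("FPS is a 2-approximation of the k-center optimum on small
           instances", {
  withr::with_seed(27, {
    for (rep in 1:15) {
      n <- sample(6:10, 1)
      k <- sample(2:4, 1)
      co <- matrix(runif(3 * n), n, 3)
      d <- as.matrix(dist(co))
      radius <- function(sel) max(apply(d[, sel, drop = FALSE], 1, min))
      opt <- min(apply(utils::combn(n, k), 2, radius))
      got <- radius(farthestPointSample(LabeledCloud(co, rep(0L, n)), k,
                                        rep))
      expect_lte(got, 2 * opt + 1e-12)
    }
  })
})

test_that("unit-cube normalization is isotropic, idempotent, and preserves
           distance ratios", {
  withr::with_seed(28, {
    cl <- LabeledCloud(matrix(runif(90, -5, 5), 30, 3), rep(1L, 30))
    norm1 <- normalizeUnitCube(cl)
    co <- cloudCoords(norm1)
    expect_true(all(co >= 0 & co <= 1))
    expect_equal(max(apply(co, 2, max) - apply(co, 2, min)), 1)

    norm2 <- normalizeUnitCube(norm1)
    expect_equal(cloudCoords(norm2), co, tolerance = 1e-12)

    d0 <- dist(cloudCoords(cl))
    d1 <- dist(co)
    expect_equal(as.vector(d1 / d0), rep(d1[1] / d0[1], length(d0)),
                 tolerance = 1e-9)
  })
  flat <- LabeledCloud(matrix(0.2, 5, 3), rep(0L, 5))
  expect_error(normalizeUnitCube(flat), "zero extent")
})

test_that("the preprocessing pipeline hits the target count with both
           classes intact", {
  p <- panicleParams(totalPointsRaw = 5000L, seed = 31)
  cl <- generatePanicle(p)
  out <- preprocessPipeline(cl, preprocessConfig(targetN = 2048L, seed = 1))
  expect_equal(nPoints(out), 2048L)
  expect_setequal(unique(cloudLabels(out)), c(0L, 1L))
  expect_true(all(cloudCoords(out) >= 0 & cloudCoords(out) <= 1))

  small <- randomCloud(30, seed = 32)
  expect_error(preprocessPipeline(small,
                                  preprocessConfig(targetN = 500L)),
               "targetN|survive")
})

test_that("FPS approximately preserves label proportions", {
  p <- panicleParams(totalPointsRaw = 5000L, seed = 33)
  cl <- generatePanicle(p)
  frac0 <- mean(cloudLabels(cl) == 0L)
  for (seed in 1:20) {
    idx <- farthestPointSample(cl, 2048, seed)
    expect_lt(abs(mean(cloudLabels(cl)[idx] == 0L) - frac0), 0.05)
  }
})
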