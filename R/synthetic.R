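#' Parameters of the synthetic rice panicle generator
#'
#' Describes a simplified rice plant: a curved cylindrical stalk (class 0)
#' topped by a set of drooping rachis branches bearing ellipsoidal grain
#' clusters (class 1, the panicle/ear). Labels are assigned by the emitting
#' primitive, so ground truth is exact by construction. Lengths are relative
#' to `stemLength`; the cloud is generated in these raw units and normalized
#' later by the preprocessing pipeline.
#'
#' The `"realistic"` preset approximates a scanned rice plant: moderate
#' surface noise, pronounced droop, stem and ear overlapping at the apex so
#' the class boundary is genuinely ambiguous there. The `"easy"` preset
#' keeps the same geometry with near-zero noise and milder droop, giving
#' well-separated primitives for sanity checks and fast training tests.
#'
#' @param stemLength Stalk length (the unit of all other lengths).
#' @param stemRadius Stalk cylinder radius.
#' @param stemCurvature Lateral displacement of the stalk tip as a fraction
#'   of `stemLength` (quadratic bend).
#' @param nBranches Number of rachis branches attached at the stem apex.
#' @param grainsPerBranch Ellipsoidal grain clusters per branch.
#' @param grainAxes Length-3 ellipsoid semi-axes (major axis along the
#'   branch direction).
#' @param branchLength Branch arc length as a fraction of `stemLength`.
#' @param droopAngle Radians by which a branch's elevation decreases from
#'   base to tip (drooping under grain weight).
#' @param surfaceNoiseSigma Additive isotropic Gaussian coordinate noise.
#' @param stemPointFraction Target share of class-0 (stem) points; rice
#'   clouds are ear-dominated, so the stem is the minority class.
#' @param totalPointsRaw Points generated before any downsampling.
#' @param seed Integer seed.
#' @param preset `"realistic"` (default) or `"easy"`.
#' @return A validated list of class `PanicleParams`.
#' @export
panicleParams <- function(stemLength = 1.0, stemRadius = 0.02,
                          stemCurvature = 0.15, nBranches = 8L,
                          grainsPerBranch = 12L,
                          grainAxes = c(0.035, 0.018, 0.018),
                          branchLength = 0.45, droopAngle = 0.5,
                          surfaceNoiseSigma = 0.005,
                          stemPointFraction = 0.35,
                          totalPointsRaw = 6000L, seed = 1L,
                          preset = c("realistic", "easy")) {
  preset <- match.arg(preset)
  if (preset == "easy") {
    surfaceNoiseSigma <- 0.001
    droopAngle <- 0.3
  }
  stopifnot(stemLength > 0, stemRadius > 0, branchLength > 0,
            all(grainAxes > 0), nBranches >= 1L, grainsPerBranch >= 1L,
            stemPointFraction > 0, stemPointFraction < 1,
            totalPointsRaw >= 2L, surfaceNoiseSigma >= 0)
  structure(list(stemLength = stemLength, stemRadius = stemRadius,
                 stemCurvature = stemCurvature,
                 nBranches = as.integer(nBranches),
                 grainsPerBranch = as.integer(grainsPerBranch),
                 grainAxes = grainAxes, branchLength = branchLength,
                 droopAngle = droopAngle,
                 surfaceNoiseSigma = surfaceNoiseSigma,
                 stemPointFraction = stemPointFraction,
                 totalPointsRaw = as.integer(totalPointsRaw),
                 seed = as.integer(seed), preset = preset),
            class = "PanicleParams")
}

# Stalk centerline: quadratic lateral bend, parameter t in [0,1].
stemCenterline <- function(p, t) {
  cbind(p$stemCurvature * p$stemLength * t^2, 0, p$stemLength * t)
}

# Branch curve from the apex: fixed azimuth, elevation decreasing linearly
# from 1.2 rad by droopAngle along the arc; integrated numerically.
branchCurve <- function(p, azimuth, t) {
  res <- 200L
  tt <- seq(0, 1, length.out = res)
  elev <- 1.2 - p$droopAngle * tt
  dir <- cbind(cos(elev) * cos(azimuth), cos(elev) * sin(azimuth), sin(elev))
  step <- p$branchLength * p$stemLength / (res - 1L)
  path <- apply(dir * step, 2L, cumsum)
  path <- rbind(0, path[-res, , drop = FALSE])
  apex <- stemCenterline(p, 1)[1L, ]
  pos <- path[pmax(1L, pmin(res, round(t * (res - 1L)) + 1L)), , drop = FALSE]
  sweep(pos, 2L, apex, "+")
}

samplePerp <- function(n) {
  th <- stats::runif(n, 0, 2 * pi)
  cbind(cos(th), sin(th), 0)
}

# Points on an ellipsoid surface with major axis along `axis`.
sampleEllipsoid <- function(n, center, semi, axis) {
  g <- matrix(stats::rnorm(3L * n), n, 3L)
  g <- g / sqrt(rowSums(g^2))
  g <- sweep(g, 2L, semi, "*")
  a <- axis / sqrt(sum(axis^2))
  b <- c(1, 0, 0)
  if (abs(sum(a * b)) > 0.9) b <- c(0, 1, 0)
  u <- b - sum(b * a) * a; u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  R <- cbind(a, u, v)  # maps local x (major) onto the branch direction
  sweep(g %*% t(R), 2L, center, "+")
}

#' Generate one synthetic labeled panicle cloud
#'
#' @param params A [panicleParams()] bundle.
#' @param details If `TRUE`, also return the generating primitives (stalk
#'   centerline samples, grain centers and radii) for oracle-style checks.
#' @return A [LabeledCloud-class] with exactly `params$totalPointsRaw`
#'   points (label 0 = stem, 1 = panicle), or a list
#'   `(cloud, stemCurve, grainCenters, grainSemi)` when `details = TRUE`.
#' @examples
#' cl <- generatePanicle(panicleParams(totalPointsRaw = 500, seed = 7))
#' table(cloudLabels(cl))
#' @export
generatePanicle <- function(params = panicleParams(), details = FALSE) {
  p <- params
  withSeed(p$seed, {
    N <- p$totalPointsRaw
    nStem <- max(1L, min(N - 1L, round(p$stemPointFraction * N)))
    nEar <- N - nStem

    # stalk surface
    t <- stats::runif(nStem)
    ctr <- stemCenterline(p, t)
    stemPts <- ctr + p$stemRadius * samplePerp(nStem)

    # branch azimuths evenly spread with jitter
    az <- 2 * pi * (seq_len(p$nBranches) - 1L) / p$nBranches +
      stats::runif(p$nBranches, -0.2, 0.2)
    nRachis <- round(0.2 * nEar)
    nGrainPts <- nEar - nRachis

    rachisPts <- NULL
    if (nRachis > 0L) {
      b <- sample.int(p$nBranches, nRachis, replace = TRUE)
      tb <- stats::runif(nRachis)
      rp <- matrix(0, nRachis, 3L)
      for (bi in seq_len(p$nBranches)) {
        sel <- b == bi
        if (any(sel)) rp[sel, ] <- branchCurve(p, az[bi], tb[sel])
      }
      rachisPts <- rp + 0.004 * p$stemLength * samplePerp(nRachis)
    }

    # grain centers along each branch
    nGrains <- p$nBranches * p$grainsPerBranch
    gt <- seq(0.15, 1, length.out = p$grainsPerBranch)
    centers <- matrix(0, nGrains, 3L)
    axes <- matrix(0, nGrains, 3L)
    gi <- 1L
    for (bi in seq_len(p$nBranches)) {
      cc <- branchCurve(p, az[bi], gt)
      nxt <- branchCurve(p, az[bi], pmin(1, gt + 0.05))
      for (g in seq_len(p$grainsPerBranch)) {
        centers[gi, ] <- cc[g, ] + stats::rnorm(3L, 0, 0.005 * p$stemLength)
        d <- nxt[g, ] - cc[g, ]
        if (sum(d^2) < 1e-12) d <- c(0, 0, 1)
        axes[gi, ] <- d
        gi <- gi + 1L
      }
    }
    semi <- p$grainAxes * p$stemLength
    alloc <- rep(nGrainPts %/% nGrains, nGrains)
    extra <- nGrainPts - sum(alloc)
    if (extra > 0L) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
    grainPts <- vector("list", nGrains)
    for (g in seq_len(nGrains)) {
      if (alloc[g] > 0L)
        grainPts[[g]] <- sampleEllipsoid(alloc[g], centers[g, ], semi,
                                         axes[g, ])
    }
    earPts <- rbind(do.call(rbind, grainPts), rachisPts)

    coords <- rbind(stemPts, earPts)
    labels <- c(rep(0L, nStem), rep(1L, nrow(earPts)))
    if (p$surfaceNoiseSigma > 0) {
      coords <- coords + matrix(stats::rnorm(length(coords), 0,
                                             p$surfaceNoiseSigma *
                                               p$stemLength),
                                nrow(coords), 3L)
    }
    cloud <- LabeledCloud(coords, labels,
                          name = sprintf("synthetic_panicle_seed%d", p$seed))
    if (!details) return(cloud)
    list(cloud = cloud,
         stemCurve = stemCenterline(p, seq(0, 1, length.out = 200L)),
         stemRadius = p$stemRadius,
         grainCenters = centers, grainSemi = semi)
  })
}

#' Generate a synthetic labeled dataset
#'
#' Draws `n` panicle clouds with per-cloud parameter jitter (+/- 20% on
#' lengths and counts), runs each through the preprocessing pipeline to a
#' uniform point count, and assigns train/test split tags.
#'
#' @param n Number of clouds.
#' @param params Base [panicleParams()]; per-cloud values are jittered
#'   around it.
#' @param seed Master seed (overrides `params$seed`).
#' @param targetN Uniform point count after preprocessing.
#' @param trainFraction Fraction of clouds tagged "train" (default 0.9,
#'   i.e. a 10% held-out test set).
#' @return A [CloudDataset-class] with split tags.
#' @export
generateDataset <- function(n, params = panicleParams(), seed = 1L,
                            targetN = 2048L, trainFraction = 0.9) {
  stopifnot(n >= 1L)
  jit <- function(x, s) x * stats::runif(1L, 0.8, 1.2)
  clouds <- vector("list", n)
  for (i in seq_len(n)) {
    si <- deriveSeed(seed, paste0("cloud", i))
    pi <- withSeed(si, {
      p <- params
      p$stemLength <- jit(p$stemLength)
      p$stemRadius <- jit(p$stemRadius)
      p$branchLength <- jit(p$branchLength)
      p$grainAxes <- p$grainAxes * stats::runif(1L, 0.8, 1.2)
      p$droopAngle <- jit(p$droopAngle)
      p$nBranches <- max(1L, as.integer(round(jit(p$nBranches))))
      p$grainsPerBranch <- max(1L, as.integer(round(jit(p$grainsPerBranch))))
      p
    })
    pi$seed <- deriveSeed(si, "generate")
    cl <- generatePanicle(pi)
    cfg <- preprocessConfig(targetN = targetN,
                            seed = deriveSeed(si, "fps"))
    cl <- preprocessPipeline(cl, cfg)
    cl@name <- sprintf("panicle_%03d", i)
    clouds[[i]] <- cl
  }
  nTest <- round((1 - trainFraction) * n)
  splits <- rep("train", n)
  if (nTest > 0L) {
    testIdx <- withSeed(deriveSeed(seed, "split"), sample.int(n, nTest))
    splits[testIdx] <- "test"
  }
  CloudDataset(clouds, splits)
}
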