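#' Augmentation configuration
#'
#' Magnitudes for the label-preserving transforms used to expand the
#' training set: rotation (full circle about the vertical axis plus a small
#' random tilt), multiplicative scaling, half-space cropping with refill,
#' and additive Gaussian coordinate noise. The scanned stem axis is
#' approximately vertical, so full rotation is applied about z only.
#'
#' @param rotMaxTilt Maximum tilt angle about a random horizontal axis
#'   (radians, default 10 degrees).
#' @param scaleRange Length-2 multiplicative range `[lo, hi]`.
#' @param cropFraction Maximum fraction of points removable by one random
#'   half-space crop; must be < 0.5.
#' @param noiseSigma Std of additive Gaussian noise, unit-cube units.
#' @param nAugment Augmented copies per source cloud.
#' @param seed Integer seed.
#' @return A validated list of class `AugmentConfig`.
#' @export
augmentConfig <- function(rotMaxTilt = 10 * pi / 180,
                          scaleRange = c(0.8, 1.25), cropFraction = 0.2,
                          noiseSigma = 0.01, nAugment = 3L, seed = 1L) {
  stopifnot(length(scaleRange) == 2L, scaleRange[1L] > 0,
            scaleRange[1L] <= scaleRange[2L],
            cropFraction >= 0, cropFraction < 0.5,
            noiseSigma >= 0, nAugment >= 0L, rotMaxTilt >= 0)
  structure(list(rotMaxTilt = rotMaxTilt, scaleRange = scaleRange,
                 cropFraction = cropFraction, noiseSigma = noiseSigma,
                 nAugment = as.integer(nAugment), seed = as.integer(seed)),
            class = "AugmentConfig")
}

rotationAbout <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Random rotation
#'
#' A uniform rotation about the vertical (z) axis followed by a tilt of at
#' most `maxTilt` radians about a random horizontal axis. An isometry about
#' the origin; labels unchanged. Draws from the caller's RNG stream.
#'
#' @param cloud A [LabeledCloud-class].
#' @param maxTilt Maximum tilt angle in radians.
#' @return The rotated [LabeledCloud-class].
#' @export
randomRotate <- function(cloud, maxTilt = 10 * pi / 180) {
  ang <- stats::runif(1L, 0, 2 * pi)
  phi <- stats::runif(1L, 0, 2 * pi)
  tilt <- stats::runif(1L, 0, maxTilt)
  R <- rotationAbout(c(cos(phi), sin(phi), 0), tilt) %*%
       rotationAbout(c(0, 0, 1), ang)
  replaceCoords(cloud, cloudCoords(cloud) %*% t(R))
}

#' Random multiplicative scaling
#'
#' @param cloud A [LabeledCloud-class].
#' @param scaleRange Length-2 range `[lo, hi]` of the uniform scale draw.
#' @return The scaled [LabeledCloud-class].
#' @export
randomScale <- function(cloud, scaleRange = c(0.8, 1.25)) {
  s <- stats::runif(1L, scaleRange[1L], scaleRange[2L])
  replaceCoords(cloud, cloudCoords(cloud) * s)
}

#' Random half-space crop with refill
#'
#' Deletes at most `cropFraction` of the points on one side of a random
#' plane through the centroid, then restores the original point count by
#' resampling survivors (farthest-point-sampling-guided, with a small
#' positional jitter) so the fixed network input size is preserved. If a
#' crop would remove an entire class the plane is redrawn, up to 10 times,
#' after which the cloud is returned unchanged.
#'
#' @param cloud A labeled [LabeledCloud-class].
#' @param cropFraction Maximum removable fraction.
#' @return A [LabeledCloud-class] with the same point count.
#' @export
randomCrop <- function(cloud, cropFraction = 0.2) {
  if (cropFraction <= 0) return(cloud)
  co <- cloudCoords(cloud)
  labs <- cloudLabels(cloud)
  n <- nrow(co)
  frac <- stats::runif(1L, 0, cropFraction)
  nDrop <- floor(frac * n)
  for (try in seq_len(10L)) {
    normal <- stats::rnorm(3L)
    normal <- normal / sqrt(sum(normal^2))
    proj <- as.vector(co %*% normal)
    drop <- order(proj)[seq_len(nDrop)]
    keep <- if (nDrop > 0L) setdiff(seq_len(n), drop) else seq_len(n)
    if (is.null(labs) || length(unique(labs[keep])) ==
        length(unique(labs))) {
      if (nDrop == 0L) return(cloud)
      surv <- subsetCloud(cloud, keep)
      # refill: spatially uniform picks among survivors, jittered
      fill <- fpsIndices(cloudCoords(surv), min(nDrop, nPoints(surv)),
                         fpsGeometricStart(cloudCoords(surv)))
      fill <- fill[(seq_len(nDrop) - 1L) %% length(fill) + 1L]
      diag <- sqrt(sum((apply(co, 2L, max) - apply(co, 2L, min))^2))
      jit <- matrix(stats::rnorm(3L * nDrop, 0, 0.005 * diag), nDrop, 3L)
      newCo <- rbind(cloudCoords(surv), cloudCoords(surv)[fill, ,
                                                          drop = FALSE] + jit)
      newLab <- if (!is.null(labs)) c(cloudLabels(surv),
                                      cloudLabels(surv)[fill]) else NULL
      return(LabeledCloud(newCo, newLab, cloudName(cloud)))
    }
  }
  cloud
}

#' Additive Gaussian coordinate noise
#'
#' @param cloud A [LabeledCloud-class].
#' @param noiseSigma Standard deviation of the iid offsets.
#' @return The jittered [LabeledCloud-class].
#' @export
addGaussianNoise <- function(cloud, noiseSigma = 0.01) {
  if (noiseSigma <= 0) return(cloud)
  co <- cloudCoords(cloud)
  replaceCoords(cloud, co + matrix(stats::rnorm(length(co), 0, noiseSigma),
                                   nrow(co), 3L))
}

#' Expand a dataset by label-preserving augmentation
#'
#' Each training-split cloud receives `cfg$nAugment` augmented copies
#' (rotate, scale, crop, noise, in that order); originals are retained and
#' held-out test clouds are never augmented. Copies are renamed with an
#' `_augK_s<seed>` suffix and the whole operation is deterministic under
#' `cfg$seed`.
#'
#' @param ds A [CloudDataset-class].
#' @param cfg An [augmentConfig()] bundle.
#' @return The expanded [CloudDataset-class].
#' @export
augmentDataset <- function(ds, cfg = augmentConfig()) {
  stopifnot(is(ds, "CloudDataset"))
  splits <- splitTags(ds)
  if (is.null(splits)) splits <- rep("train", length(ds))
  outClouds <- cloudList(ds)
  outSplits <- splits
  for (i in seq_along(cloudList(ds))) {
    if (splits[i] != "train") next
    src <- ds[[i]]
    for (a in seq_len(cfg$nAugment)) {
      s <- deriveSeed(cfg$seed, paste0(cloudName(src), "_aug", a))
      aug <- withSeed(s, {
        cl <- randomRotate(src, cfg$rotMaxTilt)
        cl <- randomScale(cl, cfg$scaleRange)
        cl <- randomCrop(cl, cfg$cropFraction)
        addGaussianNoise(cl, cfg$noiseSigma)
      })
      aug@name <- sprintf("%s_aug%d_s%d", cloudName(src), a, s)
      outClouds <- c(outClouds, aug)
      outSplits <- c(outSplits, "train")
    }
  }
  CloudDataset(outClouds, if (!is.null(splitTags(ds))) outSplits else NULL)
}
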