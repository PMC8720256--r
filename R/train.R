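#' Training configuration
#'
#' Defaults follow the published schedule: Adam at learning rate 0.01,
#' batches of 8, at most 50 epochs, and reduce-on-plateau that halves the
#' learning rate (floor `minLr` = 0) when the epoch training loss has not
#' improved for more than `plateauPatience` = 5 epochs. "No improvement" is
#' a strict decrease of more than `plateauTol` below the best loss seen.
#'
#' @param lr Initial Adam learning rate.
#' @param batchSize Clouds per optimizer step.
#' @param maxEpochs Maximum training epochs.
#' @param plateauPatience Epochs without improvement tolerated before a
#'   learning-rate drop.
#' @param plateauFactor Multiplicative drop factor.
#' @param minLr Learning-rate floor.
#' @param plateauTol Minimum decrease that counts as an improvement.
#' @param seed Integer seed governing initialization, shuffling and
#'   dropout.
#' @param verbose Print one line per epoch.
#' @return A validated list of class `TrainConfig`.
#' @export
trainConfig <- function(lr = 0.01, batchSize = 8L, maxEpochs = 50L,
                        plateauPatience = 5L, plateauFactor = 0.5,
                        minLr = 0, plateauTol = 1e-4, seed = 1L,
                        verbose = FALSE) {
  stopifnot(lr > 0, batchSize >= 1L, maxEpochs >= 1L,
            plateauFactor > 0, plateauFactor < 1, minLr >= 0,
            plateauPatience >= 1L)
  structure(list(lr = lr, batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 plateauPatience = as.integer(plateauPatience),
                 plateauFactor = plateauFactor, minLr = minLr,
                 plateauTol = plateauTol, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "TrainConfig")
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' Stateful scheduler monitoring a per-epoch loss stream: when the loss has
#' failed to improve (strict decrease by more than `tol`) for more than
#' `patience` consecutive epochs, the learning rate is multiplied by
#' `factor` (never below `minLr`) and the wait counter resets.
#'
#' @param lr Initial learning rate.
#' @param patience Tolerated epochs without improvement.
#' @param factor Multiplicative drop.
#' @param minLr Floor.
#' @param tol Improvement tolerance.
#' @return A function `f(loss)` returning the learning rate to use after
#'   observing that epoch's loss.
#' @examples
#' sched <- plateauScheduler(0.01)
#' rates <- vapply(rep(1.0, 15), sched, numeric(1))
#' rates[7]   # first halving: patience exceeded at epoch 7
#' @export
plateauScheduler <- function(lr, patience = 5L, factor = 0.5, minLr = 0,
                             tol = 1e-4) {
  best <- Inf
  wait <- 0L
  function(loss) {
    if (loss < best - tol) {
      best <<- loss
      wait <<- 0L
    } else {
      wait <<- wait + 1L
      if (wait > patience) {
        lr <<- max(minLr, lr * factor)
        wait <<- 0L
      }
    }
    lr
  }
}

#' Binary cross-entropy loss of a two-channel sigmoid head
#'
#' Each point contributes both channels: the class-1 channel is supervised
#' with the true label and the class-0 channel with its complement, so the
#' two redundant sigmoid outputs are both trained. The reported value is
#' the per-point mean (averaged over points and the two channels):
#' a maximally uncertain prediction (both channels 0.5) costs ln 2 per
#' point. Probabilities are clipped at 1e-7 for numerical stability.
#'
#' @param probs N x 2 probability matrix in (0,1).
#' @param labels Length-N true labels in \{0,1\}.
#' @return Nonnegative per-point mean loss.
#' @export
crossentropyLoss <- function(probs, labels) {
  probs <- as.matrix(probs)
  if (nrow(probs) != length(labels))
    stop("probs rows and labels length differ")
  if (ncol(probs) != 2L) stop("probs must have 2 columns")
  bceLoss(probs, cbind(1 - labels, labels, deparse.level = 0))
}

#' Pointwise segmentation accuracy
#'
#' Fraction of points whose predicted label equals the true label.
#'
#' @param predLabels,trueLabels Equal-length integer label vectors.
#' @return Accuracy in [0,1].
#' @export
segmentationAccuracy <- function(predLabels, trueLabels) {
  if (length(predLabels) != length(trueLabels))
    stop("label vectors must have equal length")
  if (length(predLabels) == 0L) stop("empty label vectors")
  mean(predLabels == trueLabels)
}

#' Confusion counts for one class
#'
#' @param predLabels,trueLabels Label vectors in \{0,1\}.
#' @param cls The class treated as positive.
#' @return List with `tp`, `fp`, `fn`, `tn`.
#' @export
confusionCounts <- function(predLabels, trueLabels, cls = 1L) {
  p <- predLabels == cls
  t <- trueLabels == cls
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
       tn = sum(!p & !t))
}

#' Intersection over union
#'
#' IoU = TP / (FP + TP + FN). When a class is absent from both prediction
#' and truth the ratio is undefined and reported as 1 (perfect agreement on
#' absence), with an `absent` attribute flagging the case.
#'
#' @param counts A [confusionCounts()] list.
#' @return IoU in [0,1].
#' @export
iou <- function(counts) {
  denom <- counts$fp + counts$tp + counts$fn
  if (denom == 0) return(structure(1.0, absent = TRUE))
  counts$tp / denom
}

#' Evaluate a model on a set of clouds
#'
#' Pools confusion counts over all clouds, then reports overall accuracy,
#' per-class and mean IoU, and the mean cross-entropy loss.
#'
#' @param clouds List of labeled [LabeledCloud-class] objects at the
#'   network input size, or a [CloudDataset-class] (optionally restricted
#'   via `split`).
#' @param spec An [architectureSpec()].
#' @param params Model parameters.
#' @param split When `clouds` is a dataset with split tags: evaluate only
#'   this split (`"test"`, `"train"`, or `"all"`).
#' @param geoms Optional list of precomputed geometries (internal reuse).
#' @return List with `accuracy`, `iouPerClass` (named length-2), `meanIoU`,
#'   `loss`, and `nClouds`.
#' @export
evaluateModel <- function(clouds, spec, params, split = "all",
                          geoms = NULL) {
  if (is(clouds, "CloudDataset")) {
    keep <- seq_len(length(clouds))
    tags <- splitTags(clouds)
    if (split != "all" && !is.null(tags)) keep <- which(tags == split)
    clouds <- cloudList(clouds)[keep]
    if (!is.null(geoms)) geoms <- geoms[keep]
  }
  if (!length(clouds)) stop("no clouds to evaluate")
  tot <- list(`0` = list(tp = 0, fp = 0, fn = 0, tn = 0),
              `1` = list(tp = 0, fp = 0, fn = 0, tn = 0))
  losses <- numeric(length(clouds))
  nCorrect <- 0; nTotal <- 0
  for (i in seq_along(clouds)) {
    cl <- clouds[[i]]
    geom <- if (!is.null(geoms)) geoms[[i]] else
      buildGeometry(cloudCoords(cl), spec)
    probs <- p3dForwardFull(geom, spec, params, "eval")$probs
    y <- cloudLabels(cl)
    losses[i] <- crossentropyLoss(probs, y)
    pred <- predictLabels(probs)
    nCorrect <- nCorrect + sum(pred == y)
    nTotal <- nTotal + length(y)
    for (cls in c(0L, 1L)) {
      cc <- confusionCounts(pred, y, cls)
      key <- as.character(cls)
      tot[[key]] <- Map(`+`, tot[[key]], cc)
    }
  }
  iouPC <- c(`0` = as.numeric(iou(tot[["0"]])),
             `1` = as.numeric(iou(tot[["1"]])))
  list(accuracy = nCorrect / nTotal, iouPerClass = iouPC,
       meanIoU = mean(iouPC), loss = mean(losses),
       nClouds = length(clouds))
}

#' Train the segmentation network
#'
#' Adam optimization of the two-channel cross-entropy over shuffled
#' mini-batches, with reduce-on-plateau scheduling on the epoch training
#' loss (the held-out split is never used for scheduling). Per-epoch
#' train/test loss, accuracy and mean IoU are logged, and the parameters
#' with the best test mean IoU are retained as the returned checkpoint.
#' Fully deterministic under `cfg$seed`.
#'
#' @param ds A split-tagged [CloudDataset-class] whose clouds are at the
#'   network input size.
#' @param spec An [architectureSpec()].
#' @param cfg A [trainConfig()].
#' @param initialParams Optional warm-start parameters.
#' @return List with `params` (best checkpoint), `finalParams`, `history`
#'   (one row per epoch), `bestEpoch`, `spec`, `cfg`.
#' @export
trainModel <- function(ds, spec = tinyArchitectureSpec(),
                       cfg = trainConfig(), initialParams = NULL) {
  stopifnot(is(ds, "CloudDataset"))
  tags <- splitTags(ds)
  if (is.null(tags)) tags <- rep("train", length(ds))
  trainIdx <- which(tags == "train")
  testIdx <- which(tags == "test")
  if (!length(trainIdx)) stop("dataset contains no training clouds")
  clouds <- cloudList(ds)
  geoms <- lapply(clouds, function(cl) buildGeometry(cloudCoords(cl), spec))

  params <- if (is.null(initialParams)) {
    initParams(spec, deriveSeed(cfg$seed, "init"))
  } else initialParams
  mAdam <- zerosLike(params)
  vAdam <- zerosLike(params)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  tA <- 0
  lr <- cfg$lr
  sched <- plateauScheduler(cfg$lr, cfg$plateauPatience, cfg$plateauFactor,
                            cfg$minLr, cfg$plateauTol)
  hist <- vector("list", cfg$maxEpochs)
  best <- list(iou = -Inf, params = params, epoch = 0L)

  for (epoch in seq_len(cfg$maxEpochs)) {
    epochLoss <- withSeed(deriveSeed(cfg$seed, paste0("epoch", epoch)), {
      perm <- trainIdx[sample.int(length(trainIdx))]
      batchStarts <- seq(1L, length(perm), by = cfg$batchSize)
      bl <- numeric(length(batchStarts))
      for (b in seq_along(batchStarts)) {
        members <- perm[batchStarts[b]:min(length(perm),
                                           batchStarts[b] +
                                             cfg$batchSize - 1L)]
        acc <- NULL
        lsum <- 0
        for (ci in members) {
          lg <- panicle3dLossGrad(cloudCoords(clouds[[ci]]),
                                  cloudLabels(clouds[[ci]]), spec, params,
                                  mode = "train", geom = geoms[[ci]])
          lsum <- lsum + lg$loss
          acc <- if (is.null(acc)) lg$grads else
            mapParams(`+`, acc, lg$grads)
        }
        nb <- length(members)
        grads <- mapParams(function(g) g / nb, acc)
        bl[b] <- lsum / nb
        tA <- tA + 1
        mAdam <- mapParams(function(m, g) b1 * m + (1 - b1) * g, mAdam,
                           grads)
        vAdam <- mapParams(function(v, g) b2 * v + (1 - b2) * g^2, vAdam,
                           grads)
        bc1 <- 1 - b1^tA; bc2 <- 1 - b2^tA
        params <- mapParams(function(p, m, v) {
          p - lr * (m / bc1) / (sqrt(v / bc2) + epsA)
        }, params, mAdam, vAdam)
      }
      mean(bl)
    })

    trainEval <- evaluateModel(clouds[trainIdx], spec, params,
                               geoms = geoms[trainIdx])
    testEval <- if (length(testIdx)) {
      evaluateModel(clouds[testIdx], spec, params, geoms = geoms[testIdx])
    } else NULL
    monIoU <- if (!is.null(testEval)) testEval$meanIoU else
      trainEval$meanIoU
    if (monIoU > best$iou) {
      best <- list(iou = monIoU, params = params, epoch = epoch)
    }
    hist[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, trainLoss = epochLoss,
      trainEvalLoss = trainEval$loss, trainAcc = trainEval$accuracy,
      trainIoU = trainEval$meanIoU,
      testLoss = if (is.null(testEval)) NA_real_ else testEval$loss,
      testAcc = if (is.null(testEval)) NA_real_ else testEval$accuracy,
      testIoU = if (is.null(testEval)) NA_real_ else testEval$meanIoU)
    if (cfg$verbose) {
      message(sprintf(
        "epoch %2d lr %.4g trainLoss %.4f trainIoU %.3f testIoU %s",
        epoch, lr, epochLoss, trainEval$meanIoU,
        if (is.null(testEval)) "-" else sprintf("%.3f", testEval$meanIoU)))
    }
    lr <- sched(epochLoss)
  }
  list(params = best$params, finalParams = params,
       history = do.call(rbind, hist), bestEpoch = best$epoch,
       spec = spec, cfg = cfg)
}

#' Skip-connection ablation harness
#'
#' Trains three models that differ only in their skip-connection wiring —
#' long and short on, long only, short only — and tabulates the final
#' training and validation (held-out split) losses.
#'
#' @param ds A split-tagged [CloudDataset-class].
#' @param spec Base [architectureSpec()] (its skip flags are overridden per
#'   setting).
#' @param cfg A [trainConfig()].
#' @return A data.frame with columns `setting`, `longSkips`, `shortSkips`,
#'   `trainLoss`, `valLoss`, `valIoU`, plus attribute `"fits"` holding the
#'   three fitted models.
#' @export
ablationRun <- function(ds, spec = tinyArchitectureSpec(),
                        cfg = trainConfig()) {
  settings <- list(
    `long+short` = c(long = TRUE, short = TRUE),
    `long only`  = c(long = TRUE, short = FALSE),
    `short only` = c(long = FALSE, short = TRUE))
  fits <- vector("list", length(settings))
  rows <- vector("list", length(settings))
  for (i in seq_along(settings)) {
    sp <- spec
    sp$longSkips <- unname(settings[[i]]["long"])
    sp$shortSkips <- unname(settings[[i]]["short"])
    fit <- trainModel(ds, sp, cfg)
    last <- fit$history[nrow(fit$history), ]
    rows[[i]] <- data.frame(setting = names(settings)[i],
                            longSkips = sp$longSkips,
                            shortSkips = sp$shortSkips,
                            trainLoss = last$trainLoss,
                            valLoss = last$testLoss,
                            valIoU = last$testIoU)
    fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}
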