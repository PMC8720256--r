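test_that("cross-entropy reproduces closed forms and an independent
           summation oracle", {
  # perfect prediction costs (numerically) nothing
  y <- c(1L, 0L, 1L, 1L)
  perfect <- cbind(1 - y, y)
  expect_lt(crossentropyLoss(perfect, y), 1e-5)

  # maximal uncertainty costs ln 2 per point
  half <- matrix(0.5, 10, 2)
  expect_equal(crossentropyLoss(half, rep(1L, 10)), log(2),
               tolerance = 1e-9)

  # independent oracle on random instances
  withr::with_seed(71, {
    for (rep in 1:10) {
      n <- sample(5:40, 1)
      probs <- matrix(runif(2 * n, 0.01, 0.99), n, 2)
      y <- sample(0:1, n, replace = TRUE)
      oracle <- 0
      for (i in seq_len(n)) {
        t1 <- y[i]; t0 <- 1 - y[i]
        oracle <- oracle -
          (t0 * log(probs[i, 1]) + (1 - t0) * log(1 - probs[i, 1])) -
          (t1 * log(probs[i, 2]) + (1 - t1) * log(1 - probs[i, 2]))
      }
      expect_equal(crossentropyLoss(probs, y), oracle / (2 * n),
                   tolerance = 1e-9)
    }
  })
  expect_error(crossentropyLoss(half, rep(1L, 3)), "differ")
})

test_that("accuracy is the exact agreement fraction", {
  expect_equal(segmentationAccuracy(c(1, 0, 1), c(1, 0, 1)), 1.0)
  expect_equal(segmentationAccuracy(c(1, 0, 1), c(0, 1, 0)), 0.0)
  expect_equal(segmentationAccuracy(c(rep(1, 8), 0, 0),
                                    c(rep(1, 8), 1, 1)), 0.8)
  expect_error(segmentationAccuracy(integer(0), integer(0)), "empty")
})

test_that("IoU follows TP/(FP+TP+FN) with the absent-class convention", {
  expect_equal(iou(list(tp = 8, fp = 1, fn = 1, tn = 5)), 0.8)
  expect_equal(as.numeric(iou(list(tp = 10, fp = 0, fn = 0, tn = 0))), 1.0)
  expect_equal(iou(list(tp = 0, fp = 3, fn = 4, tn = 0)), 0.0)
  absent <- iou(list(tp = 0, fp = 0, fn = 0, tn = 9))
  expect_equal(as.numeric(absent), 1.0)
  expect_true(attr(absent, "absent"))

  pred <- c(1L, 1L, 0L, 1L, 0L)
  truth <- c(1L, 0L, 0L, 1L, 1L)
  cc <- confusionCounts(pred, truth, 1L)
  expect_equal(cc, list(tp = 2L, fp = 1L, fn = 1L, tn = 1L))
  expect_equal(sum(unlist(cc)), 5L)
})

test_that("a coin-flip predictor scores chance-level accuracy", {
  withr::with_seed(72, {
    n <- 10000
    truth <- sample(0:1, n, replace = TRUE)
    pred <- sample(0:1, n, replace = TRUE)
    acc <- segmentationAccuracy(pred, truth)
    expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n))
  })
})

test_that("the plateau scheduler halves after each exhausted patience
           window and respects the floor", {
  sched <- plateauScheduler(0.01, patience = 5, factor = 0.5, minLr = 0)
  lrs <- vapply(rep(1.0, 15), sched, numeric(1))
  expect_equal(lrs[1:6], rep(0.01, 6))   # best set at epoch 1, wait 1..5
  expect_equal(lrs[7], 0.005)            # wait exceeds patience
  expect_equal(lrs[8:12], rep(0.005, 5))
  expect_equal(lrs[13], 0.0025)

  # improvement resets the wait counter
  sched2 <- plateauScheduler(0.01, patience = 2, factor = 0.5)
  stream <- c(1.0, 0.9, 0.9, 0.8, 0.8, 0.8, 0.8)
  lrs2 <- vapply(stream, sched2, numeric(1))
  expect_equal(lrs2, c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.005))

  # floor is honored
  sched3 <- plateauScheduler(0.01, patience = 1, factor = 0.5,
                             minLr = 0.004)
  lrs3 <- vapply(rep(1, 10), sched3, numeric(1))
  expect_equal(min(lrs3), 0.004)
})

test_that("training is bit-reproducible under a fixed seed and learns on
           easy synthetic data", {
  p <- panicleParams(totalPointsRaw = 800L, preset = "easy")
  spec <- tinyArchitectureSpec(nPoints = c(128L, 64L, 48L, 40L, 36L),
                               channels = c(3L, 8L, 8L, 12L, 12L),
                               decoderChannels = c(12L, 12L, 8L, 8L))
  ds <- generateDataset(12, p, seed = 4, targetN = 128L,
                        trainFraction = 0.75)
  cfg <- trainConfig(maxEpochs = 6L, batchSize = 4L, seed = 11L)
  fit1 <- trainModel(ds, spec, cfg)
  fit2 <- trainModel(ds, spec, cfg)
  expect_identical(fit1$history$trainLoss, fit2$history$trainLoss)
  expect_identical(fit1$finalParams, fit2$finalParams)
  # eval-mode loss on the training split decreases over the run
  expect_lt(fit1$history$trainEvalLoss[6], fit1$history$trainEvalLoss[1])
  expect_equal(nrow(fit1$history), 6L)
  expect_true(all(c("trainLoss", "testLoss", "testIoU", "lr") %in%
                  names(fit1$history)))

  rep <- evaluateModel(ds, spec, fit1$params, split = "test")
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  expect_length(rep$iouPerClass, 2L)
  expect_equal(rep$nClouds, 3L)

  expect_error(trainModel(CloudDataset(cloudList(ds),
                                       rep("test", length(ds))),
                          spec, cfg),
               "no training clouds")
})
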