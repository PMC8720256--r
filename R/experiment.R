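#' Scaled-down end-to-end segmentation experiment
#'
#' The packaged stand-in for a full training run: generates a synthetic
#' labeled dataset, trains the reduced network on the training split and
#' reports held-out metrics. With the defaults (80 easy-preset clouds of
#' 512 points, 64 train / 16 test, 10 epochs) it runs in minutes on one
#' CPU core and the network reliably separates stem from panicle.
#'
#' @param seed Master seed for generation and training.
#' @param nClouds Total synthetic clouds.
#' @param trainFraction Fraction tagged "train".
#' @param targetN Points per cloud after preprocessing.
#' @param epochs Training epochs.
#' @param spec Network [architectureSpec()].
#' @param preset Generator preset (`"easy"` or `"realistic"`).
#' @param rawPoints Generator points before downsampling.
#' @param batchSize Optimizer batch size.
#' @param verbose Print per-epoch progress.
#' @return List with `report` (held-out evaluation), `trainReport`, `fit`
#'   (the [trainModel()] result) and `ds`.
#' @export
scaledExperiment <- function(seed = 1L, nClouds = 80L, trainFraction = 0.8,
                             targetN = 512L, epochs = 10L,
                             spec = tinyArchitectureSpec(),
                             preset = "easy", rawPoints = 2000L,
                             batchSize = 8L, verbose = FALSE) {
  params <- panicleParams(totalPointsRaw = rawPoints, preset = preset)
  ds <- generateDataset(nClouds, params, seed = deriveSeed(seed, "data"),
                        targetN = targetN, trainFraction = trainFraction)
  cfg <- trainConfig(maxEpochs = epochs, batchSize = batchSize,
                     seed = deriveSeed(seed, "train"), verbose = verbose)
  fit <- trainModel(ds, spec, cfg)
  report <- evaluateModel(ds, spec, fit$params, split = "test")
  trainReport <- evaluateModel(ds, spec, fit$params, split = "train")
  list(report = report, trainReport = trainReport, fit = fit, ds = ds)
}
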