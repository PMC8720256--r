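#' Architecture description of the segmentation network
#'
#' The encoder is a stack of SE-Inception-PointConv blocks that shrinks the
#' cloud along `nPoints` (farthest-point-sampled centroids) while widening
#' features along `channels`; the decoder mirrors it with interpolation +
#' PointConv stages ending at `decoderChannels[last]` channels over the full
#' input cloud, followed by dropout and a two-channel sigmoid head. Defaults
#' follow the published design: 2048 input points down to a 36-point
#' bottleneck, features widened from the 3 raw coordinates to 512 and
#' decoded back to 128, two-scale Inception neighborhoods k1 = 16 and
#' k2 = 32, SE compression factor 4, and toggleable long (encoder-to-decoder
#' concatenation) and short (within-block residual) skip connections.
#' Intermediate schedule values are near-geometric interpolations between
#' the fixed endpoints.
#'
#' @param nPoints Strictly decreasing encoder point counts per level.
#' @param channels Feature channels per level; first entry must be 3.
#' @param decoderChannels One output width per decoder stage
#'   (`length(nPoints) - 1` entries).
#' @param k1,k2 The two Inception neighborhood sizes, `k1 < k2`.
#' @param kDecoder Neighborhood size of the decoder-stage convolutions.
#' @param kInterp Neighbors used by decoder feature interpolation.
#' @param weightnetHidden Hidden width of the kernel-function MLP.
#' @param seReduction SE channel compression factor.
#' @param dropoutRate Dropout probability before the output head.
#' @param outChannels Output channels (2: stem and panicle).
#' @param longSkips,shortSkips Skip-connection toggles (the ablation
#'   switches).
#' @param useDensity Apply inverse-density weighting inside convolutions.
#' @param densityLearned Remap the density weight with a small learned MLP
#'   instead of using the plain reciprocal.
#' @param kDensity,densityBandwidth Inverse-density estimate parameters
#'   (unit-cube units).
#' @return A validated list of class `ArchitectureSpec`.
#' @export
architectureSpec <- function(nPoints = c(2048L, 1024L, 256L, 64L, 36L),
                             channels = c(3L, 64L, 128L, 256L, 512L),
                             decoderChannels = c(256L, 256L, 128L, 128L),
                             k1 = 16L, k2 = 32L, kDecoder = 16L,
                             kInterp = 3L, weightnetHidden = 16L,
                             seReduction = 4L, dropoutRate = 0.5,
                             outChannels = 2L, longSkips = TRUE,
                             shortSkips = TRUE, useDensity = TRUE,
                             densityLearned = FALSE, kDensity = 16L,
                             densityBandwidth = 0.05) {
  nPoints <- as.integer(nPoints); channels <- as.integer(channels)
  decoderChannels <- as.integer(decoderChannels)
  if (length(nPoints) < 2L || any(diff(nPoints) >= 0L))
    stop("nPoints must be strictly decreasing with at least 2 levels")
  if (length(channels) != length(nPoints))
    stop("channels must have one entry per point level")
  if (channels[1L] != 3L)
    stop("the first channel count is the 3 raw coordinates")
  if (length(decoderChannels) != length(nPoints) - 1L)
    stop("decoderChannels must have one entry per decoder stage")
  if (any(channels[-1L] %% 2L != 0L))
    stop("encoder output channels must be even (split across two branches)")
  if (!(k1 < k2)) stop("k1 must be smaller than k2")
  stopifnot(dropoutRate >= 0, dropoutRate < 1, seReduction >= 1L,
            kInterp >= 1L, weightnetHidden >= 1L, densityBandwidth > 0)
  structure(list(nPoints = nPoints, channels = channels,
                 decoderChannels = decoderChannels, k1 = as.integer(k1),
                 k2 = as.integer(k2), kDecoder = as.integer(kDecoder),
                 kInterp = as.integer(kInterp),
                 weightnetHidden = as.integer(weightnetHidden),
                 seReduction = as.integer(seReduction),
                 dropoutRate = dropoutRate,
                 outChannels = as.integer(outChannels),
                 longSkips = isTRUE(longSkips),
                 shortSkips = isTRUE(shortSkips),
                 useDensity = isTRUE(useDensity),
                 densityLearned = isTRUE(densityLearned),
                 kDensity = as.integer(kDensity),
                 densityBandwidth = densityBandwidth),
            class = "ArchitectureSpec")
}

#' Reduced architecture for CPU-scale experiments
#'
#' Same wiring as the default network at a fraction of the size: 512-point
#' inputs and channel widths 3-16-32-64-128. Used throughout the test suite
#' and the packaged scaled-down experiments.
#'
#' @param ... Overrides forwarded to [architectureSpec()].
#' @export
tinyArchitectureSpec <- function(...) {
  args <- list(nPoints = c(512L, 256L, 128L, 64L, 36L),
               channels = c(3L, 16L, 32L, 64L, 128L),
               decoderChannels = c(64L, 64L, 32L, 32L))
  override <- list(...)
  args[names(override)] <- override
  do.call(architectureSpec, args)
}

nStages <- function(spec) length(spec$nPoints) - 1L

#' Initialize all learnable parameters of the network
#'
#' @param spec An [architectureSpec()].
#' @param seed Integer seed for the variance-scaling draws.
#' @return Nested named list of parameter arrays (the `ModelParams`
#'   container); serializable and round-trippable via checkpoints.
#' @export
initParams <- function(spec, seed = 1L) {
  withSeed(seed, {
    S <- nStages(spec)
    ch <- spec$channels
    enc <- vector("list", S)
    for (i in seq_len(S)) {
      half <- ch[i + 1L] %/% 2L
      st <- list(
        b1 = initPointConvParams(ch[i], half, spec$weightnetHidden,
                                 spec$k1, spec$densityLearned),
        b2 = initPointConvParams(ch[i], half, spec$weightnetHidden,
                                 spec$k2, spec$densityLearned),
        se = initSEParams(ch[i + 1L], spec$seReduction))
      if (spec$shortSkips) {
        st$proj <- list(
          W = matrix(stats::rnorm(ch[i] * ch[i + 1L], 0, sqrt(2 / ch[i])),
                     ch[i], ch[i + 1L]),
          b = rep(0, ch[i + 1L]))
      }
      enc[[i]] <- st
    }
    L <- S + 1L
    dec <- vector("list", S)
    for (j in seq_len(S)) {
      d <- L - j
      cs <- if (j == 1L) ch[L] else spec$decoderChannels[j - 1L]
      cskip <- ch[d]
      fin <- cs + if (spec$longSkips) cskip else 0L
      cd <- spec$decoderChannels[j]
      dec[[j]] <- list(
        fuse = list(W = matrix(stats::rnorm(fin * cd, 0, sqrt(2 / fin)),
                               fin, cd),
                    # small positive bias: features are smooth across
                    # points, so a zero-bias ReLU unit can die for the
                    # whole stage at init
                    b = rep(0.1, cd)),
        pc = initPointConvParams(cd, cd, spec$weightnetHidden,
                                 spec$kDecoder, spec$densityLearned))
    }
    cl <- spec$decoderChannels[S]
    head <- list(W = matrix(stats::rnorm(cl * spec$outChannels, 0,
                                         sqrt(1 / cl)),
                            cl, spec$outChannels),
                 b = rep(0, spec$outChannels))
    list(enc = enc, dec = dec, head = head)
  })
}

#' Closed-form learnable parameter count
#'
#' The parameter count is a pure function of the architecture description;
#' this computes it analytically (it is asserted against the initialized
#' model in the test suite).
#'
#' @param spec An [architectureSpec()].
#' @return Integer parameter count.
#' @export
paramCount <- function(spec) {
  h <- spec$weightnetHidden
  pc <- function(cin, cout) {
    n <- 3 * h + h + h * cin + cin + cin * cout + cout
    if (spec$densityLearned) n <- n + (8 + 8 + 8 + 1)
    n
  }
  se <- function(C) {
    hid <- max(1L, ceiling(C / spec$seReduction))
    C * hid + hid + hid * C + C
  }
  S <- nStages(spec); ch <- spec$channels; L <- S + 1L
  total <- 0
  for (i in seq_len(S)) {
    half <- ch[i + 1L] %/% 2L
    total <- total + 2 * pc(ch[i], half) + se(ch[i + 1L])
    if (spec$shortSkips) total <- total + ch[i] * ch[i + 1L] + ch[i + 1L]
  }
  for (j in seq_len(S)) {
    d <- L - j
    cs <- if (j == 1L) ch[L] else spec$decoderChannels[j - 1L]
    fin <- cs + if (spec$longSkips) ch[d] else 0L
    cd <- spec$decoderChannels[j]
    total <- total + fin * cd + cd + pc(cd, cd)
  }
  total + spec$decoderChannels[S] * spec$outChannels + spec$outChannels
}

# ---- static geometry -------------------------------------------------------

# Everything in the network that depends only on point positions (FPS
# pyramid, neighbor tables, offsets, densities, interpolation weights) is
# precomputed once per cloud and reused across epochs.
buildGeometry <- function(coords, spec) {
  coords <- asCoordMatrix(coords)
  L <- length(spec$nPoints)
  if (nrow(coords) != spec$nPoints[1L])
    stop("input has ", nrow(coords), " points; the network expects ",
         spec$nPoints[1L])
  P <- vector("list", L)
  P[[1L]] <- coords
  for (l in 2:L) {
    prev <- P[[l - 1L]]
    idx <- fpsIndices(prev, spec$nPoints[l], fpsGeometricStart(prev))
    P[[l]] <- prev[idx, , drop = FALSE]
  }
  s <- vector("list", L)
  for (l in seq_len(L)) {
    if (spec$useDensity) {
      si <- inverseDensity(P[[l]], min(spec$kDensity, nrow(P[[l]])),
                           spec$densityBandwidth)
      s[[l]] <- si / mean(si)  # unit mean keeps layer scales stable
    } else {
      s[[l]] <- rep(1, nrow(P[[l]]))
    }
  }
  S <- L - 1L
  enc <- vector("list", S)
  for (i in seq_len(S)) {
    enc[[i]] <- list(
      g1 = makeNeighborhood(P[[i + 1L]], P[[i]], s[[i]],
                            min(spec$k1, spec$nPoints[i])),
      g2 = makeNeighborhood(P[[i + 1L]], P[[i]], s[[i]],
                            min(spec$k2, spec$nPoints[i])))
  }
  dec <- vector("list", S)
  for (j in seq_len(S)) {
    d <- L - j
    dec[[j]] <- list(
      iw = interpWeights(P[[d]], P[[d + 1L]], spec$kInterp),
      gs = makeNeighborhood(P[[d]], P[[d]], s[[d]],
                            min(spec$kDecoder, spec$nPoints[d])))
  }
  list(P = P, s = s, enc = enc, dec = dec, L = L)
}

# ---- full model forward / backward -----------------------------------------

encStageFwd <- function(feat, ge, pe, spec) {
  Fe <- relu(feat)
  r1 <- pcForward(ge$g1, Fe, pe$b1, "linear")
  r2 <- pcForward(ge$g2, Fe, pe$b2, "linear")
  Cc <- cbind(r1$out, r2$out)
  se <- seFwd(Cc, pe$se)
  out <- se$out
  mp <- NULL
  if (spec$shortSkips) {
    G <- addBias(Fe %*% pe$proj$W, pe$proj$b)
    mp <- maxPoolFwd(G, ge$g1)
    out <- out + mp$out
  }
  list(out = out, cache = list(feat = feat, Fe = Fe, r1 = r1$cache,
                               r2 = r2$cache, se = se$cache, mp = mp,
                               ge = ge))
}

encStageBwd <- function(dOut, cache, pe, spec) {
  dFe <- matrix(0, nrow(cache$Fe), ncol(cache$Fe))
  projGrads <- NULL
  if (spec$shortSkips) {
    dG <- maxPoolBwd(dOut, cache$mp$amax, cache$ge$g1, nrow(cache$Fe),
                     ncol(dOut))
    projGrads <- list(W = crossprod(cache$Fe, dG), b = colSums(dG))
    dFe <- dFe + dG %*% t(pe$proj$W)
  }
  seb <- seBwd(dOut, cache$se, pe$se)
  half <- ncol(dOut) %/% 2L
  b1b <- pcBackward(seb$dF[, seq_len(half), drop = FALSE], cache$r1, pe$b1)
  b2b <- pcBackward(seb$dF[, half + seq_len(half), drop = FALSE], cache$r2,
                    pe$b2)
  dFe <- dFe + b1b$dF + b2b$dF
  # same element order as the stage's parameter list: b1, b2, se[, proj]
  grads <- list(b1 = b1b$grads, b2 = b2b$grads, se = seb$grads)
  if (spec$shortSkips) grads$proj <- projGrads
  list(grads = grads, dF = dFe * (cache$feat > 0))
}

decStageFwd <- function(Fsparse, Fskip, gd, pd, spec) {
  I <- applyInterp(gd$iw, Fsparse)
  X <- if (spec$longSkips) cbind(I, Fskip) else I
  pre <- addBias(X %*% pd$fuse$W, pd$fuse$b)
  Fu <- relu(pre)
  r <- pcForward(gd$gs, Fu, pd$pc, "relu")
  list(out = r$out, cache = list(X = X, pre = pre, pc = r$cache, gd = gd,
                                 cs = ncol(Fsparse),
                                 nSparse = nrow(Fsparse)))
}

decStageBwd <- function(dOut, cache, pd, spec) {
  pcb <- pcBackward(dOut, cache$pc, pd$pc)
  dpre <- pcb$dF * (cache$pre > 0)
  dWf <- crossprod(cache$X, dpre)
  dbf <- colSums(dpre)
  dX <- dpre %*% t(pd$fuse$W)
  dI <- dX[, seq_len(cache$cs), drop = FALSE]
  dFskip <- if (spec$longSkips) {
    dX[, cache$cs + seq_len(ncol(dX) - cache$cs), drop = FALSE]
  } else NULL
  dFsparse <- applyInterpBackward(cache$gd$iw, dI, cache$nSparse)
  list(grads = list(fuse = list(W = dWf, b = dbf), pc = pcb$grads),
       dFsparse = dFsparse, dFskip = dFskip)
}

p3dForwardFull <- function(geom, spec, params, mode = "eval",
                           dropoutSeed = NULL) {
  S <- geom$L - 1L
  feats <- vector("list", geom$L)   # features at each level, level 1 = xyz
  feats[[1L]] <- geom$P[[1L]]
  encCaches <- vector("list", S)
  for (i in seq_len(S)) {
    r <- encStageFwd(feats[[i]], geom$enc[[i]], params$enc[[i]], spec)
    feats[[i + 1L]] <- r$out
    encCaches[[i]] <- r$cache
  }
  decCaches <- vector("list", S)
  cur <- feats[[geom$L]]
  for (j in seq_len(S)) {
    d <- geom$L - j
    r <- decStageFwd(cur, feats[[d]], geom$dec[[j]], params$dec[[j]], spec)
    cur <- r$out
    decCaches[[j]] <- r$cache
  }
  mask <- NULL
  Fdrop <- cur
  if (mode == "train" && spec$dropoutRate > 0) {
    draw <- function() (matrix(stats::runif(length(cur)), nrow(cur)) >=
                          spec$dropoutRate) / (1 - spec$dropoutRate)
    mask <- if (is.null(dropoutSeed)) draw() else withSeed(dropoutSeed,
                                                           draw())
    Fdrop <- cur * mask
  }
  logits <- addBias(Fdrop %*% params$head$W, params$head$b)
  probs <- sigmoid(logits)
  list(probs = probs, logits = logits,
       cache = list(encCaches = encCaches, decCaches = decCaches,
                    feats = feats, Fdrop = Fdrop, mask = mask, cur = cur))
}

p3dBackwardFull <- function(dLogits, fw, geom, spec, params) {
  S <- geom$L - 1L
  cache <- fw$cache
  grads <- list(enc = vector("list", S), dec = vector("list", S))
  grads$head <- list(W = crossprod(cache$Fdrop, dLogits),
                     b = colSums(dLogits))
  dF <- dLogits %*% t(params$head$W)
  if (!is.null(cache$mask)) dF <- dF * cache$mask
  dFeat <- vector("list", geom$L)  # grads wrt encoder-level features
  for (l in seq_len(geom$L)) {
    dFeat[[l]] <- matrix(0, nrow(cache$feats[[l]]),
                         ncol(cache$feats[[l]]))
  }
  dDec <- dF
  for (j in rev(seq_len(S))) {
    d <- geom$L - j
    r <- decStageBwd(dDec, cache$decCaches[[j]], params$dec[[j]], spec)
    grads$dec[[j]] <- r$grads
    if (spec$longSkips) dFeat[[d]] <- dFeat[[d]] + r$dFskip
    if (j > 1L) dDec <- r$dFsparse
    else dFeat[[geom$L]] <- dFeat[[geom$L]] + r$dFsparse
  }
  for (i in rev(seq_len(S))) {
    r <- encStageBwd(dFeat[[i + 1L]], cache$encCaches[[i]],
                     params$enc[[i]], spec)
    grads$enc[[i]] <- r$grads
    if (i > 1L) dFeat[[i]] <- dFeat[[i]] + r$dF
  }
  grads
}

#' Run the full network on one cloud
#'
#' @param coords N x 3 coordinate matrix (or a [LabeledCloud-class]); N must
#'   equal `spec$nPoints[1]`.
#' @param spec An [architectureSpec()].
#' @param params Model parameters from [initParams()] or a checkpoint.
#' @param mode `"eval"` (deterministic) or `"train"` (dropout active).
#' @param geom Optional precomputed geometry (internal reuse).
#' @param dropoutSeed Optional seed for the dropout mask in train mode.
#' @return N x 2 matrix of per-point sigmoid probabilities (columns: stem,
#'   panicle), rows aligned 1:1 with the input points.
#' @export
panicle3dForward <- function(coords, spec, params,
                             mode = c("eval", "train"), geom = NULL,
                             dropoutSeed = NULL) {
  mode <- match.arg(mode)
  if (is(coords, "LabeledCloud")) coords <- cloudCoords(coords)
  if (is.null(geom)) geom <- buildGeometry(coords, spec)
  p3dForwardFull(geom, spec, params, mode, dropoutSeed)$probs
}

#' Convert per-point probabilities to hard labels
#'
#' A point takes the class whose probability channel exceeds 0.5; when both
#' or neither channel exceeds 0.5 the larger channel wins, with exact ties
#' resolved to class 1 (panicle).
#'
#' @param probs N x 2 probability matrix (columns: class 0, class 1).
#' @return Integer vector of labels in \{0,1\}.
#' @export
predictLabels <- function(probs) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 2L) stop("probs must have 2 columns")
  ifelse(probs[, 2L] >= probs[, 1L], 1L, 0L)
}

#' Loss and parameter gradients for one cloud
#'
#' Forward pass plus full backpropagation of the binary cross-entropy loss.
#' Exposed for optimizer loops and gradient verification.
#'
#' @inheritParams panicle3dForward
#' @param labels Length-N true labels in \{0,1\}.
#' @return List with `loss` (per-point mean), `probs`, and `grads` (same
#'   nested shape as `params`).
#' @export
panicle3dLossGrad <- function(coords, labels, spec, params,
                              mode = c("train", "eval"), geom = NULL,
                              dropoutSeed = NULL) {
  mode <- match.arg(mode)
  if (is(coords, "LabeledCloud")) {
    if (is.null(labels)) labels <- cloudLabels(coords)
    coords <- cloudCoords(coords)
  }
  if (is.null(geom)) geom <- buildGeometry(coords, spec)
  fw <- p3dForwardFull(geom, spec, params, mode, dropoutSeed)
  n <- nrow(fw$probs)
  targets <- cbind(1 - labels, labels, deparse.level = 0)
  loss <- bceLoss(fw$probs, targets)
  dLogits <- (fw$probs - targets) / (2 * n)
  grads <- p3dBackwardFull(dLogits, fw, geom, spec, params)
  list(loss = loss, probs = fw$probs, grads = grads)
}

bceLoss <- function(probs, targets, clip = 1e-7) {
  p <- pmin(pmax(probs, clip), 1 - clip)
  mean(-(targets * log(p) + (1 - targets) * log(1 - p)))
}

# ---- parameter utilities ---------------------------------------------------

flattenParams <- function(params) unlist(params, use.names = TRUE)

unflattenParams <- function(vec, skeleton) {
  cursor <- 0L
  walk <- function(node) {
    if (is.list(node)) return(lapply(node, walk))
    n <- length(node)
    out <- vec[cursor + seq_len(n)]
    cursor <<- cursor + n
    attributes(out) <- attributes(node)
    out
  }
  walk(skeleton)
}

mapParams <- function(f, ...) {
  trees <- list(...)
  walk <- function(...) {
    nodes <- list(...)
    if (is.list(nodes[[1L]])) {
      out <- mapply(walk, ..., SIMPLIFY = FALSE)
      names(out) <- names(nodes[[1L]])
      return(out)
    }
    do.call(f, nodes)
  }
  do.call(walk, trees)
}

zerosLike <- function(params) mapParams(function(x) x * 0, params)

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture description alongside the
#' parameters so a model is restorable from the file alone.
#'
#' @param params Model parameters.
#' @param spec The [architectureSpec()] they instantiate.
#' @param path Checkpoint path (`.rds`).
#' @return `saveCheckpoint`: `path`, invisibly. `loadCheckpoint`: a list
#'   with `params` and `spec`.
#' @export
saveCheckpoint <- function(params, spec, path) {
  saveRDS(list(format = "panicle3D-checkpoint-v1", spec = spec,
               params = params), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "panicle3D-checkpoint-v1"))
    stop(path, " is not a panicle3D checkpoint")
  x[c("params", "spec")]
}
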