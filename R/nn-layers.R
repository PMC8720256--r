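# Low-level neural building blocks. Every forward returns a cache carrying
# exactly the intermediates its backward needs; backwards return parameter
# gradients in the same nested shape AND order as the parameters (tree
# updates pair nodes positionally) plus the gradient with respect to the
# input features.

addBias <- function(x, b) sweep(x, 2L, b, "+")

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# ---- continuous convolution (PointConv) ------------------------------------

#' One continuous point convolution
#'
#' The discretized continuous convolution over a k-nearest-neighbor
#' neighborhood: for each centroid, the learned kernel function W (an MLP on
#' the 3D offset of each neighbor) is evaluated per neighbor and per input
#' channel, multiplied elementwise by the neighbor's features and its
#' inverse-density weight S, summed over the neighborhood, and passed
#' through a linear channel-mixing map and optional ReLU.
#'
#' This is the reference entry point used by tests and by users exploring a
#' single layer; inside the full model the same computation runs against a
#' precomputed geometry bundle.
#'
#' @param centroids Q x 3 output point positions.
#' @param reference N x 3 input point positions.
#' @param refFeatures N x Cin feature matrix over `reference`.
#' @param s Length-N inverse densities (use `rep(1, N)` to disable density
#'   compensation).
#' @param params Layer parameters from [initPointConvParams()].
#' @param k Neighborhood size.
#' @param activation `"relu"` or `"linear"`.
#' @return Q x Cout feature matrix over `centroids`.
#' @export
pointconvForward <- function(centroids, reference, refFeatures, s, params,
                             k, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  g <- makeNeighborhood(centroids, reference, s, k)
  pcForward(g, as.matrix(refFeatures), params, activation)$out
}

# Bundle of static geometry for one convolution: flattened neighbor indices
# (neighbor index varies fastest within each centroid), offsets and gathered
# inverse densities.
makeNeighborhood <- function(centroids, reference, s, k) {
  nn <- knnIndices(centroids, reference, k)
  q <- nrow(nn$idx)
  idxvec <- as.vector(t(nn$idx))
  off <- reference[idxvec, , drop = FALSE] -
    centroids[rep(seq_len(q), each = k), , drop = FALSE]
  list(idx = idxvec, off = off, sv = s[idxvec], Q = q, k = k,
       nRef = nrow(reference))
}

#' Initialize parameters for one PointConv layer
#'
#' Variance-scaling (He) initialization for the weight-function MLP and the
#' channel mixer; the kernel MLP bias starts at 0.5 so the layer begins
#' close to a density-weighted neighborhood sum, and the mixer is scaled by
#' the neighborhood size so summed activations stay O(1).
#'
#' @param cin,cout Input/output channel counts.
#' @param hidden Hidden width of the weight-function MLP.
#' @param k Neighborhood size the layer will run with (scales the mixer
#'   init).
#' @param densityLearned Add a small MLP that remaps the inverse-density
#'   weight nonlinearly (the learned variant of the density function).
#' @return Named list of parameter matrices.
#' @export
initPointConvParams <- function(cin, cout, hidden = 16L, k = 16L,
                                densityLearned = FALSE) {
  p <- list(
    # b1 strictly positive: self-neighbors have exactly zero offsets, and a
    # zero bias would park those pre-activations on the ReLU kink
    W1 = matrix(stats::rnorm(3L * hidden, 0, sqrt(2 / 3)), 3L, hidden),
    b1 = rep(0.01, hidden),
    W2 = matrix(stats::rnorm(hidden * cin, 0, sqrt(2 / hidden)), hidden,
                cin),
    b2 = rep(0.5, cin),
    Wm = matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin) / k), cin,
                cout),
    bm = rep(0, cout))
  if (densityLearned) {
    h <- 8L
    p$dW1 <- matrix(stats::rnorm(h, 0, 1), 1L, h)
    p$db1 <- rep(0, h)
    p$dW2 <- matrix(stats::rnorm(h, 0, sqrt(2 / h)), h, 1L)
    p$db2 <- 0.55  # softplus(0.55) ~ 1: start near the plain reciprocal
  }
  p
}

pcForward <- function(g, feat, p, activation = "relu") {
  if (g$nRef != nrow(feat)) stop("feature rows must match reference points")
  cin <- ncol(feat)
  if (!is.null(p$dW1)) {
    sm <- matrix(g$sv, ncol = 1L)
    dh <- addBias(sm %*% p$dW1, p$db1)
    da <- relu(dh)
    dt <- addBias(da %*% p$dW2, p$db2)
    sEff <- as.vector(softplus(dt))
    dcache <- list(sm = sm, dh = dh, da = da, dt = dt)
  } else {
    sEff <- g$sv
    dcache <- NULL
  }
  Fn <- feat[g$idx, , drop = FALSE] * sEff
  H1 <- addBias(g$off %*% p$W1, p$b1)
  A1 <- relu(H1)
  K <- addBias(A1 %*% p$W2, p$b2)
  Pr <- K * Fn
  Ssum <- colSums(array(Pr, dim = c(g$k, g$Q, cin)), dims = 1L)
  if (cin == 1L) Ssum <- matrix(Ssum, ncol = 1L)
  Pre <- addBias(Ssum %*% p$Wm, p$bm)
  out <- if (activation == "relu") relu(Pre) else Pre
  list(out = out,
       cache = list(g = g, feat = feat, Fn = Fn, H1 = H1, A1 = A1, K = K,
                    Ssum = Ssum, Pre = Pre, cin = cin, sEff = sEff,
                    dcache = dcache, activation = activation))
}

pcBackward <- function(dOut, cache, p) {
  g <- cache$g
  dPre <- if (cache$activation == "relu") dOut * (cache$Pre > 0) else dOut
  dWm <- crossprod(cache$Ssum, dPre)
  dbm <- colSums(dPre)
  dSsum <- dPre %*% t(p$Wm)
  dPr <- dSsum[rep(seq_len(g$Q), each = g$k), , drop = FALSE]
  dK <- dPr * cache$Fn
  dFn <- dPr * cache$K
  dA1 <- dK %*% t(p$W2)
  dW2 <- crossprod(cache$A1, dK)
  db2 <- colSums(dK)
  dH1 <- dA1 * (cache$H1 > 0)
  dW1 <- crossprod(g$off, dH1)
  db1 <- colSums(dH1)
  grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wm = dWm, bm = dbm)

  gathered <- cache$feat[g$idx, , drop = FALSE]
  dGath <- dFn * cache$sEff
  dF <- matrix(0, g$nRef, cache$cin)
  rs <- rowsum(dGath, group = g$idx)
  dF[as.integer(rownames(rs)), ] <- rs

  if (!is.null(cache$dcache)) {
    dc <- cache$dcache
    dsEff <- rowSums(dFn * gathered)
    ddt <- dsEff * stats::plogis(dc$dt)  # d softplus = sigmoid
    ddt <- matrix(ddt, ncol = 1L)
    dda <- ddt %*% t(p$dW2)
    ddh <- dda * (dc$dh > 0)
    # appended in the same order as the parameter list: dW1,db1,dW2,db2
    grads$dW1 <- crossprod(dc$sm, ddh)
    grads$db1 <- colSums(ddh)
    grads$dW2 <- crossprod(dc$da, ddt)
    grads$db2 <- sum(ddt)
  }
  list(grads = grads, dF = dF)
}

# ---- squeeze-and-excitation ------------------------------------------------

#' Initialize a squeeze-and-excitation block
#'
#' @param channels Feature channel count.
#' @param reduction Bottleneck compression factor (default 4).
#' @return Named list of parameters.
#' @export
initSEParams <- function(channels, reduction = 4L) {
  hid <- max(1L, ceiling(channels / reduction))
  list(W1 = matrix(stats::rnorm(channels * hid, 0, sqrt(2 / channels)),
                   channels, hid),
       b1 = rep(0, hid),
       W2 = matrix(stats::rnorm(hid * channels, 0, sqrt(2 / hid)), hid,
                   channels),
       b2 = rep(0, channels))  # zero bias: gates start near 0.5
}

#' Squeeze-and-excitation channel recalibration
#'
#' Squeeze: per-channel mean over all points. Excitation: a two-layer
#' bottleneck (compression factor `reduction`) with ReLU then sigmoid,
#' producing one gate in (0,1) per channel. Output: input rescaled per
#' channel by its gate.
#'
#' @param features N x C feature matrix.
#' @param params Parameters from [initSEParams()].
#' @return N x C recalibrated features.
#' @export
seForward <- function(features, params) {
  seFwd(as.matrix(features), params)$out
}

seFwd <- function(feat, p) {
  if (ncol(feat) != nrow(p$W1))
    stop("feature channels (", ncol(feat), ") do not match SE block (",
         nrow(p$W1), ")")
  z <- matrix(colMeans(feat), 1L)
  pre1 <- addBias(z %*% p$W1, p$b1)
  a <- relu(pre1)
  pre2 <- addBias(a %*% p$W2, p$b2)
  e <- sigmoid(pre2)
  out <- sweep(feat, 2L, as.vector(e), "*")
  list(out = out, cache = list(feat = feat, z = z, pre1 = pre1, a = a,
                               e = e, n = nrow(feat)))
}

seBwd <- function(dOut, cache, p) {
  e <- as.vector(cache$e)
  dF <- sweep(dOut, 2L, e, "*")
  de <- matrix(colSums(dOut * cache$feat), 1L)
  dpre2 <- de * cache$e * (1 - cache$e)
  dW2 <- crossprod(cache$a, dpre2)
  db2 <- as.vector(dpre2)
  da <- dpre2 %*% t(p$W2)
  dpre1 <- da * (cache$pre1 > 0)
  dW1 <- crossprod(cache$z, dpre1)
  db1 <- as.vector(dpre1)
  dz <- dpre1 %*% t(p$W1)
  dF <- dF + matrix(dz / cache$n, cache$n, ncol(dF), byrow = TRUE)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dF = dF)
}

# ---- neighborhood max pooling (short-skip path) ----------------------------

maxPoolFwd <- function(G, g) {
  q <- g$Q; k <- g$k; C <- ncol(G)
  Gk <- G[g$idx, , drop = FALSE]
  mx <- matrix(-Inf, q, C)
  amax <- matrix(1L, q, C)
  for (j in seq_len(k)) {
    rows <- seq.int(j, by = k, length.out = q)
    Gj <- Gk[rows, , drop = FALSE]
    upd <- Gj > mx
    amax[upd] <- j
    mx[upd] <- Gj[upd]
  }
  list(out = mx, amax = amax)
}

maxPoolBwd <- function(dOut, amax, g, nRef, C) {
  q <- g$Q; k <- g$k
  dGk <- matrix(0, q * k, C)
  for (j in seq_len(k)) {
    rows <- seq.int(j, by = k, length.out = q)
    sel <- amax == j
    tmp <- matrix(0, q, C)
    tmp[sel] <- dOut[sel]
    dGk[rows, ] <- tmp
  }
  dG <- matrix(0, nRef, C)
  rs <- rowsum(dGk, group = g$idx)
  dG[as.integer(rownames(rs)), ] <- rs
  dG
}
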