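test_that("pointconv with an all-ones kernel, unit density and identity mix
           is a plain neighborhood sum", {
  withr::with_seed(61, {
    ref <- matrix(runif(30), 10, 3)
    cent <- ref[1:4, ]
    feat <- matrix(rnorm(30), 10, 3)
    p <- initPointConvParams(3, 3, hidden = 4)
    p$W1[] <- 0; p$b1[] <- 0
    p$W2[] <- 0; p$b2[] <- 1      # kernel is identically one
    p$Wm <- diag(3); p$bm[] <- 0  # identity channel mix
    s <- rep(1, 10)
    out <- pointconvForward(cent, ref, feat, s, p, k = 5, "linear")
    nn <- bruteKnn(cent, ref, 5)
    expected <- t(apply(nn, 1, function(r) colSums(feat[r, ])))
    expect_equal(out, expected, tolerance = 1e-6)
  })
})

test_that("pointconv is linear in the features: zero input gives the bias
           pre-activation", {
  withr::with_seed(62, {
    ref <- matrix(runif(24), 8, 3)
    p <- initPointConvParams(2, 4, k = 3)
    out <- pointconvForward(ref[1:3, ], ref, matrix(0, 8, 2), rep(1, 8), p,
                            3, "linear")
    expect_equal(out, matrix(p$bm, 3, 4, byrow = TRUE), tolerance = 1e-12)
  })
})

test_that("pointconv on a duplicated reference matches the oracle, and
           halved density weights restore the original output", {
  withr::with_seed(63, {
    ref <- matrix(runif(27), 9, 3)
    cent <- ref[c(1, 5), ]
    feat <- matrix(rnorm(18), 9, 2)
    p <- initPointConvParams(2, 3, k = 4)
    s <- runif(9, 0.5, 2)
    base <- pointconvForward(cent, ref, feat, s, p, 4, "linear")

    dupRef <- rbind(ref, ref)
    dupFeat <- rbind(feat, feat)
    dup <- pointconvForward(cent, dupRef, dupFeat, rep(s, 2) / 2, p, 8,
                            "linear")
    expect_equal(dup, base, tolerance = 1e-4)
    # and the doubled instance agrees with the brute-force oracle
    oracle <- pointconvOracle(cent, dupRef, dupFeat, rep(s, 2) / 2, p, 8)
    expect_equal(dup, oracle, tolerance = 1e-6)
  })
})

test_that("squeeze-and-excitation gates lie in (0,1), pass an identity
           configuration, and match a hand-rolled oracle", {
  withr::with_seed(64, {
    feat <- matrix(rnorm(8 * 16), 8, 16)
    p <- initSEParams(16, 4)

    # saturate the second FC bias: gates ~ 1, output ~ input
    pid <- p; pid$W2[] <- 0; pid$b2[] <- 40
    expect_equal(seForward(feat, pid), feat, tolerance = 1e-9)

    fw <- panicle3D:::seFwd(feat, p)
    expect_true(all(fw$cache$e > 0 & fw$cache$e < 1))

    # independent oracle
    z <- colMeans(feat)
    gate <- 1 / (1 + exp(-(pmax(z %*% p$W1 + p$b1, 0) %*% p$W2 + p$b2)))
    expect_equal(fw$out, sweep(feat, 2, as.vector(gate), "*"),
                 tolerance = 1e-6)

    expect_error(seForward(feat[, 1:4], p), "channels")
  })
})

test_that("encoder block wiring: disabling the short skip leaves pure
           SE(concat(branches)), and identical branches coincide when the
           neighborhoods do", {
  spec <- toySpec(shortSkips = FALSE, k1 = 4L, k2 = 8L)
  withr::with_seed(65, {
    co <- matrix(runif(16 * 3), 16, 3)
    geom <- panicle3D:::buildGeometry(
      co, toySpec(nPoints = c(16L, 8L, 6L, 5L, 4L), k1 = 4L, k2 = 8L,
                  shortSkips = FALSE))
    params <- initParams(toySpec(nPoints = c(16L, 8L, 6L, 5L, 4L),
                                 k1 = 4L, k2 = 8L, shortSkips = FALSE), 1)
    pe <- params$enc[[1]]
    specOff <- toySpec(nPoints = c(16L, 8L, 6L, 5L, 4L), k1 = 4L, k2 = 8L,
                       shortSkips = FALSE)
    r <- panicle3D:::encStageFwd(geom$P[[1]], geom$enc[[1]], pe, specOff)
    # recompute by hand: two branches, concat, SE
    Fe <- pmax(geom$P[[1]], 0)
    b1 <- panicle3D:::pcForward(geom$enc[[1]]$g1, Fe, pe$b1, "linear")$out
    b2 <- panicle3D:::pcForward(geom$enc[[1]]$g2, Fe, pe$b2, "linear")$out
    expect_equal(r$out, seForward(cbind(b1, b2), pe$se), tolerance = 1e-12)
    expect_equal(dim(r$out), c(8L, 4L))

    # with N = k1 = k2 the two branch neighborhoods coincide; identical
    # parameters then give identical branch outputs
    spec2 <- architectureSpec(nPoints = c(8L, 4L), channels = c(3L, 4L),
                              decoderChannels = 4L, k1 = 8L, k2 = 16L)
    co2 <- matrix(runif(24), 8, 3)
    geom2 <- panicle3D:::buildGeometry(co2, spec2)
    p2 <- initParams(spec2, 2)
    p2$enc[[1]]$b2 <- p2$enc[[1]]$b1
    Fe2 <- pmax(co2, 0)
    o1 <- panicle3D:::pcForward(geom2$enc[[1]]$g1, Fe2, p2$enc[[1]]$b1,
                                "linear")$out
    o2 <- panicle3D:::pcForward(geom2$enc[[1]]$g2, Fe2, p2$enc[[1]]$b2,
                                "linear")$out
    expect_equal(o1, o2, tolerance = 1e-12)
  })
})

test_that("decoder stage reduces to concat + fuse + pointconv when sparse
           equals dense, and drops the skip when long skips are off", {
  withr::with_seed(66, {
    pts <- matrix(runif(30), 10, 3)
    featS <- matrix(rnorm(40), 10, 4)
    skip <- matrix(rnorm(20), 10, 2)
    gd <- list(iw = panicle3D:::interpWeights(pts, pts, 3),
               gs = panicle3D:::makeNeighborhood(pts, pts, rep(1, 10), 4))
    pd <- list(fuse = list(W = matrix(rnorm(6 * 5, 0, 0.3), 6, 5),
                           b = rep(0, 5)),
               pc = initPointConvParams(5, 5, k = 4))
    specOn <- toySpec(longSkips = TRUE)
    r <- panicle3D:::decStageFwd(featS, skip, gd, pd, specOn)
    # coincident interpolation is the identity
    expect_equal(r$cache$X[, 1:4], featS, tolerance = 1e-6)
    expect_equal(r$cache$X[, 5:6], skip)

    pdOff <- list(fuse = list(W = pd$fuse$W[1:4, , drop = FALSE],
                              b = pd$fuse$b),
                  pc = pd$pc)
    specOff <- toySpec(longSkips = FALSE)
    r2 <- panicle3D:::decStageFwd(featS, skip, gd, pdOff, specOff)
    expect_equal(ncol(r2$cache$X), 4L)
  })
})

test_that("the full forward yields aligned sigmoid probabilities,
           deterministic in eval mode and equivariant to permutation", {
  spec <- toySpec()
  withr::with_seed(67, {
    co <- matrix(runif(64 * 3), 64, 3)
    params <- initParams(spec, 3)
    p1 <- panicle3dForward(co, spec, params)
    expect_equal(dim(p1), c(64L, 2L))
    expect_true(all(p1 > 0 & p1 < 1))
    expect_identical(panicle3dForward(co, spec, params), p1)

    perm <- sample(64)
    p2 <- panicle3dForward(co[perm, ], spec, params)
    expect_equal(p2[order(perm), ], p1, tolerance = 1e-5)

    expect_error(panicle3dForward(co[1:10, ], spec, params), "expects")
  })
})

test_that("train-mode dropout is stochastic but seed-reproducible", {
  spec <- toySpec(dropoutRate = 0.5)
  withr::with_seed(68, {
    co <- matrix(runif(64 * 3), 64, 3)
    params <- initParams(spec, 4)
    a <- panicle3dForward(co, spec, params, mode = "train",
                          dropoutSeed = 5)
    b <- panicle3dForward(co, spec, params, mode = "train",
                          dropoutSeed = 5)
    c <- panicle3dForward(co, spec, params, mode = "train",
                          dropoutSeed = 6)
    expect_identical(a, b)
    expect_false(identical(a, c))
  })
})

test_that("probability thresholding follows the documented tie rule", {
  probs <- rbind(c(0.9, 0.1), c(0.2, 0.7), c(0.5, 0.5), c(0.6, 0.7),
                 c(0.4, 0.3))
  expect_equal(predictLabels(probs), c(0L, 1L, 1L, 1L, 0L))
})

test_that("the parameter count matches its closed form for default, tiny
           and ablated architectures", {
  for (spec in list(architectureSpec(), tinyArchitectureSpec(),
                    tinyArchitectureSpec(longSkips = FALSE),
                    tinyArchitectureSpec(shortSkips = FALSE),
                    tinyArchitectureSpec(densityLearned = TRUE))) {
    expect_equal(length(unlist(initParams(spec, 1))), paramCount(spec))
  }
  expect_equal(paramCount(architectureSpec()), 1069080)
})

test_that("skip toggles change exactly the documented parameter paths", {
  paths <- function(params) {
    unique(gsub("[0-9]+$", "", names(unlist(params))))
  }
  base <- paths(initParams(tinyArchitectureSpec(), 1))
  noShort <- paths(initParams(tinyArchitectureSpec(shortSkips = FALSE), 1))
  gone <- setdiff(base, noShort)
  expect_gt(length(gone), 0)
  expect_true(all(grepl("^enc\\.proj\\.", gone)))
  expect_length(setdiff(noShort, base), 0)

  # long skips change only the decoder fuse input widths
  pLong <- initParams(tinyArchitectureSpec(), 1)
  pNoLong <- initParams(tinyArchitectureSpec(longSkips = FALSE), 1)
  expect_identical(paths(pLong), paths(pNoLong))
  for (j in 1:4) {
    expect_gt(nrow(pLong$dec[[j]]$fuse$W), nrow(pNoLong$dec[[j]]$fuse$W))
    expect_identical(dim(pLong$dec[[j]]$pc$Wm),
                     dim(pNoLong$dec[[j]]$pc$Wm))
  }
})

test_that("checkpoints embed the spec and round-trip parameters exactly", {
  spec <- toySpec()
  params <- initParams(spec, 5)
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(params, spec, f)
  back <- loadCheckpoint(f)
  expect_identical(back$params, params)
  expect_identical(back$spec, spec)
})

test_that("the learned density remap variant runs and changes the output", {
  spec <- toySpec(densityLearned = TRUE)
  withr::with_seed(69, {
    co <- matrix(runif(64 * 3), 64, 3)
    params <- initParams(spec, 6)
    p1 <- panicle3dForward(co, spec, params)
    expect_true(all(p1 > 0 & p1 < 1))
    # finite-difference check one density-net parameter
    y <- sample(0:1, 64, replace = TRUE)
    geom <- panicle3D:::buildGeometry(co, spec)
    lg <- panicle3dLossGrad(co, y, spec, params, mode = "eval",
                            geom = geom)
    flat <- unlist(params)
    j <- which(names(flat) == "enc.b1.dW21")[1]
    eps <- 1e-5
    fp <- flat; fp[j] <- fp[j] + eps
    fm <- flat; fm[j] <- fm[j] - eps
    lp <- panicle3dLossGrad(co, y, spec,
                            panicle3D:::unflattenParams(fp, params),
                            mode = "eval", geom = geom)$loss
    lm <- panicle3dLossGrad(co, y, spec,
                            panicle3D:::unflattenParams(fm, params),
                            mode = "eval", geom = geom)$loss
    num <- (lp - lm) / (2 * eps)
    ana <- unlist(lg$grads)[j]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-8), 1e-3)
  })
})
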