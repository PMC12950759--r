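# Dual autoencoder: forward contracts, joint loss, gradients, training.

zeroAEParams <- function(cfg) {
  z <- function(nin, nout) list(W = matrix(0, nin, nout), b = rep(0, nout))
  p <- list(enc1 = z(cfg$inputDim, cfg$hiddenDim),
            enc2 = z(cfg$hiddenDim, cfg$latentDim),
            dec1 = z(cfg$latentDim, cfg$hiddenDim),
            dec2 = z(cfg$hiddenDim, cfg$inputDim))
  if (cfg$useBatchNorm) p$bn <- scCrossFuse:::initBatchNorm(cfg$hiddenDim)
  p
}

test_that("encode/decode honour shape contracts and degenerate parameters", {
  cfg <- aeConfig(4, hiddenDim = 6, latentDim = 2)
  p <- zeroAEParams(cfg)
  x <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("c", 1:3), NULL))
  z <- encodeCells(x, p, cfg)
  expect_equal(omicsValues(z), matrix(0, 3, 2, dimnames = list(paste0("c", 1:3), NULL)))
  xr <- decodeCells(matrix(0, 3, 2), p, cfg)
  expect_equal(xr, matrix(0, 3, 4))
  expect_equal(ncol(xr), cfg$inputDim)
  expect_error(encodeCells(matrix(0, 3, 5), p, cfg), "expects")
})

test_that("a 1-1-1 network with known weights matches a scalar oracle", {
  cfg <- aeConfig(1, hiddenDim = 1, latentDim = 1, useBatchNorm = FALSE)
  p <- zeroAEParams(cfg)
  p$enc1$W[1, 1] <- 2; p$enc1$b <- 0.5
  p$enc2$W[1, 1] <- -1; p$enc2$b <- 0.1
  x <- matrix(1.3, 1, 1, dimnames = list("c1", NULL))
  # tanh-approximation GELU, written out independently
  geluRef <- function(v) 0.5 * v * (1 + tanh(sqrt(2 / pi) * (v + 0.044715 * v^3)))
  h <- geluRef(2 * 1.3 + 0.5)
  expect_equal(as.numeric(omicsValues(encodeCells(x, p, cfg))),
               -h + 0.1, tolerance = 1e-12)
})

test_that("duplicated input rows give duplicated latent rows", {
  cfg <- aeConfig(5, hiddenDim = 8, latentDim = 3)
  p <- withr::with_seed(1, scCrossFuse:::initAE(cfg))
  x <- matrix(rnorm(10), 2, 5)
  x <- rbind(x, x[1, , drop = FALSE])
  rownames(x) <- c("a", "b", "a2")
  z <- omicsValues(encodeCells(x, p, cfg))
  expect_equal(z[1, ], z[3, ])
})

test_that("joint reconstruction loss matches closed forms and a loop oracle", {
  expect_equal(jointReconstructionLoss(diag(3), diag(3), diag(2), diag(2)), 0)
  expect_equal(jointReconstructionLoss(matrix(1), matrix(0),
                                       matrix(2), matrix(2), 0.5, 0.5), 0.5)
  set.seed(2)
  Xi <- matrix(rnorm(15), 5, 3); XiH <- matrix(rnorm(15), 5, 3)
  Xj <- matrix(rnorm(15), 5, 3); XjH <- matrix(rnorm(15), 5, 3)
  oracle <- 0
  for (i in 1:5) for (j in 1:3)
    oracle <- oracle + 0.3 * (Xi[i, j] - XiH[i, j])^2 / 15 +
      0.7 * (Xj[i, j] - XjH[i, j])^2 / 15
  expect_equal(jointReconstructionLoss(Xi, XiH, Xj, XjH, 0.3, 0.7), oracle,
               tolerance = 1e-12)
  expect_error(jointReconstructionLoss(Xi, XiH, Xj, XjH, 0.5, 0.6),
               "alpha \\+ beta")
})

test_that("loss is symmetric under modality swap and cell permutation", {
  set.seed(3)
  Xi <- matrix(rnorm(12), 4, 3); XiH <- Xi + 0.1
  Xj <- matrix(rnorm(20), 4, 5); XjH <- Xj - 0.2
  expect_equal(jointReconstructionLoss(Xi, XiH, Xj, XjH, 0.3, 0.7),
               jointReconstructionLoss(Xj, XjH, Xi, XiH, 0.7, 0.3))
  perm <- sample(4)
  expect_equal(jointReconstructionLoss(Xi, XiH, Xj, XjH, 0.4, 0.6),
               jointReconstructionLoss(Xi[perm, ], XiH[perm, ],
                                       Xj[perm, ], XjH[perm, ], 0.4, 0.6))
})

test_that("finite-difference gradients agree with backprop", {
  set.seed(4)
  x <- matrix(rnorm(12), 3, 4)
  cfg <- aeConfig(4, hiddenDim = 5, latentDim = 2)
  p <- scCrossFuse:::initAE(cfg)
  lossFn <- function(p)
    mean((x - scCrossFuse:::aeForward(x, p, cfg, training = TRUE)$xhat)^2)
  fw <- scCrossFuse:::aeForward(x, p, cfg, training = TRUE)
  bk <- scCrossFuse:::aeBackward(p, cfg, fw$cache,
                                 dXhat = 2 * (fw$xhat - x) / length(x))
  eps <- 1e-6
  for (nm in c("enc1", "enc2", "dec1", "dec2")) {
    p2 <- p; p2[[nm]]$W[1, 2] <- p[[nm]]$W[1, 2] + eps
    p3 <- p; p3[[nm]]$W[1, 2] <- p[[nm]]$W[1, 2] - eps
    fd <- (lossFn(p2) - lossFn(p3)) / (2 * eps)
    expect_equal(fd, bk$grads[[nm]]$W[1, 2], tolerance = 1e-4)
  }
})

test_that("joint training reduces the loss across seeds", {
  ds <- tinyPaired()
  red <- preprocessPair(ds$rna, ds$atac,
                        experimentConfig(nHvg = 100, nPcs = 10, nLsi = 10))
  for (seed in 1:3) {
    fit <- trainDualAE(red$rna, red$atac,
                       rnaConfig = aeConfig(10, hiddenDim = 32, latentDim = 8),
                       atacConfig = aeConfig(10, hiddenDim = 32, latentDim = 8),
                       epochs = 40, seed = seed)
    expect_lt(fit$history[40], fit$history[1])
  }
})

test_that("epochs = 0 returns the forward pass of the initialised network", {
  set.seed(5)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("c%d", 1:10), NULL))
  cfg <- aeConfig(4, hiddenDim = 6, latentDim = 2)
  fit <- trainDualAE(x, x, rnaConfig = cfg, atacConfig = cfg,
                     epochs = 0, seed = 9)
  p0 <- withr::with_seed(9, {
    list(rna = scCrossFuse:::initAE(cfg), atac = scCrossFuse:::initAE(cfg))
  })
  expect_equal(omicsValues(fit$Zi),
               omicsValues(encodeCells(x, p0$rna, cfg)))
})

test_that("cell-order mismatch is rejected with the discordant id", {
  x <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("c", 1:5), NULL))
  y <- x[c(1, 3, 2, 4, 5), ]
  expect_error(trainDualAE(x, y, epochs = 1), "c3")
})

test_that("latent space separates well-separated synthetic types", {
  ds <- tinyPaired()
  red <- preprocessPair(ds$rna, ds$atac,
                        experimentConfig(nHvg = 150, nPcs = 10, nLsi = 10))
  for (seed in 1:3) {
    fit <- trainDualAE(red$rna, red$atac,
                       rnaConfig = aeConfig(10, hiddenDim = 32, latentDim = 8),
                       atacConfig = aeConfig(10, hiddenDim = 32, latentDim = 8),
                       epochs = 60, seed = seed)
    expect_gt(silhouetteWidth(omicsValues(fit$Zi), ds$labels), 0)
  }
})

test_that("a linear autoencoder recovers rank-1 data to tiny error", {
  set.seed(6)
  u <- rnorm(20); v <- rnorm(4)
  x <- outer(u, v)
  rownames(x) <- sprintf("c%d", 1:20)
  cfg <- aeConfig(4, hiddenDim = 3, latentDim = 1, activation = "linear",
                  useBatchNorm = FALSE)
  fit <- trainDualAE(x, x, rnaConfig = cfg, atacConfig = cfg,
                     epochs = 800, lr = 1e-2, seed = 1)
  rec <- decodeCells(fit$Zi, fit$params$rna, cfg)
  expect_lt(mean((rec - x)^2), 1e-4)
})

test_that("checkpoints round-trip trained parameters", {
  set.seed(12)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("c%d", 1:10), NULL))
  cfg <- aeConfig(4, hiddenDim = 6, latentDim = 2)
  fit <- trainDualAE(x, x, rnaConfig = cfg, atacConfig = cfg,
                     epochs = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  writeCheckpoint(fit$params, path)
  back <- readCheckpoint(path)
  expect_identical(back, fit$params)
  expect_equal(omicsValues(encodeCells(x, back$rna, cfg)),
               omicsValues(fit$Zi))
})
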