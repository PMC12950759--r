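# Cross-attention, residual layer norm, FFN fusion, contrastive loss,
# baseline fusers and the joint fusion training loop.

test_that("scaled dot-product attention follows the closed forms", {
  # single key: output equals V regardless of Q
  Q <- matrix(rnorm(6), 3, 2)
  K <- matrix(c(1, 0.5), 1, 2)
  V <- matrix(c(3, -1), 1, 2)
  out <- scaledDotAttention(Q, K, V)
  expect_equal(unname(out[, 1]), rep(3, 3))
  expect_equal(unname(out[, 2]), rep(-1, 3))

  # identical keys: uniform weights, output is the column mean of V
  K2 <- matrix(1, 4, 2); V2 <- matrix(rnorm(8), 4, 2)
  out2 <- scaledDotAttention(Q, K2, V2)
  for (i in 1:3) expect_equal(out2[i, ], colMeans(V2), tolerance = 1e-12)

  # 2-key scalar oracle
  out3 <- scaledDotAttention(matrix(1), matrix(c(1, 0), 2, 1),
                             matrix(c(2, 0), 2, 1))
  w1 <- exp(1) / (exp(1) + exp(0))
  expect_equal(as.numeric(out3), w1 * 2, tolerance = 1e-12)
  expect_equal(attr(out3, "weights")[1, 1], w1, tolerance = 1e-12)
  expect_error(scaledDotAttention(Q, K2[1:3, ], V2), "equal row counts")
})

test_that("attention weights are row-stochastic for every head", {
  set.seed(1)
  Zi <- matrix(rnorm(40), 10, 4); Zj <- matrix(rnorm(40), 10, 4)
  cfg <- attentionConfig(nHeads = 2, modelDim = 4)
  res <- crossAttentionHeads(Zi, Zj, config = cfg, seed = 3)
  for (A in c(attr(res$headI, "weights"), attr(res$headJ, "weights"))) {
    expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
    expect_gte(min(A), 0)
  }
})

test_that("cross-attention matches a per-head loop oracle on a 3-cell toy", {
  set.seed(2)
  Zi <- matrix(rnorm(12), 3, 4); Zj <- matrix(rnorm(12), 3, 4)
  cfg <- attentionConfig(nHeads = 2, modelDim = 4)
  res <- crossAttentionHeads(Zi, Zj, config = cfg, seed = 11)
  oracle <- oracleCrossAttention(Zi, Zj, res$params, 2, cfg$headDim)
  expect_equal(unclass(res$headI), oracle$headI,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unclass(res$headJ), oracle$headJ,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("Zi = Zj with shared projections collapses both directions", {
  set.seed(3)
  Z <- matrix(rnorm(20), 5, 4)
  cfg <- attentionConfig(nHeads = 2, modelDim = 4)
  params <- withr::with_seed(4, list(
    dirI = scCrossFuse:::initAttnDirection(cfg),
    dirJ = NULL))
  params$dirJ <- params$dirI
  res <- crossAttentionHeads(Z, Z, params = params, config = cfg)
  expect_equal(unclass(res$headI), unclass(res$headJ), ignore_attr = TRUE)
})

test_that("one head reduces to single scaled dot-product attention", {
  set.seed(4)
  Zi <- matrix(rnorm(20), 5, 4); Zj <- matrix(rnorm(20), 5, 4)
  cfg <- attentionConfig(nHeads = 1, modelDim = 4, headDim = 4)
  res <- crossAttentionHeads(Zi, Zj, config = cfg, seed = 5)
  p <- res$params$dirI
  manual <- scaledDotAttention(Zi %*% p$heads[[1]]$Wq,
                               Zj %*% p$heads[[1]]$Wk,
                               Zj %*% p$heads[[1]]$Wv) %*% p$Wo
  expect_equal(unclass(res$headI), unclass(manual),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cross-attention is permutation-equivariant over cells", {
  set.seed(5)
  Zi <- matrix(rnorm(24), 6, 4); Zj <- matrix(rnorm(24), 6, 4)
  cfg <- attentionConfig(nHeads = 2, modelDim = 4)
  res <- crossAttentionHeads(Zi, Zj, config = cfg, seed = 6)
  perm <- sample(6)
  resP <- crossAttentionHeads(Zi[perm, ], Zj[perm, ],
                              params = res$params, config = cfg)
  expect_equal(unclass(resP$headI), unclass(res$headI)[perm, ],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(resP$headJ), unclass(res$headJ)[perm, ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("residual layer norm normalises rows of head + Z", {
  set.seed(6)
  head <- matrix(rnorm(32), 4, 8); Z <- matrix(rnorm(32), 4, 8)
  out <- residualLayerNorm(head, Z)
  expect_lt(max(abs(rowMeans(out))), 1e-6)
  expect_equal(out, oracleLayerNorm(head + Z), tolerance = 1e-10)
  # head = -Z: zeros normalise to zeros, so output is the bias rows
  beta <- rnorm(8)
  outb <- residualLayerNorm(-Z, Z, beta = beta)
  for (i in 1:4) expect_equal(outb[i, ], beta, tolerance = 1e-10)
})

test_that("FFN fusion concatenates in order and matches a hand computation", {
  hi <- matrix(c(1, 2, 3, 4), 2, 2)
  hj <- matrix(c(5, 6, 7, 8), 2, 2)
  cfg <- ffnConfig(modelDim = 2, hiddenDim = 4)
  # identity W1, W2 = identity over zeros: output = hi + bias
  params <- list(W1 = diag(4), b1 = rep(0, 4),
                 W2 = rbind(diag(2), matrix(0, 2, 2)), b2 = c(0.5, -0.5))
  out <- omicsValues(fuseHeads(hi, hj, params = params, config = cfg))
  # relu(cbind(hi,hj) %*% I) = cbind(hi,hj) (all positive); W2 keeps hi
  expect_equal(out, cbind(hi[, 1] + 0.5, hi[, 2] - 0.5), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero inputs, zero weights: rows equal the output bias
  pz <- list(W1 = matrix(0, 4, 4), b1 = rep(0, 4),
             W2 = matrix(0, 4, 2), b2 = c(2, 3))
  oz <- omicsValues(fuseHeads(matrix(0, 2, 2), matrix(0, 2, 2),
                              params = pz, config = cfg))
  expect_equal(unname(oz[1, ]), c(2, 3))
  # order matters: swapping inputs changes the output for generic weights
  pr <- withr::with_seed(7, scCrossFuse:::initFFN(cfg))
  o1 <- omicsValues(fuseHeads(hi, hj, params = pr, config = cfg))
  o2 <- omicsValues(fuseHeads(hj, hi, params = pr, config = cfg))
  expect_gt(max(abs(o1 - o2)), 1e-6)
})

test_that("supervised contrastive loss matches the scalar oracle", {
  # anchor/positive identical, three orthogonal negatives, tau = 0.5
  Z <- rbind(c(1, 0, 0, 0, 0),
             c(1, 0, 0, 0, 0),
             c(0, 1, 0, 0, 0),
             c(0, 0, 1, 0, 0),
             c(0, 0, 0, 1, 0))
  labels <- c(1, 1, 2, 3, 4)
  expect_warning(
    val <- supervisedContrastiveLoss(Z, labels,
                                     contrastiveConfig(temperature = 0.5)),
    "skipped")
  expect_equal(val, -log(exp(2) / (exp(2) + 3)), tolerance = 1e-6)
})

test_that("contrastive loss is monotone in negative similarity", {
  base <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  labels <- c(1, 1, 2, 2)
  cfg <- contrastiveConfig(temperature = 0.5)
  l0 <- supervisedContrastiveLoss(base, labels, cfg)
  closer <- base
  closer[3, ] <- c(0.5, sqrt(1 - 0.25))   # negative rotated towards anchor
  closer[4, ] <- closer[3, ]
  l1 <- supervisedContrastiveLoss(closer, labels, cfg)
  expect_gt(l1, l0)
  expect_error(supervisedContrastiveLoss(base, rep(1, 4), cfg), "2 classes")
  expect_error(contrastiveConfig(temperature = 0), "temperature")
})

test_that("contrastive loss is invariant to orthogonal rotation", {
  set.seed(8)
  Z <- matrix(rnorm(40), 10, 4)
  labels <- rep(1:2, 5)
  R <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  cfg <- contrastiveConfig()
  expect_equal(supervisedContrastiveLoss(Z, labels, cfg),
               supervisedContrastiveLoss(Z %*% R, labels, cfg),
               tolerance = 1e-10)
})

test_that("class-aligned embeddings score below label-shuffled ones", {
  Z <- rbind(matrix(rep(c(1, 0), each = 6), 6, 2),
             matrix(rep(c(0, 1), each = 6), 6, 2))
  labels <- rep(1:2, each = 6)
  cfg <- contrastiveConfig()
  aligned <- supervisedContrastiveLoss(Z, labels, cfg)
  set.seed(9)
  shuffled <- replicate(20,
    supervisedContrastiveLoss(Z[sample(12), ], labels, cfg))
  expect_lt(aligned, mean(shuffled))
})

test_that("baseline fusers follow their contracts", {
  set.seed(10)
  Zi <- matrix(rnorm(20), 5, 4); Z0 <- matrix(0, 5, 4)
  expect_equal(omicsValues(baselineFuse(Zi, Z0, "sum")), Zi,
               ignore_attr = TRUE)
  expect_equal(omicsValues(baselineFuse(Zi, Zi, "average")), Zi,
               ignore_attr = TRUE)
  cc <- baselineFuse(Zi, Z0, "concat", seed = 2)
  expect_equal(dim(omicsValues(cc)), c(5L, 4L))
  sa <- baselineFuse(Zi, Z0, "self_attention", seed = 2)
  expect_equal(dim(omicsValues(sa)), c(5L, 4L))
  expect_error(baselineFuse(Zi, Z0, "geometric"), "arg")
})

test_that("fusion training objective components behave as specified", {
  ds <- tinyPaired()
  red <- preprocessPair(ds$rna, ds$atac,
                        experimentConfig(nHvg = 100, nPcs = 10, nLsi = 10))
  ae <- trainDualAE(red$rna, red$atac,
                    rnaConfig = aeConfig(10, hiddenDim = 24, latentDim = 8),
                    atacConfig = aeConfig(10, hiddenDim = 24, latentDim = 8),
                    epochs = 30, seed = 1)
  attnCfg <- attentionConfig(nHeads = 2, modelDim = 8)
  # lambda = 0 reduces to the reconstruction objective alone
  f0 <- trainFusion(red$rna, red$atac, ae, labels = ds$labels,
                    attnCfg = attnCfg,
                    contrastCfg = contrastiveConfig(lambda = 0),
                    epochs = 5, seed = 2)
  expect_equal(f0$history$total, f0$history$recon)
  expect_true(all(f0$history$contrastive == 0))
  # contrastive term decreases over training, across seeds
  for (seed in 1:3) {
    ft <- trainFusion(red$rna, red$atac, ae, labels = ds$labels,
                      attnCfg = attnCfg, epochs = 30, seed = seed,
                      finetuneEncoders = FALSE)
    expect_lt(ft$history$contrastive[30], ft$history$contrastive[1])
  }
  expect_error(trainFusion(red$rna, red$atac, ae, labels = ds$labels,
                           trainMask = rep(FALSE, 120), attnCfg = attnCfg,
                           epochs = 1),
               "train mask")
})

test_that("fusion gradients agree with finite differences end to end", {
  set.seed(11)
  n <- 5; d <- 4
  Zi <- matrix(rnorm(n * d), n, d); Zj <- matrix(rnorm(n * d), n, d)
  labels <- c(1, 1, 2, 2, 1)
  attnCfg <- attentionConfig(nHeads = 2, modelDim = d)
  ffnCfg <- ffnConfig(modelDim = d, hiddenDim = 6)
  params <- scCrossFuse:::initFusionParams("mhca", attnCfg, ffnCfg)
  lossFn <- function(p)
    scCrossFuse:::supConLoss(
      scCrossFuse:::fusionForward(Zi, Zj, p, "mhca", attnCfg, ffnCfg)$Z,
      labels, 0.5)$loss
  fus <- scCrossFuse:::fusionForward(Zi, Zj, params, "mhca", attnCfg, ffnCfg)
  sc <- scCrossFuse:::supConLoss(fus$Z, labels, 0.5, wantGrad = TRUE)
  fb <- scCrossFuse:::fusionBackward(sc$dZ, Zi, Zj, params, "mhca",
                                     attnCfg, ffnCfg, fus$cache)
  eps <- 1e-6
  probe <- list(
    list(get = function(p) p$dirI$heads[[1]]$Wq[1, 2],
         set = function(p, v) { p$dirI$heads[[1]]$Wq[1, 2] <- v; p },
         an = fb$grads$dirI$heads[[1]]$Wq[1, 2]),
    list(get = function(p) p$dirJ$Wo[2, 3],
         set = function(p, v) { p$dirJ$Wo[2, 3] <- v; p },
         an = fb$grads$dirJ$Wo[2, 3]),
    list(get = function(p) p$lnI$gamma[2],
         set = function(p, v) { p$lnI$gamma[2] <- v; p },
         an = fb$grads$lnI$gamma[2]),
    list(get = function(p) p$ffn$b2[1],
         set = function(p, v) { p$ffn$b2[1] <- v; p },
         an = fb$grads$ffn$b2[1]))
  for (pr in probe) {
    v <- pr$get(params)
    fd <- (lossFn(pr$set(params, v + eps)) -
             lossFn(pr$set(params, v - eps))) / (2 * eps)
    expect_equal(fd, pr$an, tolerance = 1e-4)
  }
})

test_that("single-positive sampling reduces to the multi-positive loss when unique", {
  Z <- rbind(c(1, 0), c(0.9, 0.1), c(0, 1), c(-0.1, 0.9))
  labels <- c(1, 1, 2, 2)   # exactly one positive per anchor either way
  multi <- supervisedContrastiveLoss(Z, labels, contrastiveConfig())
  single <- withr::with_seed(1,
    supervisedContrastiveLoss(Z, labels,
                              contrastiveConfig(singlePositive = TRUE)))
  expect_equal(single, multi, tolerance = 1e-12)
  # with several positives the sampled variant still yields a finite loss
  labels2 <- c(1, 1, 1, 2)
  s2 <- withr::with_seed(2, suppressWarnings(
    supervisedContrastiveLoss(Z, labels2,
                              contrastiveConfig(singlePositive = TRUE))))
  expect_true(is.finite(s2) && s2 >= 0)
})
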