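# Bidirectional multi-head cross-attention fusion with residual layer
# normalisation and a feed-forward fusion network, refined by a supervised
# contrastive objective. Queries come from one modality and keys/values from
# the other, in both directions, with separate projections per direction.

#' Attention configuration
#'
#' @param nHeads number of attention heads (default 4)
#' @param modelDim latent dimension d of the inputs (default 128)
#' @param headDim per-head dimension d_k; default `modelDim / nHeads`
#'   (requires divisibility)
#' @return a named config list; the concatenated head dimension is
#'   `nHeads * headDim`
#' @export
attentionConfig <- function(nHeads = 4, modelDim = 128, headDim = NULL) {
  stopifnot(nHeads >= 1, modelDim >= 1)
  if (is.null(headDim)) {
    if (modelDim %% nHeads != 0)
      stop("modelDim (", modelDim, ") is not divisible by nHeads (", nHeads,
           "); give headDim explicitly")
    headDim <- modelDim %/% nHeads
  }
  stopifnot(headDim >= 1)
  list(nHeads = as.integer(nHeads), modelDim = as.integer(modelDim),
       headDim = as.integer(headDim))
}

#' Supervised contrastive configuration
#'
#' @param temperature softmax temperature tau > 0 (default 0.5)
#' @param lambda weight of the contrastive term in the joint fusion
#'   objective (default 1)
#' @param singlePositive sample one positive per anchor instead of averaging
#'   over all anchor-positive pairs (default `FALSE`)
#' @return a named config list
#' @export
contrastiveConfig <- function(temperature = 0.5, lambda = 1,
                              singlePositive = FALSE) {
  if (temperature <= 0) stop("temperature must be > 0")
  stopifnot(lambda >= 0)
  list(temperature = temperature, lambda = lambda,
       singlePositive = singlePositive)
}

#' Fusion feed-forward network configuration
#'
#' Two dense layers mapping the concatenated refined heads (2d) through a
#' hidden layer to the fused dimension d: `FFN(x) = relu(x W1 + b1) W2 + b2`.
#'
#' @param modelDim latent dimension d (default 128); input is `2 * modelDim`
#' @param hiddenDim hidden width (default 256)
#' @param activation hidden activation (default `"relu"`)
#' @return a named config list
#' @export
ffnConfig <- function(modelDim = 128, hiddenDim = 256, activation = "relu") {
  list(inputDim = 2L * as.integer(modelDim), hiddenDim = as.integer(hiddenDim),
       outputDim = as.integer(modelDim), activation = activation)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`; each softmax row is a probability vector
#' over keys.
#'
#' @param Q queries, n_q x d_k
#' @param K keys, n_k x d_k
#' @param V values, n_k x d_v
#' @return n_q x d_v output matrix with the row-stochastic attention weight
#'   matrix attached as attribute `"weights"`
#' @export
scaledDotAttention <- function(Q, K, V) {
  if (ncol(Q) == 0) stop("d_k must be positive")
  if (nrow(K) != nrow(V)) stop("K and V must have equal row counts")
  if (ncol(Q) != ncol(K)) stop("Q and K must have equal column counts")
  A <- rowSoftmax(Q %*% t(K) / sqrt(ncol(Q)))
  out <- A %*% V
  attr(out, "weights") <- A
  out
}

# Parameter init for one attention direction: per-head Q/K/V projections
# plus the output projection (h*d_k) x d. No biases (as in Eq.-style MHA).
initAttnDirection <- function(cfg) {
  heads <- lapply(seq_len(cfg$nHeads), function(h)
    list(Wq = initDense(cfg$modelDim, cfg$headDim)$W,
         Wk = initDense(cfg$modelDim, cfg$headDim)$W,
         Wv = initDense(cfg$modelDim, cfg$headDim)$W))
  list(heads = heads,
       Wo = initDense(cfg$nHeads * cfg$headDim, cfg$modelDim)$W)
}

attnDirForward <- function(Zq, Zkv, dp, cfg) {
  hs <- vector("list", cfg$nHeads)
  outs <- vector("list", cfg$nHeads)
  for (h in seq_len(cfg$nHeads)) {
    p <- dp$heads[[h]]
    Q <- Zq %*% p$Wq
    K <- Zkv %*% p$Wk
    V <- Zkv %*% p$Wv
    A <- rowSoftmax(Q %*% t(K) / sqrt(cfg$headDim))
    O <- A %*% V
    hs[[h]] <- list(Q = Q, K = K, V = V, A = A)
    outs[[h]] <- O
  }
  concat <- do.call(cbind, outs)
  list(out = concat %*% dp$Wo, cache = list(heads = hs, concat = concat))
}

attnDirBackward <- function(dOut, Zq, Zkv, dp, cfg, cache) {
  g <- list(heads = vector("list", cfg$nHeads),
            Wo = crossprod(cache$concat, dOut))
  dConcat <- dOut %*% t(dp$Wo)
  dZq <- matrix(0, nrow(Zq), ncol(Zq))
  dZkv <- matrix(0, nrow(Zkv), ncol(Zkv))
  sc <- sqrt(cfg$headDim)
  for (h in seq_len(cfg$nHeads)) {
    p <- dp$heads[[h]]
    ch <- cache$heads[[h]]
    cols <- ((h - 1) * cfg$headDim + 1):(h * cfg$headDim)
    dO <- dConcat[, cols, drop = FALSE]
    dA <- dO %*% t(ch$V)
    dV <- crossprod(ch$A, dO)
    dS <- softmax_backward_cpp(ch$A, dA)
    dQ <- dS %*% ch$K / sc
    dK <- crossprod(dS, ch$Q) / sc
    g$heads[[h]] <- list(Wq = crossprod(Zq, dQ),
                         Wk = crossprod(Zkv, dK),
                         Wv = crossprod(Zkv, dV))
    dZq <- dZq + dQ %*% t(p$Wq)
    dZkv <- dZkv + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  }
  list(grads = g, dZq = dZq, dZkv = dZkv)
}

#' Bidirectional multi-head cross-attention
#'
#' Direction i uses queries from `Zi` against keys/values from `Zj`
#' (`Q = Zi Wq`, `K = Zj Wk`, `V = Zj Wv` per head); direction j is the
#' converse. Heads are concatenated and projected back to dimension d.
#' Projections are separate per direction.
#'
#' @param Zi,Zj N x d latent matrices (or [LatentEmbedding-class]s)
#' @param params attention parameters (`$dirI`, `$dirJ`); freshly
#'   initialised from `seed` when `NULL`
#' @param config an [attentionConfig()]
#' @param seed RNG seed used when `params` is `NULL`
#' @return list with `headI`, `headJ` (N x d multi-head outputs, each
#'   carrying per-head attention weight matrices as attribute `"weights"`)
#'   and the `params` used
#' @export
crossAttentionHeads <- function(Zi, Zj, params = NULL,
                                config = attentionConfig(), seed = 0) {
  Zi <- extractMatrix(Zi); Zj <- extractMatrix(Zj)
  if (!all(dim(Zi) == dim(Zj)))
    stop("Zi and Zj must have identical shape")
  if (ncol(Zi) != config$modelDim)
    stop("input dimension ", ncol(Zi), " != modelDim ", config$modelDim)
  if (is.null(params))
    params <- withSeed(seed, list(dirI = initAttnDirection(config),
                                  dirJ = initAttnDirection(config)))
  fi <- attnDirForward(Zi, Zj, params$dirI, config)
  fj <- attnDirForward(Zj, Zi, params$dirJ, config)
  headI <- fi$out; headJ <- fj$out
  attr(headI, "weights") <- lapply(fi$cache$heads, `[[`, "A")
  attr(headJ, "weights") <- lapply(fj$cache$heads, `[[`, "A")
  list(headI = headI, headJ = headJ, params = params)
}

#' Residual connection followed by layer normalisation
#'
#' `LayerNorm(head + Z)`: each row of the sum is centred and scaled to unit
#' variance, then the affine gain/bias applied.
#'
#' @param head,Z N x d matrices of equal shape
#' @param gamma,beta affine gain and bias vectors of length d (defaults 1, 0)
#' @return N x d matrix
#' @export
residualLayerNorm <- function(head, Z, gamma = NULL, beta = NULL) {
  stopifnot(all(dim(head) == dim(Z)))
  d <- ncol(head)
  p <- list(gamma = if (is.null(gamma)) rep(1, d) else gamma,
            beta = if (is.null(beta)) rep(0, d) else beta)
  layerNormForward(head + Z, p)$y
}

#' Fuse refined attention heads through the feed-forward network
#'
#' Concatenates `headIp` (RNA direction) then `headJp` (ATAC direction)
#' along features and applies the two-layer FFN, producing the N x d fused
#' embedding.
#'
#' @param headIp,headJp N x d refined head matrices
#' @param params FFN parameters (`$W1`, `$b1`, `$W2`, `$b2`); freshly
#'   initialised from `seed` when `NULL`
#' @param config an [ffnConfig()]
#' @param seed RNG seed used when `params` is `NULL`
#' @return a [LatentEmbedding-class] with source `"fused"`
#' @export
fuseHeads <- function(headIp, headJp, params = NULL, config = NULL, seed = 0) {
  stopifnot(all(dim(headIp) == dim(headJp)))
  if (is.null(config)) config <- ffnConfig(modelDim = ncol(headIp))
  if (is.null(params)) params <- withSeed(seed, initFFN(config))
  x <- cbind(headIp, headJp)
  z <- ffnForward(x, params, config)$y
  rownames(z) <- rownames(headIp)
  LatentEmbedding(z, source = "fused")
}

initFFN <- function(cfg) {
  p1 <- initDense(cfg$inputDim, cfg$hiddenDim)
  p2 <- initDense(cfg$hiddenDim, cfg$outputDim)
  list(W1 = p1$W, b1 = p1$b, W2 = p2$W, b2 = p2$b)
}

ffnForward <- function(x, p, cfg) {
  ab <- actBoth(cfg$activation, addRowVec(x %*% p$W1, p$b1))
  y <- addRowVec(ab$y %*% p$W2, p$b2)
  list(y = y, cache = list(x = x, gA1 = ab$g, h = ab$y))
}

ffnBackward <- function(dY, p, cfg, cache) {
  dW2 <- crossprod(cache$h, dY)
  db2 <- colSums(dY)
  dH <- dY %*% t(p$W2)
  dA1 <- dH * cache$gA1
  dW1 <- crossprod(cache$x, dA1)
  db1 <- colSums(dA1)
  dX <- dA1 %*% t(p$W1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dX = dX)
}

#' Supervised contrastive loss
#'
#' Embeddings are L2-normalised and cosine similarities divided by the
#' temperature. For every anchor and every same-class positive, the term
#' `-log( exp(s(a,a+)/tau) / (exp(s(a,a+)/tau) + sum_negatives
#' exp(s(a,a-)/tau)) )` is computed, negatives being all different-class
#' cells; the loss is the mean over anchor-positive pairs. Anchors without
#' any positive are skipped with a warning.
#'
#' @param Z N x d embedding matrix (or [LatentEmbedding-class])
#' @param labels integer/factor class labels, length N; at least 2 classes
#' @param config a [contrastiveConfig()]
#' @return nonnegative scalar loss
#' @export
supervisedContrastiveLoss <- function(Z, labels, config = contrastiveConfig()) {
  supConLoss(extractMatrix(Z), as.integer(as.factor(labels)),
             config$temperature, wantGrad = FALSE,
             singlePositive = config$singlePositive)$loss
}

# Core SupCon computation; optionally returns dLoss/dZ. With
# singlePositive, one positive per anchor is sampled from the current RNG
# stream instead of averaging over all anchor-positive pairs.
supConLoss <- function(Z, labels, tau, wantGrad = FALSE,
                       singlePositive = FALSE) {
  if (tau <= 0) stop("temperature must be > 0")
  n <- nrow(Z)
  if (length(labels) != n) stop("labels length must match rows of Z")
  if (length(unique(labels)) < 2)
    stop("supervised contrastive loss needs at least 2 classes")
  nrm <- sqrt(rowSums(Z^2))
  nrm <- pmax(nrm, 1e-12)
  Zn <- Z / nrm
  S <- tcrossprod(Zn) / tau
  E <- exp(S)
  diag(E) <- 0
  same <- outer(labels, labels, `==`)
  diag(same) <- FALSE
  if (singlePositive) {
    for (i in seq_len(n)) {
      pos <- which(same[i, ])
      if (length(pos) > 1) {
        keep <- pos[sample.int(length(pos), 1L)]
        same[i, ] <- FALSE
        same[i, keep] <- TRUE
      }
    }
  }
  negMask <- outer(labels, labels, `!=`)
  Tneg <- rowSums(E * negMask)
  nPos <- rowSums(same)
  if (any(nPos == 0))
    warning(sum(nPos == 0), " anchor(s) without a same-class positive were skipped")
  M <- sum(nPos)
  if (M == 0) stop("no anchor-positive pairs available")
  denom <- E + matrix(Tneg, n, n)   # T_a is constant along each anchor row
  terms <- -log(E / denom)
  loss <- sum(terms[same]) / M
  if (!wantGrad) return(list(loss = loss))
  G <- matrix(0, n, n)
  G[same] <- (E[same] / denom[same] - 1) / M
  R <- rowSums(same / denom)            # sum over positives of 1/(E_ap + T_a)
  G <- G + (E * negMask) * R / M
  dZn <- ((G + t(G)) %*% Zn) / tau
  dZ <- (dZn - Zn * rowSums(Zn * dZn)) / nrm
  list(loss = loss, dZ = dZ)
}

#' Baseline fusion strategies for ablation
#'
#' `concat` concatenates and linearly projects back to d; `sum` and
#' `average` combine elementwise; `self_attention` runs single-modality
#' scaled dot-product attention over the concatenated representation
#' `[Zi || Zj]`.
#'
#' @param Zi,Zj N x d latent matrices of equal shape
#' @param method one of `"concat"`, `"sum"`, `"average"`, `"self_attention"`
#' @param params optional projection parameters (initialised from `seed`
#'   when `NULL` and needed)
#' @param seed RNG seed for parameter initialisation
#' @return a [LatentEmbedding-class] with source `"fused"`
#' @export
baselineFuse <- function(Zi, Zj, method = c("concat", "sum", "average",
                                            "self_attention"),
                         params = NULL, seed = 0) {
  method <- match.arg(method)
  Zi <- extractMatrix(Zi); Zj <- extractMatrix(Zj)
  stopifnot(all(dim(Zi) == dim(Zj)))
  d <- ncol(Zi)
  z <- switch(method,
    sum = Zi + Zj,
    average = (Zi + Zj) / 2,
    concat = {
      if (is.null(params)) params <- withSeed(seed, initBaselineParams("concat", d))
      addRowVec(cbind(Zi, Zj) %*% params$W, params$b)
    },
    self_attention = {
      if (is.null(params))
        params <- withSeed(seed, initBaselineParams("self_attention", d))
      x <- cbind(Zi, Zj)
      out <- scaledDotAttention(x %*% params$Wq, x %*% params$Wk,
                                x %*% params$Wv)
      attr(out, "weights") <- NULL
      out
    })
  rownames(z) <- rownames(Zi)
  LatentEmbedding(z, source = "fused")
}

initBaselineParams <- function(method, d) {
  if (method == "concat") {
    p <- initDense(2L * d, d)
    list(W = p$W, b = p$b)
  } else if (method == "self_attention") {
    list(Wq = initDense(2L * d, d)$W,
         Wk = initDense(2L * d, d)$W,
         Wv = initDense(2L * d, d)$W)
  } else NULL
}

# ---------------------------------------------------------------------------
# Joint fusion training

initFusionParams <- function(method, attnCfg, ffnCfg) {
  d <- attnCfg$modelDim
  if (method == "mhca") {
    list(dirI = initAttnDirection(attnCfg),
         dirJ = initAttnDirection(attnCfg),
         lnI = initLayerNorm(d), lnJ = initLayerNorm(d),
         ffn = initFFN(ffnCfg))
  } else if (method %in% c("concat", "self_attention")) {
    initBaselineParams(method, d)
  } else NULL   # sum / average have no parameters
}

# Forward through the fusion architecture; returns fused Z and caches.
fusionForward <- function(Zi, Zj, params, method, attnCfg, ffnCfg) {
  if (method == "mhca") {
    fi <- attnDirForward(Zi, Zj, params$dirI, attnCfg)
    fj <- attnDirForward(Zj, Zi, params$dirJ, attnCfg)
    li <- layerNormForward(fi$out + Zi, params$lnI)
    lj <- layerNormForward(fj$out + Zj, params$lnJ)
    ff <- ffnForward(cbind(li$y, lj$y), params$ffn, ffnCfg)
    list(Z = ff$y, cache = list(fi = fi, fj = fj, li = li, lj = lj, ff = ff))
  } else if (method == "concat") {
    list(Z = addRowVec(cbind(Zi, Zj) %*% params$W, params$b),
         cache = list(x = cbind(Zi, Zj)))
  } else if (method == "sum") {
    list(Z = Zi + Zj, cache = NULL)
  } else if (method == "average") {
    list(Z = (Zi + Zj) / 2, cache = NULL)
  } else if (method == "self_attention") {
    x <- cbind(Zi, Zj)
    Q <- x %*% params$Wq; K <- x %*% params$Wk; V <- x %*% params$Wv
    A <- rowSoftmax(Q %*% t(K) / sqrt(ncol(Q)))
    list(Z = A %*% V, cache = list(x = x, Q = Q, K = K, V = V, A = A))
  } else stop("unknown fusion method: ", method)
}

fusionBackward <- function(dZf, Zi, Zj, params, method, attnCfg, ffnCfg,
                           cache) {
  d <- ncol(Zi)
  if (method == "mhca") {
    fb <- ffnBackward(dZf, params$ffn, ffnCfg, cache$ff$cache)
    dLi <- fb$dX[, seq_len(d), drop = FALSE]
    dLj <- fb$dX[, d + seq_len(d), drop = FALSE]
    bi <- layerNormBackward(dLi, params$lnI, cache$li$cache)
    bj <- layerNormBackward(dLj, params$lnJ, cache$lj$cache)
    ai <- attnDirBackward(bi$dX, Zi, Zj, params$dirI, attnCfg, cache$fi$cache)
    aj <- attnDirBackward(bj$dX, Zj, Zi, params$dirJ, attnCfg, cache$fj$cache)
    list(grads = list(dirI = ai$grads, dirJ = aj$grads,
                      lnI = list(gamma = bi$dgamma, beta = bi$dbeta),
                      lnJ = list(gamma = bj$dgamma, beta = bj$dbeta),
                      ffn = fb$grads),
         dZi = bi$dX + ai$dZq + aj$dZkv,
         dZj = bj$dX + aj$dZq + ai$dZkv)
  } else if (method == "concat") {
    dX <- dZf %*% t(params$W)
    list(grads = list(W = crossprod(cache$x, dZf), b = colSums(dZf)),
         dZi = dX[, seq_len(d), drop = FALSE],
         dZj = dX[, d + seq_len(d), drop = FALSE])
  } else if (method == "sum") {
    list(grads = NULL, dZi = dZf, dZj = dZf)
  } else if (method == "average") {
    list(grads = NULL, dZi = dZf / 2, dZj = dZf / 2)
  } else if (method == "self_attention") {
    A <- cache$A; x <- cache$x
    sc <- sqrt(ncol(cache$Q))
    dA <- dZf %*% t(cache$V)
    dV <- crossprod(A, dZf)
    dS <- softmax_backward_cpp(A, dA)
    dQ <- dS %*% cache$K / sc
    dK <- crossprod(dS, cache$Q) / sc
    dX <- dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)
    list(grads = list(Wq = crossprod(x, dQ), Wk = crossprod(x, dK),
                      Wv = crossprod(x, dV)),
         dZi = dX[, seq_len(d), drop = FALSE],
         dZj = dX[, d + seq_len(d), drop = FALSE])
  }
}

#' Train the cross-attention fusion with supervised contrastive refinement
#'
#' Minimises `L_recon + lambda * L_contrastive`, the reconstruction term
#' being the weighted dual-autoencoder objective and the contrastive term
#' computed on the fused embedding of train-mask cells only; test-mask
#' labels are never read. By default the autoencoder weights keep training
#' alongside the fusion parameters (`finetuneEncoders = FALSE` freezes
#' them). With `lambda = 0` (or `labels = NULL`) training reduces to the
#' reconstruction objective alone and no labels are required.
#'
#' @param rna,atac the cells x features inputs the autoencoders were trained
#'   on (matrix, [OmicsMatrix-class] or [LatentEmbedding-class])
#' @param aeFit result of [trainDualAE()]
#' @param labels class labels (used for train-mask cells only); may be
#'   `NULL` when `lambda = 0`
#' @param trainMask logical vector marking cells whose labels may be used;
#'   defaults to all cells when labels are given
#' @param method fusion architecture: `"mhca"` (default) or one of the
#'   ablation baselines `"concat"`, `"sum"`, `"average"`, `"self_attention"`
#' @param attnCfg,ffnCfg,contrastCfg configs ([attentionConfig()],
#'   [ffnConfig()], [contrastiveConfig()])
#' @param epochs training epochs (default 100)
#' @param lr Adam learning rate (default 1e-3)
#' @param seed RNG seed for fusion parameter initialisation
#' @param finetuneEncoders keep optimising the AE weights (default `TRUE`)
#' @return list with `params`, the fused [LatentEmbedding-class] `fused`
#'   for all cells, updated `Zi`/`Zj`, the `aeFit` (possibly fine-tuned),
#'   and a `history` data.frame (total / reconstruction / contrastive loss
#'   per epoch)
#' @export
trainFusion <- function(rna, atac, aeFit, labels = NULL, trainMask = NULL,
                        method = c("mhca", "concat", "sum", "average",
                                   "self_attention"),
                        attnCfg = NULL, ffnCfg = NULL,
                        contrastCfg = contrastiveConfig(),
                        epochs = 100, lr = 1e-3, seed = 0,
                        finetuneEncoders = TRUE) {
  method <- match.arg(method)
  xi <- extractMatrix(rna); xj <- extractMatrix(atac)
  checkPairedCells(xi, xj)
  n <- nrow(xi)
  d <- aeFit$rnaConfig$latentDim
  if (is.null(attnCfg)) attnCfg <- attentionConfig(modelDim = d)
  if (is.null(ffnCfg)) ffnCfg <- ffnConfig(modelDim = d)
  lambda <- contrastCfg$lambda
  useContrast <- lambda > 0 && !is.null(labels)
  if (useContrast) {
    if (is.null(trainMask)) trainMask <- rep(TRUE, n)
    if (!any(trainMask)) stop("train mask is empty")
    labTrain <- as.integer(as.factor(labels))[trainMask]
  }
  alpha <- aeFit$rnaConfig$alpha
  beta <- aeFit$rnaConfig$beta
  withSeed(seed, {
    fparams <- initFusionParams(method, attnCfg, ffnCfg)
    params <- list(fusion = fparams, ae = aeFit$params)
    state <- adamInit(params)
    history <- data.frame(total = numeric(epochs), recon = numeric(epochs),
                          contrastive = numeric(epochs))
    if (!finetuneEncoders) {
      # encoders frozen: latent embeddings and the reconstruction term are
      # constant across epochs, so compute them once
      fwi <- aeForward(xi, params$ae$rna, aeFit$rnaConfig, training = FALSE)
      fwj <- aeForward(xj, params$ae$atac, aeFit$atacConfig, training = FALSE)
      frozenRecon <- jointReconstructionLoss(xi, fwi$xhat, xj, fwj$xhat,
                                             alpha, beta)
    }
    for (ep in seq_len(epochs)) {
      if (finetuneEncoders) {
        fwi <- aeForward(xi, params$ae$rna, aeFit$rnaConfig, training = FALSE)
        fwj <- aeForward(xj, params$ae$atac, aeFit$atacConfig, training = FALSE)
        recon <- jointReconstructionLoss(xi, fwi$xhat, xj, fwj$xhat,
                                         alpha, beta)
      } else {
        recon <- frozenRecon
      }
      Zi <- fwi$z; Zj <- fwj$z
      fus <- fusionForward(Zi, Zj, params$fusion, method, attnCfg, ffnCfg)
      if (useContrast) {
        sc <- supConLoss(fus$Z[trainMask, , drop = FALSE], labTrain,
                         contrastCfg$temperature, wantGrad = TRUE,
                         singlePositive = isTRUE(contrastCfg$singlePositive))
        closs <- sc$loss
        dZf <- matrix(0, n, ncol(fus$Z))
        dZf[trainMask, ] <- lambda * sc$dZ
      } else {
        closs <- 0
        dZf <- NULL
      }
      history$recon[ep] <- recon
      history$contrastive[ep] <- closs
      history$total[ep] <- recon + lambda * closs
      grads <- list()
      dZi <- dZj <- NULL
      if (!is.null(dZf)) {
        fb <- fusionBackward(dZf, Zi, Zj, params$fusion, method, attnCfg,
                             ffnCfg, fus$cache)
        grads$fusion <- fb$grads
        dZi <- fb$dZi; dZj <- fb$dZj
      }
      dXi <- alpha * 2 * (fwi$xhat - xi) / length(xi)
      dXj <- beta * 2 * (fwj$xhat - xj) / length(xj)
      if (finetuneEncoders) {
        bi <- aeBackward(params$ae$rna, aeFit$rnaConfig, fwi$cache,
                         dXhat = dXi, dZ = dZi)
        bj <- aeBackward(params$ae$atac, aeFit$atacConfig, fwj$cache,
                         dXhat = dXj, dZ = dZj)
        grads$ae <- list(rna = bi$grads, atac = bj$grads)
      }
      upd <- adamStep(params, grads, state, lr = lr)
      params <- upd$params
      state <- upd$state
    }
    fwi <- aeForward(xi, params$ae$rna, aeFit$rnaConfig, training = FALSE)
    fwj <- aeForward(xj, params$ae$atac, aeFit$atacConfig, training = FALSE)
    fus <- fusionForward(fwi$z, fwj$z, params$fusion, method, attnCfg, ffnCfg)
    Zf <- fus$Z
    rownames(Zf) <- rownames(xi)
    Zi <- fwi$z; rownames(Zi) <- rownames(xi)
    Zj <- fwj$z; rownames(Zj) <- rownames(xj)
    aeFit$params <- params$ae
    list(params = params$fusion,
         fused = LatentEmbedding(Zf, source = "fused"),
         Zi = LatentEmbedding(Zi, source = "rna"),
         Zj = LatentEmbedding(Zj, source = "atac"),
         aeFit = aeFit, method = method,
         attnCfg = attnCfg, ffnCfg = ffnCfg, contrastCfg = contrastCfg,
         history = history)
  })
}
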