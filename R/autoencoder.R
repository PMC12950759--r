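# Dual modality-specific autoencoders. Each pathway is input -> hidden ->
# latent with batch normalisation and GELU on the hidden layer, mirrored by a
# decoder with a linear output layer. Both pathways are trained jointly on
# the weighted reconstruction objective alpha*MSE(rna) + beta*MSE(atac),
# alpha + beta = 1.

#' Autoencoder configuration
#'
#' @param inputDim input feature dimension (d_m)
#' @param hiddenDim hidden layer width (default 512)
#' @param latentDim latent dimension d (default 128)
#' @param activation hidden activation, `"gelu"` by default
#' @param useBatchNorm apply batch normalisation after the hidden layer,
#'   before the activation (default `TRUE`); frozen at inference
#' @param alpha,beta reconstruction weights for the two modalities; must sum
#'   to 1 (checked to 1e-9)
#' @return a named config list
#' @export
aeConfig <- function(inputDim, hiddenDim = 512, latentDim = 128,
                     activation = "gelu", useBatchNorm = TRUE,
                     alpha = 0.5, beta = 0.5) {
  if (abs(alpha + beta - 1) > 1e-9)
    stop("alpha + beta must equal 1 (got ", alpha + beta, ")")
  stopifnot(inputDim >= 1, hiddenDim >= 1, latentDim >= 1)
  list(inputDim = inputDim, hiddenDim = hiddenDim, latentDim = latentDim,
       activation = activation, useBatchNorm = useBatchNorm,
       alpha = alpha, beta = beta)
}

# Initialise one AE's parameters from the current RNG stream.
initAE <- function(cfg) {
  p <- list(enc1 = initDense(cfg$inputDim, cfg$hiddenDim),
            enc2 = initDense(cfg$hiddenDim, cfg$latentDim),
            dec1 = initDense(cfg$latentDim, cfg$hiddenDim),
            dec2 = initDense(cfg$hiddenDim, cfg$inputDim))
  if (cfg$useBatchNorm) p$bn <- initBatchNorm(cfg$hiddenDim)
  p
}

# Full forward pass; returns latent, reconstruction and backward caches.
aeForward <- function(x, params, cfg, training = FALSE) {
  a1 <- denseForward(x, params$enc1)
  if (cfg$useBatchNorm) {
    bn <- batchNormForward(a1, params$bn, training)
    params$bn <- bn$params
    pre <- bn$y
    bnCache <- bn$cache
  } else {
    pre <- a1
    bnCache <- NULL
  }
  ab1 <- actBoth(cfg$activation, pre)
  z <- denseForward(ab1$y, params$enc2)
  a2 <- denseForward(z, params$dec1)
  ab2 <- actBoth(cfg$activation, a2)
  xhat <- denseForward(ab2$y, params$dec2)
  list(z = z, xhat = xhat, params = params,
       cache = list(x = x, gPre = ab1$g, h1 = ab1$y, z = z,
                    gA2 = ab2$g, h2 = ab2$y, bn = bnCache))
}

# Backward pass given upstream gradients on the reconstruction and/or the
# latent. Returns parameter grads and the gradient w.r.t. the input.
aeBackward <- function(params, cfg, cache, dXhat = NULL, dZ = NULL) {
  g <- list()
  dzTotal <- if (is.null(dZ)) 0 else dZ
  if (!is.null(dXhat)) {
    bd2 <- denseBackward(cache$h2, params$dec2, dXhat)
    g$dec2 <- list(W = bd2$dW, b = bd2$db)
    dA2 <- bd2$dX * cache$gA2
    bd1 <- denseBackward(cache$z, params$dec1, dA2)
    g$dec1 <- list(W = bd1$dW, b = bd1$db)
    dzTotal <- dzTotal + bd1$dX
  }
  be2 <- denseBackward(cache$h1, params$enc2, dzTotal)
  g$enc2 <- list(W = be2$dW, b = be2$db)
  dPre <- be2$dX * cache$gPre
  if (cfg$useBatchNorm) {
    bb <- batchNormBackward(dPre, params$bn, cache$bn)
    g$bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
    dA1 <- bb$dX
  } else {
    dA1 <- dPre
  }
  be1 <- denseBackward(cache$x, params$enc1, dA1)
  g$enc1 <- list(W = be1$dW, b = be1$db)
  list(grads = g, dX = be1$dX)
}

#' Encode cells into the latent space
#'
#' Deterministic forward pass of the encoder in evaluation mode (batch-norm
#' statistics frozen).
#'
#' @param x cells x inputDim matrix, [OmicsMatrix-class] or
#'   [LatentEmbedding-class]
#' @param params trained AE parameters
#' @param cfg the [aeConfig()] used at training time
#' @param source tag for the returned embedding (`"rna"` or `"atac"`)
#' @return a [LatentEmbedding-class], cells x latentDim
#' @export
encodeCells <- function(x, params, cfg, source = "rna") {
  xm <- extractMatrix(x)
  if (ncol(xm) != cfg$inputDim)
    stop("input has ", ncol(xm), " features; encoder expects ", cfg$inputDim)
  fw <- aeForward(xm, params, cfg, training = FALSE)
  z <- fw$z
  rownames(z) <- rownames(xm)
  LatentEmbedding(z, source = source)
}

#' Decode latent vectors back to feature space
#'
#' @param z cells x latentDim matrix or [LatentEmbedding-class]
#' @param params trained AE parameters
#' @param cfg the [aeConfig()] used at training time
#' @return cells x inputDim reconstruction matrix
#' @export
decodeCells <- function(z, params, cfg) {
  zm <- extractMatrix(z)
  if (ncol(zm) != cfg$latentDim)
    stop("latent has ", ncol(zm), " dims; decoder expects ", cfg$latentDim)
  act <- activationFun(cfg$activation)
  h2 <- act$f(denseForward(zm, params$dec1))
  denseForward(h2, params$dec2)
}

#' Weighted joint reconstruction loss
#'
#' `alpha * mean((Xi - XiHat)^2) + beta * mean((Xj - XjHat)^2)`, the mean
#' taken over all entries of each matrix. The weights must sum to 1.
#'
#' @param Xi,XiHat RNA input and reconstruction (same shape)
#' @param Xj,XjHat ATAC input and reconstruction (same shape)
#' @param alpha,beta modality weights, `alpha + beta = 1`
#' @return nonnegative scalar
#' @export
jointReconstructionLoss <- function(Xi, XiHat, Xj, XjHat,
                                    alpha = 0.5, beta = 0.5) {
  if (abs(alpha + beta - 1) > 1e-9)
    stop("alpha + beta must equal 1 (got ", alpha + beta, ")")
  stopifnot(all(dim(Xi) == dim(XiHat)), all(dim(Xj) == dim(XjHat)))
  alpha * mean((Xi - XiHat)^2) + beta * mean((Xj - XjHat)^2)
}

extractMatrix <- function(x) {
  if (is(x, "OmicsMatrix")) asDense(omicsValues(x))
  else if (is(x, "LatentEmbedding")) x@values
  else as.matrix(x)
}

checkPairedCells <- function(xi, xj) {
  if (nrow(xi) != nrow(xj))
    stop("modalities have different cell counts: ", nrow(xi), " vs ", nrow(xj))
  ri <- rownames(xi); rj <- rownames(xj)
  if (!is.null(ri) && !is.null(rj) && !identical(ri, rj)) {
    bad <- which(ri != rj)[1]
    stop("cell order differs between modalities; first discordant id at ",
         "position ", bad, ": '", ri[bad], "' vs '", rj[bad], "'")
  }
}

#' Train the dual autoencoders jointly
#'
#' Both pathways are optimised in a single Adam loop on the joint objective
#' `alpha*MSE(rna) + beta*MSE(atac)` with full-batch gradients. Weights are
#' not shared between pathways. Reproducible given `seed` under
#' single-threaded BLAS.
#'
#' @param rna,atac paired cells x features inputs (matrix,
#'   [OmicsMatrix-class] or [LatentEmbedding-class]); equal cell counts and
#'   identical cell order required
#' @param rnaConfig,atacConfig [aeConfig()]s; `inputDim` may be omitted
#'   (`NULL` entries are filled from the data)
#' @param epochs training epochs (default 200); `epochs = 0` returns the
#'   freshly initialised network
#' @param lr Adam learning rate (default 1e-3)
#' @param seed RNG seed for initialisation
#' @return list with `params` (`$rna`, `$atac`), latent embeddings `Zi`
#'   (RNA) and `Zj` (ATAC), per-epoch `history` of the joint loss, and the
#'   two configs
#' @export
trainDualAE <- function(rna, atac, rnaConfig = NULL, atacConfig = NULL,
                        epochs = 200, lr = 1e-3, seed = 0) {
  xi <- extractMatrix(rna)
  xj <- extractMatrix(atac)
  checkPairedCells(xi, xj)
  if (is.null(rnaConfig)) rnaConfig <- aeConfig(ncol(xi))
  if (is.null(atacConfig)) atacConfig <- aeConfig(ncol(xj))
  alpha <- rnaConfig$alpha
  beta <- rnaConfig$beta
  withSeed(seed, {
    params <- list(rna = initAE(rnaConfig), atac = initAE(atacConfig))
    state <- adamInit(params)
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      fi <- aeForward(xi, params$rna, rnaConfig, training = TRUE)
      params$rna <- fi$params
      fj <- aeForward(xj, params$atac, atacConfig, training = TRUE)
      params$atac <- fj$params
      history[ep] <- jointReconstructionLoss(xi, fi$xhat, xj, fj$xhat,
                                             alpha, beta)
      dXi <- alpha * 2 * (fi$xhat - xi) / length(xi)
      dXj <- beta * 2 * (fj$xhat - xj) / length(xj)
      gi <- aeBackward(params$rna, rnaConfig, fi$cache, dXhat = dXi)
      gj <- aeBackward(params$atac, atacConfig, fj$cache, dXhat = dXj)
      upd <- adamStep(params, list(rna = gi$grads, atac = gj$grads),
                      state, lr = lr)
      # keep batch-norm running stats, which Adam does not touch
      if (rnaConfig$useBatchNorm)
        upd$params$rna$bn[c("runMean", "runVar")] <-
          params$rna$bn[c("runMean", "runVar")]
      if (atacConfig$useBatchNorm)
        upd$params$atac$bn[c("runMean", "runVar")] <-
          params$atac$bn[c("runMean", "runVar")]
      params <- upd$params
      state <- upd$state
    }
    list(params = params,
         Zi = encodeCells(xi, params$rna, rnaConfig, source = "rna"),
         Zj = encodeCells(xj, params$atac, atacConfig, source = "atac"),
         history = history, rnaConfig = rnaConfig, atacConfig = atacConfig)
  })
}
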