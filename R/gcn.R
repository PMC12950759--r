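# Two-layer graph convolutional classifier on the fused similarity graph:
# H1 = elu(A~ H W1), dropout, H2 = elu(A~ H1 W2), linear output head.
# Trained transductively with softmax cross-entropy on train-mask nodes.

#' GCN configuration
#'
#' @param hiddenDim hidden layer width (default 64)
#' @param activation graph-layer activation (default `"elu"`)
#' @param dropout dropout rate in \[0, 1) applied between the graph layers
#'   during training (default 0.5)
#' @param lr Adam learning rate (default 0.001)
#' @param weightDecay Adam weight decay (default 0.01)
#' @param epochs training epochs (default 150)
#' @param seed RNG seed for initialisation and dropout
#' @param mergeOutput fold the output transform into the second graph layer
#'   instead of a distinct linear head (default `FALSE`)
#' @return a named config list
#' @export
gcnConfig <- function(hiddenDim = 64, activation = "elu", dropout = 0.5,
                      lr = 0.001, weightDecay = 0.01, epochs = 150,
                      seed = 0, mergeOutput = FALSE) {
  stopifnot(dropout >= 0, dropout < 1, hiddenDim >= 1, epochs >= 0)
  list(hiddenDim = as.integer(hiddenDim), activation = activation,
       dropout = dropout, lr = lr, weightDecay = weightDecay,
       epochs = as.integer(epochs), seed = as.integer(seed),
       mergeOutput = mergeOutput)
}

#' Symmetric degree normalisation of an adjacency matrix
#'
#' `A~ = D^(-1/2) A D^(-1/2)` with D the diagonal degree matrix. Scale
#' invariant: `normalizeAdjacency(c * A)` equals `normalizeAdjacency(A)` for
#' any c > 0.
#'
#' @param A symmetric nonnegative adjacency with positive row sums
#' @return the normalised adjacency, symmetric with spectral radius at most
#'   1 when A carries self loops
#' @export
normalizeAdjacency <- function(A) {
  if (max(abs(A - t(A))) > 1e-8) stop("A must be symmetric")
  if (min(A) < 0) stop("A must be nonnegative")
  deg <- rowSums(A)
  if (any(deg <= 0)) {
    bad <- which(deg <= 0)[1]
    nm <- rownames(A)[bad]
    stop("zero-degree node at row ", bad,
         if (!is.null(nm)) paste0(" ('", nm, "')") else "")
  }
  inv <- 1 / sqrt(deg)
  A * outer(inv, inv)
}

initGCN <- function(inputDim, hiddenDim, nClasses, mergeOutput = FALSE) {
  if (mergeOutput) {
    list(gc1 = initDense(inputDim, hiddenDim),
         gc2 = initDense(hiddenDim, nClasses))
  } else {
    list(gc1 = initDense(inputDim, hiddenDim),
         gc2 = initDense(hiddenDim, hiddenDim),
         out = initDense(hiddenDim, nClasses))
  }
}

#' GCN forward pass
#'
#' Layer 1: `elu(A~ H W1 + b1)`; dropout (training only); layer 2:
#' `elu(A~ (.) W2 + b2)`; then a distinct linear output head produces the
#' logits (merged into layer 2 when the config says so).
#'
#' @param Anorm normalised adjacency from [normalizeAdjacency()]
#' @param H N x d node feature matrix
#' @param params GCN parameters from [trainGCN()] (or [initGCN] shape)
#' @param cfg a [gcnConfig()]
#' @param training apply dropout (draws from the current RNG stream)
#' @return N x nClasses logits matrix
#' @export
gcnForward <- function(Anorm, H, params, cfg = gcnConfig(),
                       training = FALSE) {
  gcnForwardFull(Anorm, H, params, cfg, training)$logits
}

gcnForwardFull <- function(Anorm, H, params, cfg, training, AH = NULL) {
  if (is.null(AH)) AH <- Anorm %*% H
  ab1 <- actBoth(cfg$activation, denseForward(AH, params$gc1))
  dp <- dropoutForward(ab1$y, cfg$dropout, training)
  Ah1 <- Anorm %*% dp$y
  a2 <- denseForward(Ah1, params$gc2)
  if (is.null(params$out)) {
    logits <- a2
    cache <- list(AH = AH, gA1 = ab1$g, mask = dp$mask, Ah1 = Ah1)
  } else {
    ab2 <- actBoth(cfg$activation, a2)
    logits <- denseForward(ab2$y, params$out)
    cache <- list(AH = AH, gA1 = ab1$g, mask = dp$mask, Ah1 = Ah1,
                  gA2 = ab2$g, h2 = ab2$y)
  }
  list(logits = logits, cache = cache)
}

gcnBackward <- function(dLogits, Anorm, params, cfg, cache) {
  g <- list()
  if (is.null(params$out)) {
    dA2 <- dLogits
  } else {
    bo <- denseBackward(cache$h2, params$out, dLogits)
    g$out <- list(W = bo$dW, b = bo$db)
    dA2 <- bo$dX * cache$gA2
  }
  b2 <- denseBackward(cache$Ah1, params$gc2, dA2)
  g$gc2 <- list(W = b2$dW, b = b2$db)
  dDp <- crossprod(Anorm, b2$dX)        # Anorm symmetric; kept explicit
  dH1 <- dropoutBackward(dDp, cache$mask)
  dA1 <- dH1 * cache$gA1
  b1 <- denseBackward(cache$AH, params$gc1, dA1)
  g$gc1 <- list(W = b1$dW, b = b1$db)
  g
}

softmaxRows <- function(logits) rowSoftmax(logits)

#' Train the GCN on a transductive node-classification task
#'
#' Softmax cross-entropy is computed on train-mask nodes only; test-mask
#' labels are never read. Adam with the configured learning rate, weight
#' decay and epoch count; reproducible given the config seed under
#' single-threaded BLAS.
#'
#' @param task a [GraphTask-class]
#' @param cfg a [gcnConfig()]
#' @return list with trained `params`, the normalised adjacency `Anorm`,
#'   the `cfg`, and the per-epoch train `history` of the cross-entropy loss
#' @export
trainGCN <- function(task, cfg = gcnConfig()) {
  stopifnot(is(task, "GraphTask"))
  if (!any(task@trainMask)) stop("train mask is empty")
  if (any(is.na(task@labels[task@trainMask])))
    stop("train-mask node(s) with unknown label")
  Anorm <- normalizeAdjacency(task@adjacency)
  H <- task@features
  n <- nrow(H)
  nTrain <- sum(task@trainMask)
  y <- task@labels
  withSeed(cfg$seed, {
    params <- initGCN(ncol(H), cfg$hiddenDim, task@nClasses, cfg$mergeOutput)
    state <- adamInit(params)
    history <- numeric(cfg$epochs)
    trIdx <- which(task@trainMask)
    oneHot <- matrix(0, n, task@nClasses)
    oneHot[cbind(trIdx, y[trIdx])] <- 1
    AH <- Anorm %*% H          # layer-1 input is constant across epochs
    for (ep in seq_len(cfg$epochs)) {
      fw <- gcnForwardFull(Anorm, H, params, cfg, training = TRUE, AH = AH)
      prob <- softmaxRows(fw$logits)
      history[ep] <- -mean(log(pmax(prob[cbind(trIdx, y[trIdx])], 1e-300)))
      dLogits <- matrix(0, n, task@nClasses)
      dLogits[trIdx, ] <- (prob[trIdx, , drop = FALSE] -
                             oneHot[trIdx, , drop = FALSE]) / nTrain
      grads <- gcnBackward(dLogits, Anorm, params, cfg, fw$cache)
      upd <- adamStep(params, grads, state, lr = cfg$lr,
                      weightDecay = cfg$weightDecay)
      params <- upd$params
      state <- upd$state
    }
    list(params = params, Anorm = Anorm, cfg = cfg, history = history)
  })
}

#' Predict labels and class probabilities for all nodes
#'
#' Deterministic evaluation-mode forward pass; probabilities are the row
#' softmax of the logits and predictions their argmax.
#'
#' @param task a [GraphTask-class]
#' @param fit result of [trainGCN()]
#' @return list with integer `labels` (length N) and N x nClasses
#'   `probabilities` (rows sum to 1)
#' @export
predictGCN <- function(task, fit) {
  logits <- gcnForward(fit$Anorm, task@features, fit$params, fit$cfg,
                       training = FALSE)
  prob <- softmaxRows(logits)
  list(labels = max.col(prob, ties.method = "first"),
       probabilities = prob)
}

#' Write per-cell predictions as TSV
#'
#' Columns: cell_id, true_label (NA where unknown), predicted_label,
#' max_probability.
#'
#' @param task a [GraphTask-class]
#' @param pred result of [predictGCN()]
#' @param path output TSV path
#' @param cellIds optional cell identifiers (defaults to feature rownames)
#' @return `path`, invisibly
#' @export
writePredictions <- function(task, pred, path, cellIds = NULL) {
  if (is.null(cellIds)) cellIds <- rownames(task@features)
  if (is.null(cellIds)) cellIds <- sprintf("cell%d", seq_len(nrow(task@features)))
  df <- data.frame(cell_id = cellIds,
                   true_label = task@labels,
                   predicted_label = pred$labels,
                   max_probability = apply(pred$probabilities, 1L, max))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
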