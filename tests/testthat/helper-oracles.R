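# Independent, loop-based reference implementations used as oracles.
# These deliberately mirror the written equations one scalar at a time and
# share no code with the package internals they check.

# --- SNF -------------------------------------------------------------------

oracleDistance <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  D
}

oracleAffinity <- function(D, K, mu, squared = TRUE) {
  n <- nrow(D)
  num <- if (squared) D^2 else D
  meanK <- numeric(n)
  for (i in seq_len(n))
    meanK[i] <- mean(sort(num[i, -i])[seq_len(K)])
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    eps <- (meanK[i] + meanK[j] + num[i, j]) / 3
    W[i, j] <- exp(-num[i, j] / (mu * eps))
  }
  W <- (W + t(W)) / 2
  diag(W) <- 1
  W
}

oracleFullKernel <- function(W) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sum(W[i, -i])
    for (j in seq_len(n)) P[i, j] <- if (i == j) 0.5 else W[i, j] / (2 * s)
  }
  P
}

oracleKnnKernel <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    nb <- order(w, seq_len(n), decreasing = c(TRUE, FALSE),
                method = "radix")[seq_len(K)]
    s <- sum(W[i, nb])
    for (j in nb) S[i, j] <- W[i, j] / s
  }
  S
}

oracleRenormalize <- function(P) {
  n <- nrow(P)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sum(P[i, -i])
    s <- max(s, .Machine$double.eps)
    for (j in seq_len(n)) Q[i, j] <- if (i == j) 0.5 else P[i, j] / (2 * s)
  }
  Q
}

# straight-line implementation of the cross-diffusion updates; returns every
# iterate so the vectorized pipeline can be compared step by step
oracleSnfIterates <- function(P1, P2, S1, S2, t, renormalize = TRUE) {
  out <- vector("list", t)
  for (it in seq_len(t)) {
    P1n <- S1 %*% P2 %*% t(S1)
    P2n <- S2 %*% P1 %*% t(S2)
    if (renormalize) {
      P1n <- oracleRenormalize(P1n)
      P2n <- oracleRenormalize(P2n)
    }
    P1 <- P1n
    P2 <- P2n
    out[[it]] <- list(P1 = P1, P2 = P2)
  }
  out
}

# --- attention -------------------------------------------------------------

oracleSoftmaxRow <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

oracleAttention <- function(Q, K, V) {
  n <- nrow(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    scores <- as.numeric(K %*% Q[i, ]) / sqrt(ncol(Q))
    out[i, ] <- colSums(oracleSoftmaxRow(scores) * V)
  }
  out
}

# per-head loop over the bidirectional cross-attention equations
oracleCrossAttention <- function(Zi, Zj, params, nHeads, headDim) {
  oneDir <- function(Zq, Zkv, dp) {
    outs <- NULL
    for (h in seq_len(nHeads)) {
      p <- dp$heads[[h]]
      O <- oracleAttention(Zq %*% p$Wq, Zkv %*% p$Wk, Zkv %*% p$Wv)
      outs <- cbind(outs, O)
    }
    outs %*% dp$Wo
  }
  list(headI = oneDir(Zi, Zj, params$dirI),
       headJ = oneDir(Zj, Zi, params$dirJ))
}

oracleLayerNorm <- function(X, eps = 1e-5) {
  out <- X
  for (i in seq_len(nrow(X))) {
    mu <- mean(X[i, ])
    va <- mean((X[i, ] - mu)^2)
    out[i, ] <- (X[i, ] - mu) / sqrt(va + eps)
  }
  out
}

# --- misc ------------------------------------------------------------------

# mean silhouette width over cells given class labels
silhouetteWidth <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# hand ARI from a contingency table via pair counts
oracleARI <- function(C) {
  n <- sum(C)
  sumComb <- sum(choose(C, 2))
  a <- sum(choose(rowSums(C), 2))
  b <- sum(choose(colSums(C), 2))
  e <- a * b / choose(n, 2)
  (sumComb - e) / ((a + b) / 2 - e)
}
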