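# Internal neural-network primitives: activations, dense/batch-norm/layer-norm
# layers with analytic backward passes, dropout, and an Adam optimizer.
# Everything operates on plain matrices; parameters live in named lists so
# they can be flattened for optimizer updates and checkpointing.

# GELU in the tanh approximation used by deep-learning frameworks.
GELU_C <- sqrt(2 / pi)
gelu <- function(x) {
  0.5 * x * (1 + tanh(GELU_C * (x + 0.044715 * x^3)))
}
geluGrad <- function(x) {
  th <- tanh(GELU_C * (x + 0.044715 * x^3))
  0.5 * (1 + th) + 0.5 * x * (1 - th^2) * GELU_C * (1 + 3 * 0.044715 * x^2)
}

elu <- function(x) ifelse(x > 0, x, expm1(x))
eluGrad <- function(x) ifelse(x > 0, 1, exp(x))

relu <- function(x) pmax(x, 0)
reluGrad <- function(x) (x > 0) * 1

activationFun <- function(name) {
  switch(name,
         gelu = list(f = gelu, g = geluGrad),
         elu = list(f = elu, g = eluGrad),
         relu = list(f = relu, g = reluGrad),
         linear = list(f = identity, g = function(x) array(1, dim(x))),
         stop("unknown activation: ", name))
}

# Fused value + derivative in one C pass; used inside training loops.
actBoth <- function(name, x) {
  switch(name,
         gelu = gelu_both_cpp(x),
         elu = elu_both_cpp(x),
         relu = relu_both_cpp(x),
         linear = list(y = x, g = array(1, dim(x))),
         stop("unknown activation: ", name))
}

# Glorot-uniform weight init.
initDense <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  list(W = matrix(stats::runif(nin * nout, -lim, lim), nin, nout),
       b = rep(0, nout))
}

denseForward <- function(x, p) addRowVec(x %*% p$W, p$b)

# dY -> list(dX, dW, db)
denseBackward <- function(x, p, dY) {
  list(dX = dY %*% t(p$W),
       dW = crossprod(x, dY),
       db = colSums(dY))
}

initBatchNorm <- function(dim) {
  list(gamma = rep(1, dim), beta = rep(0, dim),
       runMean = rep(0, dim), runVar = rep(1, dim))
}

BN_EPS <- 1e-5

batchNormForward <- function(x, p, training, momentum = 0.1) {
  if (training) {
    mu <- colMeans(x)
    va <- colMeans(addRowVec(x, -mu)^2)   # biased, matching framework practice
    p$runMean <- (1 - momentum) * p$runMean + momentum * mu
    p$runVar <- (1 - momentum) * p$runVar + momentum * va
  } else {
    mu <- p$runMean
    va <- p$runVar
  }
  inv <- 1 / sqrt(va + BN_EPS)
  xhat <- mulRowVec(addRowVec(x, -mu), inv)
  y <- addRowVec(mulRowVec(xhat, p$gamma), p$beta)
  list(y = y, cache = list(xhat = xhat, inv = inv, training = training),
       params = p)
}

batchNormBackward <- function(dY, p, cache) {
  xhat <- cache$xhat
  inv <- cache$inv
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- mulRowVec(dY, p$gamma)
  if (cache$training) {
    dX <- mulRowVec(addRowVec(dxhat, -colMeans(dxhat)) -
                      mulRowVec(xhat, colMeans(dxhat * xhat)), inv)
  } else {
    dX <- mulRowVec(dxhat, inv)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

LN_EPS <- 1e-5

initLayerNorm <- function(dim) list(gamma = rep(1, dim), beta = rep(0, dim))

layerNormForward <- function(x, p) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + LN_EPS)
  xhat <- xc * inv
  y <- addRowVec(mulRowVec(xhat, p$gamma), p$beta)
  list(y = y, cache = list(xhat = xhat, inv = inv))
}

layerNormBackward <- function(dY, p, cache) {
  xhat <- cache$xhat
  inv <- cache$inv
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- mulRowVec(dY, p$gamma)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Inverted dropout; mask drawn from the current RNG stream.
dropoutForward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1L, 1 - rate), nrow(x), ncol(x)) /
    (1 - rate)
  list(y = x * mask, mask = mask)
}

dropoutBackward <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# --- Adam -------------------------------------------------------------------
# Parameters and gradients are nested named lists of numeric arrays with
# identical structure; adamStep walks them recursively.

adamInit <- function(params) {
  zero <- function(p) {
    if (is.list(p)) lapply(p, zero) else p * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8, weightDecay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next   # frozen branch
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      if (weightDecay > 0) g <- g + weightDecay * p
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Elementwise sum of two grad lists with the same structure (NULL = zero).
gradAdd <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in union(names(a), names(b))) a[[nm]] <- gradAdd(a[[nm]], b[[nm]])
    a
  } else a + b
}

gradScale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) lapply(g, gradScale, s = s) else g * s
}
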