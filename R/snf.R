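# Similarity network fusion: per-modality affinity kernels with local
# scaling, full (row-stochastic, diagonal 1/2) and sparse kNN transition
# kernels, and the cross-diffusion iteration whose average yields the fused
# cell similarity matrix used as the GCN adjacency.

#' SNF configuration
#'
#' @param nNeighbors K, the neighbourhood size (default 9)
#' @param mu kernel scale parameter in (0, 1] (default 0.5)
#' @param iterations number of cross-diffusion iterations t (default 20)
#' @param distance `"squared_euclidean"` (default) or `"euclidean"`;
#'   controls the exponent numerator of the affinity kernel
#' @return a named config list
#' @export
snfConfig <- function(nNeighbors = 9, mu = 0.5, iterations = 20,
                      distance = c("squared_euclidean", "euclidean")) {
  stopifnot(nNeighbors >= 1, mu > 0, iterations >= 1)
  list(nNeighbors = as.integer(nNeighbors), mu = mu,
       iterations = as.integer(iterations), distance = match.arg(distance))
}

#' Pairwise Euclidean distances between cells
#'
#' @param X N x d matrix (or [LatentEmbedding-class])
#' @param squared return squared distances (default `FALSE`)
#' @return symmetric nonnegative N x N matrix with zero diagonal
#' @export
pairwiseDistance <- function(X, squared = FALSE) {
  X <- extractMatrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  d2 <- (d2 + t(d2)) / 2
  diag(d2) <- 0
  if (squared) d2 else sqrt(d2)
}

#' Locally scaled affinity kernel
#'
#' `W(i,j) = exp(-rho(i,j)^2 / (mu * eps_ij))` with the local scale
#' `eps_ij = (meanDistToK(i) + meanDistToK(j) + rho(i,j)^2) / 3`, where
#' `meanDistToK` is the mean squared distance to the K nearest neighbours
#' (self excluded); with `distance = "euclidean"` both the numerator and the
#' scale use unsquared distances. The diagonal is exactly 1 and the matrix
#' symmetric.
#'
#' @param dist symmetric N x N Euclidean distance matrix
#' @param config an [snfConfig()]
#' @return symmetric nonnegative N x N affinity matrix W
#' @export
affinityMatrix <- function(dist, config = snfConfig()) {
  n <- nrow(dist)
  if (max(abs(dist - t(dist))) > 1e-8) stop("dist must be symmetric")
  K <- min(config$nNeighbors, n - 1L)
  # numerator and local scale live in the same (by default squared) domain,
  # which keeps the exponent scale-free and bounded
  num <- if (config$distance == "squared_euclidean") dist^2 else dist
  meanK <- vapply(seq_len(n), function(i) {
    di <- sort(num[i, -i], partial = K)[seq_len(K)]
    mean(di)
  }, numeric(1))
  eps <- (outer(meanK, meanK, `+`) + num) / 3
  small <- eps <= 0
  if (any(small)) {
    warning("coincident points: local scale floored at machine epsilon")
    eps[small] <- .Machine$double.eps
  }
  W <- exp(-num / (config$mu * eps))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  W
}

#' Full transition kernel
#'
#' `P(i,j) = W(i,j) / (2 * sum_{k != i} W(i,k))` off the diagonal and
#' exactly 1/2 on it, so every row sums to 1.
#'
#' @param W nonnegative affinity matrix with positive off-diagonal row sums
#' @return row-stochastic N x N matrix P
#' @export
fullKernel <- function(W) {
  n <- nrow(W)
  off <- rowSums(W) - diag(W)
  if (any(off <= 0)) {
    bad <- which(off <= 0)[1]
    stop("isolated cell (zero off-diagonal affinity) at row ", bad)
  }
  P <- W / (2 * off)
  diag(P) <- 0.5
  P
}

#' Sparse kNN transition kernel
#'
#' Keeps, per row, only the K most similar other cells and row-normalises
#' over that support: `S(i,j) = W(i,j) / sum_{k in N_i} W(i,k)` for j in the
#' neighbour set, else 0. Ties at the K-th neighbour break towards the
#' smaller column index.
#'
#' @param W nonnegative affinity matrix
#' @param K neighbourhood size, `K < N`
#' @return N x N row-stochastic-on-support matrix S (generally asymmetric)
#' @export
knnKernel <- function(W, K) {
  n <- nrow(W)
  if (K >= n) stop("K must be < number of cells")
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf                       # self never a neighbour
    ord <- order(w, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
    nb <- ord[seq_len(K)]
    s <- sum(W[i, nb])
    if (s <= 0) stop("cell ", i, " has zero affinity to all its K neighbours")
    S[i, nb] <- W[i, nb] / s
  }
  S
}

# Restore the full-kernel structure (diag 1/2, off-diagonal row mass 1/2)
# after a diffusion step.
renormalizeKernel <- function(P) {
  off <- rowSums(P) - diag(P)
  off[off <= 0] <- .Machine$double.eps
  Q <- P / (2 * off)
  diag(Q) <- 0.5
  Q
}

#' Cross-diffusion fusion of two modality kernels
#'
#' Iterates the simultaneous updates `P1 <- S1 P2 S1'` and `P2 <- S2 P1 S2'`
#' (each from the previous iterates), renormalising after every step to
#' restore the full-kernel structure unless `renormalize = FALSE`, and
#' returns the symmetrised average `(P1 + P2)/2`. Iteration stops early once
#' the two iterates agree to relative Frobenius tolerance `tol`.
#'
#' @param P1,P2 full kernels of the two modalities (from [fullKernel()])
#' @param S1,S2 kNN kernels of the two modalities (from [knnKernel()])
#' @param t maximum number of iterations (default 20)
#' @param renormalize restore row-stochastic structure after each update
#'   (default `TRUE`; `FALSE` follows the literal update equations)
#' @param tol early-stopping tolerance on `||P1 - P2||_F / ||P1||_F`
#' @param trace return the per-iteration iterates as attribute `"trace"`
#' @return fused symmetric N x N similarity matrix
#' @export
snfFuse <- function(P1, P2, S1, S2, t = 20, renormalize = TRUE,
                    tol = 1e-6, trace = FALSE) {
  dims <- dim(P1)
  if (!all(vapply(list(P2, S1, S2), function(m) all(dim(m) == dims),
                  logical(1))))
    stop("P1, P2, S1, S2 must all be N x N with the same N")
  if (t < 1) stop("t must be >= 1")
  tr <- if (trace) vector("list", t) else NULL
  for (it in seq_len(t)) {
    P1new <- S1 %*% P2 %*% t(S1)
    P2new <- S2 %*% P1 %*% t(S2)
    if (renormalize) {
      P1new <- renormalizeKernel(P1new)
      P2new <- renormalizeKernel(P2new)
    }
    P1 <- P1new
    P2 <- P2new
    if (trace) tr[[it]] <- list(P1 = P1, P2 = P2)
    if (norm(P1 - P2, "F") / norm(P1, "F") < tol) {
      if (trace) tr <- tr[seq_len(it)]
      break
    }
  }
  fused <- (P1 + P2) / 2
  fused <- (fused + t(fused)) / 2
  if (trace) attr(fused, "trace") <- tr
  fused
}

#' Per-modality similarity kernels and fused matrix in one call
#'
#' Convenience wrapper building W, P and S for each modality embedding and
#' running [snfFuse()]; results are returned as a
#' [SimilarityBundle-class].
#'
#' @param embeddings list of per-modality N x d matrices (or
#'   [LatentEmbedding-class]s); exactly two modalities
#' @param config an [snfConfig()]
#' @return a [SimilarityBundle-class]
#' @export
buildSimilarityBundle <- function(embeddings, config = snfConfig()) {
  if (length(embeddings) != 2)
    stop("cross-diffusion is defined for exactly two modalities")
  W <- lapply(embeddings, function(e)
    affinityMatrix(pairwiseDistance(e), config))
  P <- lapply(W, fullKernel)
  S <- lapply(W, knnKernel, K = config$nNeighbors)
  fused <- snfFuse(P[[1]], P[[2]], S[[1]], S[[2]], t = config$iterations)
  new("SimilarityBundle", W = W, P = P, S = S, fused = fused)
}

#' Build the GCN adjacency from the fused similarity matrix
#'
#' Optionally sparsifies to the top-K entries per row (re-symmetrised) and
#' adds self loops.
#'
#' @param fused symmetric nonnegative matrix (or [SimilarityBundle-class])
#' @param selfLoops add the identity (default `TRUE`)
#' @param topK keep only the K largest entries per row before
#'   re-symmetrising; `NULL` (default) keeps the dense matrix
#' @return symmetric nonnegative adjacency matrix A
#' @export
buildAdjacency <- function(fused, selfLoops = TRUE, topK = NULL) {
  if (is(fused, "SimilarityBundle")) fused <- fusedSimilarity(fused)
  if (min(fused) < 0) stop("fused similarity must be nonnegative")
  A <- fused
  if (!is.null(topK)) {
    n <- nrow(A)
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      w <- A[i, ]; w[i] <- -Inf
      nb <- order(w, seq_len(n), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(min(topK, n - 1L))]
      keep[i, nb] <- TRUE
    }
    keep <- keep | t(keep)
    A[!keep] <- 0
  }
  A <- (A + t(A)) / 2
  if (selfLoops) A <- A + diag(nrow(A))
  A
}

#' Write the fused similarity graph as an edge list
#'
#' @param fused symmetric similarity matrix (or [SimilarityBundle-class])
#' @param path output TSV path (columns i, j, weight; upper triangle,
#'   nonzero entries only)
#' @return `path`, invisibly
#' @export
writeEdgeList <- function(fused, path) {
  if (is(fused, "SimilarityBundle")) fused <- fusedSimilarity(fused)
  idx <- which(upper.tri(fused) & fused != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], weight = fused[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
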