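# Internal helpers shared across modules.

#' @importFrom stats rnorm runif rpois rbinom
NULL

# Row-wise softmax with max subtraction for numerical stability (C kernel).
rowSoftmax <- function(x) softmax_rows_cpp(x)

# m + b broadcast over rows / columnwise scaling (C kernels).
addRowVec <- function(m, v) add_row_vec_cpp(m, v)
mulRowVec <- function(m, v) mul_row_vec_cpp(m, v)

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic fan-out of one master seed into per-component seeds,
# kept inside 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset * 7919) %% 2147483647)
}

# Polynomial rolling hash of a character scalar (stays within exact-double
# integer range); used for run-manifest config hashes.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

stopifnotMatrix <- function(x, what = "input") {
  if (!is.matrix(x) && !inherits(x, "Matrix"))
    stop(what, " must be a matrix", call. = FALSE)
}

asDense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}
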