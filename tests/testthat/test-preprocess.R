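# QC filtering, normalisation, feature selection and linear reduction.

test_that("filterCells applies modality-specific bounds and preserves order", {
  m <- randomCounts(4, 6, "rna")
  qc <- passingQC(cellIds(m))
  qc$n_genes_detected <- c(250, 1000, 20000, 5000)  # low, ok, high, ok
  qc$pct_mito <- c(0.01, 0.01, 0.01, 0.2)           # last fails mito
  out <- filterCells(m, qc)
  expect_identical(cellIds(out), cellIds(m)[2])

  a <- randomCounts(3, 5, "atac")
  qa <- passingQC(cellIds(a))
  qa$tss_enrichment <- c(3.5, 2.0, 5)   # >3 required; cell 2 fails
  qa$nucleosome_signal <- c(2, 1, 1)
  qa$n_fragments_in_peaks <- c(5000, 5000, 1000)  # cell 3 fails
  qa$blacklist_fraction <- c(0.01, 0.01, 0.01)
  out <- filterCells(a, qa)
  expect_identical(cellIds(out), cellIds(a)[1])
})

test_that("filterCells is an identity on all-passing cells and drops dead genes", {
  v <- matrix(rpois(20, 2), 4, 5,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:5)))
  v[, 3] <- 0
  m <- OmicsMatrix(v, "rna")
  out <- filterCells(m, passingQC(cellIds(m)))
  expect_identical(cellIds(out), cellIds(m))
  expect_identical(featureIds(out), paste0("g", c(1, 2, 4, 5)))
  # idempotent
  out2 <- filterCells(out, passingQC(cellIds(out)))
  expect_equal(omicsValues(out2), omicsValues(out))
})

test_that("filterCells errors on a missing QC record, naming the cell", {
  m <- randomCounts(3, 4, "rna")
  qc <- passingQC(cellIds(m)[-2])
  expect_error(filterCells(m, qc), "c2")
})

test_that("logNormalize matches the closed form and a scalar-loop oracle", {
  m <- OmicsMatrix(matrix(c(10, 0), 1, 2,
                          dimnames = list("c1", c("g1", "g2"))), "rna")
  out <- omicsValues(logNormalize(m))
  expect_equal(as.numeric(out), c(log(1 + 1e4), 0))

  v <- matrix(c(3, 1, 0, 2, 5, 4), 3, 2,
              dimnames = list(paste0("c", 1:3), c("g1", "g2")))
  m <- OmicsMatrix(v, "rna")
  out <- omicsValues(logNormalize(m))
  oracle <- v
  for (i in 1:3) for (j in 1:2)
    oracle[i, j] <- log(1 + 1e4 * v[i, j] / sum(v[i, ]))
  expect_equal(out, oracle, tolerance = 1e-12)

  # all-equal counts per cell give identical normalized rows
  v2 <- matrix(2, 3, 4, dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  o2 <- omicsValues(logNormalize(OmicsMatrix(v2, "rna")))
  expect_equal(o2[1, ], o2[2, ])
  expect_error(logNormalize(OmicsMatrix(
    matrix(c(1, 0), 2, 1, dimnames = list(c("a", "b"), "g")), "rna")),
    "zero total")
})

test_that("lognormalized values invert back to per-cell proportions", {
  m <- randomCounts(5, 8, "rna", seed = 3, lambda = 5)
  v <- omicsValues(m)
  out <- omicsValues(logNormalize(m))
  rec <- expm1(out) / 1e4            # = x / total per cell
  expect_equal(rec, v / rowSums(v), tolerance = 1e-10)
})

test_that("variance-stabilised HVG selection ranks planted variance first", {
  set.seed(7)
  n <- 200; d <- 100
  mu <- runif(d, 1, 20)
  v <- sapply(mu, function(m) rnbinom(n, mu = m, size = 5))
  # gene 1: same mean, much larger variance (smaller size)
  v[, 1] <- rnbinom(n, mu = mu[1], size = 0.1)
  dimnames(v) <- list(sprintf("c%d", 1:n), sprintf("g%d", 1:d))
  m <- OmicsMatrix(v, "rna")
  idx <- selectVariableFeatures(m, nFeatures = 10)
  expect_equal(idx[1], 1L)
  # constant gene ranks last
  v2 <- v; v2[, 2] <- 4
  m2 <- OmicsMatrix(v2, "rna")
  all_idx <- selectVariableFeatures(m2, nFeatures = d)
  expect_equal(all_idx[d], 2L)
  expect_setequal(selectVariableFeatures(m, nFeatures = d), seq_len(d))
  expect_error(selectVariableFeatures(m, nFeatures = d + 1), "exceeds")
})

test_that("TF-IDF matches a scalar-loop oracle and keeps zeros", {
  v <- matrix(c(2, 0, 1, 1, 3, 2), 3, 2,
              dimnames = list(paste0("c", 1:3), c("p1", "p2")))
  m <- OmicsMatrix(v, "atac")
  out <- omicsValues(tfidfNormalize(m))
  oracle <- v
  det <- colSums(v > 0)
  for (i in 1:3) for (j in 1:2) {
    tf <- v[i, j] / sum(v[i, ])
    idf <- 3 / det[j]
    oracle[i, j] <- log(1 + tf * idf * 1e4)
  }
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_equal(out[2, 1], 0)

  # plain variant
  outp <- omicsValues(tfidfNormalize(m, variant = "plain"))
  expect_equal(outp[1, 1], (2 / 3) * (3 / 2), tolerance = 1e-12)

  # peak present in all cells with identical totals -> constant column
  v2 <- matrix(c(1, 1, 1, 2, 2, 2), 3, 2,
               dimnames = list(paste0("c", 1:3), c("p1", "p2")))
  o2 <- omicsValues(tfidfNormalize(OmicsMatrix(v2, "atac")))
  expect_equal(length(unique(o2[, 1])), 1L)

  v3 <- matrix(c(2, 1, 1, 0, 0, 0), 3, 2,
               dimnames = list(paste0("c", 1:3), c("p1", "p2")))
  expect_error(tfidfNormalize(OmicsMatrix(v3, "atac")), "zero cells")
})

test_that("scaleFeatures centres, scales, zeroes constants and clips", {
  set.seed(1)
  v <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("c", 1:10), paste0("f", 1:6)))
  v[, 2] <- 7                       # constant feature
  m <- OmicsMatrix(v, "rna", layer = "normalized")
  out <- omicsValues(scaleFeatures(m))
  expect_lt(max(abs(colMeans(out[, -2]))), 1e-10)
  expect_equal(out[, 2], setNames(rep(0, 10), rownames(v)))
  # a 50-sd outlier is clipped to the default bound of 10
  w <- matrix(rnorm(500), 500, 1,
              dimnames = list(sprintf("c%d", 1:500), "f1"))
  w[1, 1] <- mean(w[-1, 1]) + 50 * sd(w[-1, 1])
  out <- omicsValues(scaleFeatures(OmicsMatrix(w, "rna", layer = "normalized")))
  expect_equal(max(out), 10)
})

test_that("PCA scores match the covariance eigendecomposition", {
  set.seed(5)
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("c", 1:10), paste0("f", 1:4)))
  m <- OmicsMatrix(v, "rna", layer = "normalized")
  emb <- reduceDimension(m, 3, method = "pca")
  sc <- omicsValues(emb)
  ev <- eigen(stats::cov(v))
  centered <- scale(v, scale = FALSE)
  oracle <- centered %*% ev$vectors[, 1:3]
  for (j in 1:3)   # eigenvector signs are arbitrary; compare up to sign
    expect_true(max(abs(sc[, j] - oracle[, j])) < 1e-8 ||
                  max(abs(sc[, j] + oracle[, j])) < 1e-8)
  L <- attr(emb, "loadings")
  expect_equal(crossprod(L), diag(3), tolerance = 1e-8)
})

test_that("exact low-rank data is reconstructed by as many components", {
  set.seed(6)
  base <- matrix(rnorm(20), 10, 2)
  v <- base %*% matrix(rnorm(10), 2, 5)
  dimnames(v) <- list(paste0("c", 1:10), paste0("f", 1:5))
  m <- OmicsMatrix(v, "rna", layer = "normalized")
  emb <- reduceDimension(m, 2, method = "pca")
  rec <- omicsValues(emb) %*% t(attr(emb, "loadings"))
  centered <- scale(v, scale = FALSE)
  expect_lt(max(abs(rec - centered)), 1e-8)
  expect_error(reduceDimension(m, 5, method = "pca"), "nComponents")
})

test_that("LSI drops the first component and PCA is permutation-invariant", {
  set.seed(8)
  v <- matrix(rexp(200), 20, 10,
              dimnames = list(paste0("c", 1:20), paste0("f", 1:10)))
  m <- OmicsMatrix(v, "atac", layer = "normalized")
  lsi <- reduceDimension(m, 3, method = "lsi")
  sv <- svd(v)
  # component 1 of the returned embedding corresponds to singular vector 2
  expect_equal(abs(cor(omicsValues(lsi)[, 1], sv$u[, 2])), 1, tolerance = 1e-8)

  perm <- sample(10)
  mp <- OmicsMatrix(v[, perm], "rna", layer = "normalized")
  p1 <- omicsValues(reduceDimension(OmicsMatrix(v, "rna", layer = "normalized"),
                                    3, method = "pca"))
  p2 <- omicsValues(reduceDimension(mp, 3, method = "pca"))
  for (j in 1:3)
    expect_true(max(abs(p1[, j] - p2[, j])) < 1e-8 ||
                  max(abs(p1[, j] + p2[, j])) < 1e-8)
})

test_that("the QC report records per-cell pass status", {
  qc <- passingQC(c("a", "b"))
  qc$pct_mito[2] <- 0.3
  path <- withr::local_tempfile(fileext = ".tsv")
  rep <- writeQCReport(qc, "rna", path)
  expect_equal(rep$pass, c(TRUE, FALSE))
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$pass, c(TRUE, FALSE))
})
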