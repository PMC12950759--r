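# Clustering and classification metrics, the k-means evaluation protocol,
# stratified and donor-grouped cross-validation, the seed-averaged
# experiment runner, and paired significance tests.

#' k-means clustering with k-means++ seeding
#'
#' Lloyd iterations from k-means++ initial centres, best of `nInit`
#' restarts by total within-cluster sum of squares; deterministic given
#' `seed`.
#'
#' @param X N x d matrix (or [LatentEmbedding-class])
#' @param k number of clusters, `k <= N`
#' @param seed RNG seed
#' @param nInit number of restarts (default 10)
#' @return integer cluster labels of length N
#' @export
kmeansCluster <- function(X, k, seed = 0, nInit = 10) {
  X <- extractMatrix(X)
  n <- nrow(X)
  if (k > n) stop("k must be <= number of cells (", n, ")")
  if (k == n) return(seq_len(n))
  withSeed(seed, {
    best <- NULL
    bestSS <- Inf
    for (r in seq_len(nInit)) {
      centers <- kmeansPlusPlus(X, k)
      fit <- tryCatch(
        stats::kmeans(X, centers = centers, iter.max = 100,
                      algorithm = "Lloyd"),
        error = function(e) NULL,
        warning = function(w) suppressWarnings(
          stats::kmeans(X, centers = centers, iter.max = 200,
                        algorithm = "Lloyd")))
      if (is.null(fit)) next
      if (fit$tot.withinss < bestSS) {
        bestSS <- fit$tot.withinss
        best <- fit$cluster
      }
    }
    if (is.null(best)) stop("k-means failed in all restarts")
    as.integer(best)
  })
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance to the nearest chosen centre.
kmeansPlusPlus <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[idx[1], ])^2)
  for (j in seq_len(k - 1L)) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
    idx[j + 1L] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx[j + 1L], ])^2))
  }
  X[idx, , drop = FALSE]
}

contingencyTable <- function(a, b) {
  table(factor(a), factor(b))
}

#' Clustering agreement metrics: ARI, NMI, AMI
#'
#' Contingency-table adjusted Rand index, normalised mutual information
#' with arithmetic normalisation, and adjusted mutual information with the
#' expected-MI correction. All are invariant to label permutations.
#'
#' @param trueLabels,predLabels equal-length label vectors
#' @return named list `ari`, `nmi`, `ami`
#' @export
clusteringMetrics <- function(trueLabels, predLabels) {
  if (length(trueLabels) != length(predLabels))
    stop("label vectors must have equal length")
  C <- contingencyTable(trueLabels, predLabels)
  n <- sum(C)
  a <- rowSums(C)
  b <- colSums(C)

  # ARI via pair counts
  sumComb <- sum(choose(C, 2))
  sumA <- sum(choose(a, 2))
  sumB <- sum(choose(b, 2))
  expected <- sumA * sumB / choose(n, 2)
  maxIdx <- (sumA + sumB) / 2
  ari <- if (maxIdx == expected) 1 else (sumComb - expected) / (maxIdx - expected)

  # entropies and mutual information (natural log)
  pa <- a / n; pb <- b / n
  hu <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hv <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  nij <- C[C > 0]
  outerAB <- outer(a, b)[C > 0]
  mi <- sum(nij / n * log(n * nij / outerAB))
  mean_h <- (hu + hv) / 2
  nmi <- if (mean_h == 0) 1 else mi / mean_h

  emi <- expectedMutualInformation(a, b, n)
  denom <- mean_h - emi
  ami <- if (abs(denom) < .Machine$double.eps) 1 else (mi - emi) / denom

  list(ari = ari, nmi = nmi, ami = ami)
}

# Expected mutual information between random partitions with fixed
# marginals, via the hypergeometric distribution of cell counts.
expectedMutualInformation <- function(a, b, n) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      pr <- stats::dhyper(nij, ai, n - ai, bj)
      emi <- emi + sum(nij / n * log(n * nij / (ai * bj)) * pr)
    }
  }
  emi
}

#' Classification metrics: accuracy, weighted F1, weighted precision
#'
#' Accuracy is the fraction correct; F1 and precision are computed per class
#' and averaged with weights proportional to the class support in the true
#' labels. A class never predicted contributes precision 0 (with a
#' warning).
#'
#' @param trueLabels,predLabels equal-length label vectors over the same
#'   class set
#' @param weighted support-weighted averaging (default); `FALSE` for plain
#'   macro averaging
#' @return named list `acc`, `weighted_f1`, `precision`
#' @export
classificationMetrics <- function(trueLabels, predLabels, weighted = TRUE) {
  if (length(trueLabels) != length(predLabels))
    stop("label vectors must have equal length")
  classes <- sort(unique(c(as.character(trueLabels), as.character(predLabels))))
  tl <- factor(as.character(trueLabels), levels = classes)
  pl <- factor(as.character(predLabels), levels = classes)
  C <- table(tl, pl)
  support <- rowSums(C)
  tp <- diag(C)
  predCount <- colSums(C)
  if (any(predCount == 0 & support > 0))
    warning("class(es) absent from predictions; their precision counted as 0: ",
            paste(classes[predCount == 0 & support > 0], collapse = ", "))
  prec <- ifelse(predCount > 0, tp / predCount, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  keep <- support > 0
  w <- if (weighted) support[keep] / sum(support[keep])
       else rep(1 / sum(keep), sum(keep))
  list(acc = mean(tl == pl),
       weighted_f1 = sum(f1[keep] * w),
       precision = sum(prec[keep] * w))
}

#' Build a cross-validation plan
#'
#' Stratified k-fold keeps per-fold class proportions within one cell of
#' the overall distribution; donor-grouped k-fold assigns all cells of a
#' donor to a single fold, balancing folds by cell count.
#'
#' @param labels class labels (used by the stratified scheme)
#' @param donors donor ids (required by the grouped scheme)
#' @param scheme `"stratified_kfold"` or `"grouped_kfold"`
#' @param nFolds number of folds
#' @param seed RNG seed for the shuffles
#' @return list with `scheme`, `nFolds`, `seed` and `folds`, a list of test
#'   index vectors partitioning all cells
#' @export
makeCVPlan <- function(labels, donors = NULL,
                       scheme = c("stratified_kfold", "grouped_kfold"),
                       nFolds = 5, seed = 0) {
  scheme <- match.arg(scheme)
  n <- length(labels)
  folds <- withSeed(seed, {
    if (scheme == "stratified_kfold") {
      assign <- integer(n)
      offset <- 0L
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        assign[idx] <- ((offset + seq_along(idx) - 1L) %% nFolds) + 1L
        offset <- offset + length(idx)
      }
      lapply(seq_len(nFolds), function(f) which(assign == f))
    } else {
      if (is.null(donors)) stop("grouped scheme requires donor ids")
      ud <- unique(donors)
      if (length(ud) < nFolds)
        stop("fewer donors (", length(ud), ") than folds (", nFolds, ")")
      ud <- sample(ud)
      sizes <- vapply(ud, function(d) sum(donors == d), numeric(1))
      ord <- order(sizes, decreasing = TRUE)
      foldSize <- numeric(nFolds)
      donorFold <- integer(length(ud))
      for (i in ord) {
        f <- which.min(foldSize)
        donorFold[i] <- f
        foldSize[f] <- foldSize[f] + sizes[i]
      }
      lapply(seq_len(nFolds), function(f)
        which(donors %in% ud[donorFold == f]))
    }
  })
  list(scheme = scheme, nFolds = nFolds, seed = seed, folds = folds)
}

#' Paired t-test and Wilcoxon signed-rank test
#'
#' The Wilcoxon statistic is reported as the smaller of the positive- and
#' negative-rank sums (so one-sided dominance gives W near 0). When all
#' paired differences are zero the Wilcoxon test is undefined and reported
#' as `NA` with a note.
#'
#' @param metricA,metricB equal-length (>= 5) paired metric vectors
#' @return named list `t_statistic`, `p_t`, `wilcoxon_W`, `p_w`, `note`
#' @export
pairedTests <- function(metricA, metricB) {
  if (length(metricA) != length(metricB))
    stop("paired vectors must have equal length")
  if (length(metricA) < 5) stop("need at least 5 paired observations")
  d <- metricA - metricB
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    pt <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(metricA, metricB, paired = TRUE)
    tstat <- unname(tt$statistic)
    pt <- tt$p.value
  }
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(list(t_statistic = tstat, p_t = pt, wilcoxon_W = NA_real_,
                p_w = NA_real_, note = "all paired differences are zero"))
  }
  r <- rank(abs(nz))
  wPos <- sum(r[nz > 0])
  wNeg <- sum(r[nz < 0])
  wt <- suppressWarnings(stats::wilcox.test(metricA, metricB, paired = TRUE))
  list(t_statistic = tstat, p_t = pt,
       wilcoxon_W = min(wPos, wNeg), p_w = wt$p.value, note = NA_character_)
}

#' Default configuration for the experiment runner
#'
#' @param nHvg highly variable genes kept (default 2000)
#' @param topPeakFraction fraction of peaks kept by detection (default 0.25)
#' @param nPcs,nLsi PCA / LSI components fed to the autoencoders (default 50)
#' @param aeEpochs,fusionEpochs,gcnEpochs stage epoch counts (runner
#'   defaults 100/50/150; the autoencoders are pretrained once per seed and
#'   frozen during per-fold fusion training)
#' @param fusionMethod fusion architecture (see [trainFusion()])
#' @param nHeads attention heads (default 4)
#' @param latentDim shared latent dimension d (default 128)
#' @param hiddenDim autoencoder hidden width (default 512)
#' @param temperature contrastive temperature (default 0.5)
#' @param lambda contrastive weight (default 1)
#' @param snfK,snfMu,snfIterations SNF hyperparameters (defaults 9, 0.5, 20)
#' @param gcnHidden,gcnDropout,gcnLr,gcnWeightDecay GCN hyperparameters
#' @param clusterOn evaluate integration k-means on `"all"` cells (default)
#'   or `"test"` fold only
#' @return nested config list understood by [runExperiment()]
#' @export
experimentConfig <- function(nHvg = 2000, topPeakFraction = 0.25,
                             nPcs = 50, nLsi = 50,
                             aeEpochs = 100, fusionEpochs = 50,
                             gcnEpochs = 150, fusionMethod = "mhca",
                             nHeads = 4, latentDim = 128, hiddenDim = 512,
                             temperature = 0.5, lambda = 1,
                             snfK = 9, snfMu = 0.5, snfIterations = 20,
                             gcnHidden = 64, gcnDropout = 0.5,
                             gcnLr = 0.001, gcnWeightDecay = 0.01,
                             clusterOn = c("all", "test")) {
  list(preprocess = list(nHvg = nHvg, topPeakFraction = topPeakFraction,
                         nPcs = nPcs, nLsi = nLsi),
       ae = list(epochs = aeEpochs, hiddenDim = hiddenDim,
                 latentDim = latentDim, lr = 1e-3),
       fusion = list(method = fusionMethod, heads = nHeads,
                     temperature = temperature, lambda = lambda,
                     epochs = fusionEpochs, lr = 1e-3, finetune = FALSE),
       snf = list(k = snfK, mu = snfMu, iterations = snfIterations),
       gcn = list(hiddenDim = gcnHidden, dropout = gcnDropout, lr = gcnLr,
                  weightDecay = gcnWeightDecay, epochs = gcnEpochs),
       eval = list(kmeansRestarts = 10, clusterOn = match.arg(clusterOn)))
}

# Subset an OmicsMatrix to a set of feature columns.
subsetFeatures <- function(x, idx) {
  OmicsMatrix(omicsValues(x)[, idx, drop = FALSE],
              modality = modality(x), layer = layerType(x))
}

#' Modality-specific preprocessing to reduced embeddings
#'
#' RNA: HVG selection on counts, LogNormalize, centre/scale/clip, PCA.
#' ATAC: top-peak selection by detection, TF-IDF, LSI (first component
#' dropped).
#'
#' @param rna,atac count-layer [OmicsMatrix-class]s
#' @param config an [experimentConfig()] (its `$preprocess` section is used)
#' @return list of two [LatentEmbedding-class]s (`rna`, `atac`)
#' @export
preprocessPair <- function(rna, atac, config = experimentConfig()) {
  pp <- config$preprocess
  nHvg <- min(pp$nHvg, ncol(omicsValues(rna)))
  hvg <- selectVariableFeatures(rna, nFeatures = nHvg)
  rnaScaled <- scaleFeatures(subsetFeatures(logNormalize(rna), hvg))
  rnaRed <- reduceDimension(rnaScaled, pp$nPcs, method = "pca")
  top <- findTopFeatures(atac, fraction = pp$topPeakFraction)
  atacTf <- tfidfNormalize(subsetFeatures(atac, top))
  atacRed <- reduceDimension(atacTf, pp$nLsi, method = "lsi")
  list(rna = rnaRed, atac = atacRed)
}

#' Run the full pipeline across seeds and CV folds
#'
#' For each seed the autoencoders are pretrained (label-free); for each
#' fold the fusion is trained with the fold's train labels only, the
#' similarity network fused, and the GCN trained transductively with test
#' labels masked. Integration metrics come from k-means on the fused
#' embedding with k equal to the number of true classes; classification
#' metrics are computed on the held-out fold.
#'
#' @param rna,atac count-layer [OmicsMatrix-class]s with matched cells
#' @param labels cell-type labels, length N
#' @param donors donor ids (required for grouped CV), or `NULL`
#' @param config an [experimentConfig()]
#' @param plan a [makeCVPlan()] result
#' @param seeds integer vector of run seeds
#' @return list with `records` (one row per seed x fold) and `summary`
#'   (mean, sd, min, max per metric)
#' @export
runExperiment <- function(rna, atac, labels, donors = NULL,
                          config = experimentConfig(),
                          plan = NULL, seeds = 0:2) {
  labels <- as.factor(labels)
  n <- length(labels)
  k <- nlevels(labels)
  if (is.null(plan))
    plan <- makeCVPlan(labels, donors, "stratified_kfold", nFolds = 5,
                       seed = seeds[1])
  red <- preprocessPair(rna, atac, config)
  snfCfg <- snfConfig(nNeighbors = config$snf$k, mu = config$snf$mu,
                      iterations = config$snf$iterations)
  bundle <- buildSimilarityBundle(list(red$rna, red$atac), snfCfg)
  A <- buildAdjacency(bundle)
  attnCfg <- attentionConfig(nHeads = config$fusion$heads,
                             modelDim = config$ae$latentDim)
  contrastCfg <- contrastiveConfig(temperature = config$fusion$temperature,
                                   lambda = config$fusion$lambda)
  rows <- list()
  for (seed in seeds) {
    aeFit <- trainDualAE(red$rna, red$atac,
                         rnaConfig = aeConfig(ncol(omicsValues(red$rna)),
                                              hiddenDim = config$ae$hiddenDim,
                                              latentDim = config$ae$latentDim),
                         atacConfig = aeConfig(ncol(omicsValues(red$atac)),
                                               hiddenDim = config$ae$hiddenDim,
                                               latentDim = config$ae$latentDim),
                         epochs = config$ae$epochs, lr = config$ae$lr,
                         seed = deriveSeed(seed, 1))
    for (f in seq_along(plan$folds)) {
      testIdx <- plan$folds[[f]]
      trainMask <- rep(TRUE, n)
      trainMask[testIdx] <- FALSE
      fus <- trainFusion(red$rna, red$atac, aeFit,
                         labels = labels, trainMask = trainMask,
                         method = config$fusion$method,
                         attnCfg = attnCfg,
                         contrastCfg = contrastCfg,
                         epochs = config$fusion$epochs,
                         lr = config$fusion$lr,
                         seed = deriveSeed(seed, 100 + f),
                         finetuneEncoders = config$fusion$finetune)
      Zf <- omicsValues(fus$fused)
      clusterIdx <- if (config$eval$clusterOn == "test") testIdx else seq_len(n)
      km <- kmeansCluster(Zf[clusterIdx, , drop = FALSE], k,
                          seed = deriveSeed(seed, 300 + f),
                          nInit = config$eval$kmeansRestarts)
      cm <- clusteringMetrics(as.integer(labels)[clusterIdx], km)
      maskedLabels <- as.integer(labels)
      maskedLabels[testIdx] <- NA_integer_
      task <- GraphTask(A, Zf, maskedLabels,
                        trainMask = trainMask,
                        testMask = !trainMask, nClasses = k)
      gcnCfg <- gcnConfig(hiddenDim = config$gcn$hiddenDim,
                          dropout = config$gcn$dropout, lr = config$gcn$lr,
                          weightDecay = config$gcn$weightDecay,
                          epochs = config$gcn$epochs,
                          seed = deriveSeed(seed, 200 + f))
      fit <- trainGCN(task, gcnCfg)
      pred <- predictGCN(task, fit)
      cls <- classificationMetrics(as.integer(labels)[testIdx],
                                   pred$labels[testIdx])
      rows[[length(rows) + 1L]] <-
        data.frame(seed = seed, fold = f,
                   ari = cm$ari, nmi = cm$nmi, ami = cm$ami,
                   acc = cls$acc, weighted_f1 = cls$weighted_f1,
                   precision = cls$precision)
    }
  }
  records <- do.call(rbind, rows)
  metrics <- c("ari", "nmi", "ami", "acc", "weighted_f1", "precision")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(records[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(records[[m]]), numeric(1)),
    min = vapply(metrics, function(m) min(records[[m]]), numeric(1)),
    max = vapply(metrics, function(m) max(records[[m]]), numeric(1)),
    row.names = NULL)
  list(records = records, summary = summary)
}

#' Format an experiment summary as a Markdown table
#'
#' Renders each metric as "mean (min-max)" in percent, the conventional
#' reporting format for integration and classification benchmarks.
#'
#' @param summary the `summary` data.frame from [runExperiment()]
#' @return a character vector of Markdown lines
#' @export
formatSummaryMarkdown <- function(summary) {
  fmt <- sprintf("%.2f (%.2f-%.2f)", 100 * summary$mean,
                 100 * summary$min, 100 * summary$max)
  c("| Metric | Mean (range), % |",
    "|---|---|",
    sprintf("| %s | %s |", summary$metric, fmt))
}
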