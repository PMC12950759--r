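# Modality-specific preprocessing: QC filtering, LogNormalize, VST-style
# highly variable gene selection, TF-IDF, top-feature selection, PCA/LSI,
# and feature scaling.

#' Default per-cell QC thresholds
#'
#' RNA cells are kept with 300-10,000 detected genes and < 5% mitochondrial
#' reads; ATAC cells with 2,000-20,000 fragments in peaks, < 5% blacklist
#' fraction, nucleosome signal < 4 and TSS enrichment > 3.
#'
#' @param rna_genes_min,rna_genes_max detected-gene bounds for RNA cells
#' @param rna_mito_max maximum mitochondrial fraction (0-1)
#' @param atac_frag_min,atac_frag_max fragments-in-peaks bounds for ATAC cells
#' @param atac_blacklist_max maximum blacklist-overlap fraction
#' @param atac_nucleosome_max maximum nucleosome signal
#' @param atac_tss_min minimum TSS enrichment score
#' @return a named list of thresholds
#' @export
qcThresholds <- function(rna_genes_min = 300, rna_genes_max = 10000,
                         rna_mito_max = 0.05,
                         atac_frag_min = 2000, atac_frag_max = 20000,
                         atac_blacklist_max = 0.05,
                         atac_nucleosome_max = 4, atac_tss_min = 3) {
  stopifnot(rna_genes_min < rna_genes_max, atac_frag_min < atac_frag_max)
  list(rna_genes_min = rna_genes_min, rna_genes_max = rna_genes_max,
       rna_mito_max = rna_mito_max,
       atac_frag_min = atac_frag_min, atac_frag_max = atac_frag_max,
       atac_blacklist_max = atac_blacklist_max,
       atac_nucleosome_max = atac_nucleosome_max,
       atac_tss_min = atac_tss_min)
}

#' Filter low-quality cells on per-cell QC metrics
#'
#' Applies the modality-relevant QC bounds and returns the matrix restricted
#' to passing cells, preserving cell order. For RNA, genes not expressed in
#' any retained cell are also dropped. QC metrics (TSS enrichment,
#' nucleosome signal, fragments in peaks, blacklist fraction) are consumed
#' as precomputed per-cell metadata.
#'
#' @param x an [OmicsMatrix-class] with `layer == "counts"`
#' @param qc data.frame with column `cell_id` plus, for RNA,
#'   `n_genes_detected` and `pct_mito`; for ATAC, `n_fragments_in_peaks`,
#'   `blacklist_fraction`, `nucleosome_signal`, `tss_enrichment`
#' @param thresholds a list from [qcThresholds()]
#' @return the filtered [OmicsMatrix-class]
#' @export
filterCells <- function(x, qc, thresholds = qcThresholds()) {
  stopifnot(is(x, "OmicsMatrix"))
  ids <- cellIds(x)
  miss <- setdiff(ids, qc$cell_id)
  if (length(miss))
    stop("missing QC record for cell(s): ", paste(utils::head(miss, 5), collapse = ", "))
  qc <- qc[match(ids, qc$cell_id), , drop = FALSE]
  badFrac <- function(f) any(f < 0 | f > 1, na.rm = TRUE)
  if (modality(x) == "rna") {
    if (badFrac(qc$pct_mito)) stop("pct_mito must lie in [0,1]")
    keep <- qc$n_genes_detected >= thresholds$rna_genes_min &
            qc$n_genes_detected <= thresholds$rna_genes_max &
            qc$pct_mito < thresholds$rna_mito_max
  } else {
    if (badFrac(qc$blacklist_fraction)) stop("blacklist_fraction must lie in [0,1]")
    keep <- qc$n_fragments_in_peaks >= thresholds$atac_frag_min &
            qc$n_fragments_in_peaks <= thresholds$atac_frag_max &
            qc$blacklist_fraction < thresholds$atac_blacklist_max &
            qc$nucleosome_signal < thresholds$atac_nucleosome_max &
            qc$tss_enrichment > thresholds$atac_tss_min
  }
  keep[is.na(keep)] <- FALSE
  v <- omicsValues(x)[keep, , drop = FALSE]
  if (modality(x) == "rna") {
    expressed <- Matrix::colSums(v) > 0
    v <- v[, expressed, drop = FALSE]
  }
  OmicsMatrix(v, modality = modality(x), layer = layerType(x))
}

#' LogNormalize an RNA count matrix
#'
#' Each entry becomes `log(1 + scaleFactor * x / cellTotal)`, the global
#' LogNormalize transform with the conventional scale factor of 10,000.
#'
#' @param x RNA [OmicsMatrix-class], `layer == "counts"`
#' @param scaleFactor positive scale factor (default 1e4)
#' @return normalized [OmicsMatrix-class]
#' @export
logNormalize <- function(x, scaleFactor = 1e4) {
  stopifnot(is(x, "OmicsMatrix"), modality(x) == "rna",
            layerType(x) == "counts", scaleFactor > 0)
  v <- asDense(omicsValues(x))
  tot <- rowSums(v)
  if (any(tot == 0))
    stop("cell(s) with zero total count (should have been QC-filtered): ",
         paste(utils::head(rownames(v)[tot == 0], 5), collapse = ", "))
  out <- log1p(scaleFactor * v / tot)
  OmicsMatrix(out, modality = "rna", layer = "normalized")
}

#' Select highly variable genes by variance-stabilised standardisation
#'
#' Fits a mean-variance trend on log10 scale (loess where enough genes are
#' available, quadratic polynomial otherwise), standardises each gene by the
#' trend-predicted standard deviation with values clipped at `sqrt(N)`, and
#' ranks genes by the variance of the standardised counts.
#'
#' @param x RNA [OmicsMatrix-class] with `layer == "counts"`
#' @param nFeatures number of genes to return
#' @param loessSpan span of the loess trend fit
#' @return integer vector of column indices of the selected genes, ordered by
#'   decreasing standardised variance
#' @export
selectVariableFeatures <- function(x, nFeatures = 2000, loessSpan = 0.3) {
  stopifnot(is(x, "OmicsMatrix"), layerType(x) == "counts")
  v <- asDense(omicsValues(x))
  n <- nrow(v)
  d <- ncol(v)
  if (nFeatures > d) stop("nFeatures exceeds number of genes (", d, ")")
  mu <- colMeans(v)
  va <- apply(v, 2L, stats::var)
  fitted_var <- rep(0, d)
  pos <- va > 0 & mu > 0
  if (sum(pos) >= 2) {
    lx <- log10(mu[pos]); ly <- log10(va[pos])
    fv <- tryCatch({
      if (sum(pos) >= 10) {
        fit <- stats::loess(ly ~ lx, span = loessSpan, degree = 2)
        stats::fitted(fit)
      } else stop("few genes")
    }, error = function(e) {
      deg <- min(2L, sum(pos) - 1L)
      fit <- stats::lm(ly ~ stats::poly(lx, deg))
      stats::fitted(fit)
    })
    fitted_var[pos] <- 10^fv
  }
  stdvar <- rep(0, d)
  clip <- sqrt(n)
  for (j in which(fitted_var > 0)) {
    z <- (v[, j] - mu[j]) / sqrt(fitted_var[j])
    z <- pmin(z, clip)
    stdvar[j] <- sum((z - mean(z))^2) / (n - 1)
  }
  order(stdvar, decreasing = TRUE)[seq_len(nFeatures)]
}

#' Select the most informative ATAC peaks by detection rate
#'
#' Ranks peaks by the number of cells in which they are detected and keeps
#' the top fraction (default top 25%).
#'
#' @param x ATAC [OmicsMatrix-class] with counts
#' @param fraction fraction of peaks to keep, in (0, 1]
#' @param minCells alternatively, keep peaks detected in at least this many
#'   cells (overrides `fraction` when not `NULL`)
#' @return integer vector of column indices of the retained peaks
#' @export
findTopFeatures <- function(x, fraction = 0.25, minCells = NULL) {
  stopifnot(is(x, "OmicsMatrix"))
  det <- Matrix::colSums(omicsValues(x) > 0)
  if (!is.null(minCells)) return(which(det >= minCells))
  stopifnot(fraction > 0, fraction <= 1)
  k <- max(1L, ceiling(fraction * length(det)))
  order(det, decreasing = TRUE)[seq_len(k)]
}

#' TF-IDF normalisation for ATAC peak counts
#'
#' Term frequency is the peak count divided by the cell total; inverse
#' document frequency is `N / nCellsWithPeak`. The default variant returns
#' `log(1 + TF * IDF * 1e4)`; `variant = "plain"` returns `TF * IDF`.
#'
#' @param x ATAC [OmicsMatrix-class], `layer == "counts"`
#' @param scaleFactor scale inside the log for the `"log"` variant
#' @param variant `"log"` (default) or `"plain"`
#' @return normalised [OmicsMatrix-class]
#' @export
tfidfNormalize <- function(x, scaleFactor = 1e4, variant = c("log", "plain")) {
  stopifnot(is(x, "OmicsMatrix"), modality(x) == "atac",
            layerType(x) == "counts")
  variant <- match.arg(variant)
  v <- asDense(omicsValues(x))
  tot <- rowSums(v)
  if (any(tot == 0))
    stop("cell(s) with zero total peak count: ",
         paste(utils::head(rownames(v)[tot == 0], 5), collapse = ", "))
  det <- colSums(v > 0)
  if (any(det == 0))
    stop("peak(s) detected in zero cells (pre-filter with findTopFeatures): ",
         paste(utils::head(colnames(v)[det == 0], 5), collapse = ", "))
  tf <- v / tot
  idf <- nrow(v) / det
  ti <- sweep(tf, 2L, idf, `*`)
  out <- if (variant == "log") log1p(ti * scaleFactor) else ti
  OmicsMatrix(out, modality = "atac", layer = "normalized")
}

#' Centre, scale and clip features
#'
#' Each feature is standardised to mean 0 and unit standard deviation
#' (constant features map to 0) and clipped to `[-clip, clip]` to limit the
#' influence of extreme values.
#'
#' @param x [OmicsMatrix-class] with `layer == "normalized"`
#' @param clip clipping bound (default 10)
#' @return scaled [OmicsMatrix-class]
#' @export
scaleFeatures <- function(x, clip = 10) {
  stopifnot(is(x, "OmicsMatrix"), clip > 0)
  v <- asDense(omicsValues(x))
  mu <- colMeans(v)
  sd <- apply(v, 2L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- Inf   # constant features -> 0 after centring
  out <- sweep(sweep(v, 2L, mu), 2L, sd, `/`)
  out[out > clip] <- clip
  out[out < -clip] <- -clip
  OmicsMatrix(out, modality = modality(x), layer = "scaled")
}

#' Linear dimensionality reduction (PCA or LSI)
#'
#' PCA centres features and takes the leading principal component scores;
#' LSI is truncated SVD without centring, dropping the first component by
#' default because it tracks sequencing depth. Component signs are fixed by
#' making the largest-magnitude loading positive.
#'
#' @param x [OmicsMatrix-class] with a normalized or scaled layer
#' @param nComponents number of components to return
#' @param method `"pca"` or `"lsi"`
#' @param dropFirst drop the first (depth-tracking) component; default `TRUE`
#'   for LSI, `FALSE` for PCA
#' @return a [LatentEmbedding-class]; feature loadings are attached as the
#'   `"loadings"` attribute, singular values as `"d"`
#' @export
reduceDimension <- function(x, nComponents, method = c("pca", "lsi"),
                            dropFirst = NULL) {
  stopifnot(is(x, "OmicsMatrix"))
  method <- match.arg(method)
  if (is.null(dropFirst)) dropFirst <- method == "lsi"
  v <- asDense(omicsValues(x))
  n <- nrow(v); d <- ncol(v)
  if (nComponents >= min(n, d))
    stop("nComponents must be < min(nCells, nFeatures) = ", min(n, d))
  need <- nComponents + as.integer(dropFirst)
  if (need > min(n, d))
    stop("nComponents + dropped components exceeds matrix rank bound")
  if (method == "pca") v <- sweep(v, 2L, colMeans(v))
  sv <- svd(v, nu = need, nv = need)
  idx <- seq.int(1L + as.integer(dropFirst), need)
  scores <- sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], length(idx))
  loadings <- sv$v[, idx, drop = FALSE]
  # deterministic sign: largest-magnitude loading per component is positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(v)
  colnames(scores) <- sprintf("%s_%d", toupper(method), seq_len(ncol(scores)))
  emb <- LatentEmbedding(scores, source = modality(x))
  attr(emb, "loadings") <- loadings
  attr(emb, "d") <- sv$d[idx]
  emb
}
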