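#' @import methods
#' @importFrom Matrix Matrix t rowSums colSums
#' @importClassesFrom Matrix sparseMatrix
NULL

setClassUnion("matrixOrSparse", c("matrix", "sparseMatrix"))

#' OmicsMatrix: a cells-by-features single-cell assay matrix
#'
#' Container for one modality of a paired single-cell experiment. Rows are
#' cells, columns are features (genes for RNA, accessibility peaks for ATAC).
#' The `layer` slot records where the matrix sits in the processing chain:
#' raw `counts`, `normalized` (LogNormalize or TF-IDF), or `scaled`
#' (centred/clipped z-scores).
#'
#' @slot values numeric matrix or sparse Matrix, cells x features
#' @slot modality `"rna"` or `"atac"`
#' @slot layer `"counts"`, `"normalized"` or `"scaled"`
#'
#' @examples
#' m <- OmicsMatrix(matrix(rpois(12, 2), 3, 4,
#'                         dimnames = list(paste0("c", 1:3), paste0("g", 1:4))),
#'                  modality = "rna")
#' modality(m)
#' @export
setClass("OmicsMatrix",
  representation(values = "matrixOrSparse",
                 modality = "character",
                 layer = "character"))

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!object@modality %in% c("rna", "atac"))
    msg <- c(msg, "modality must be 'rna' or 'atac'")
  if (!object@layer %in% c("counts", "normalized", "scaled"))
    msg <- c(msg, "layer must be one of 'counts', 'normalized', 'scaled'")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry cell ids (rownames) and feature ids (colnames)")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "cell ids must be unique")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "feature ids must be unique")
  }
  if (object@layer == "counts" && length(v) && min(v) < 0)
    msg <- c(msg, "counts layer must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values cells x features numeric matrix (dense or sparse). If it has
#'   no dimnames, synthetic cell/feature ids are created.
#' @param modality `"rna"` or `"atac"`
#' @param layer processing layer; default `"counts"`
#' @return an [OmicsMatrix-class] object
#' @export
OmicsMatrix <- function(values, modality, layer = "counts") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("cell%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("feat%d", seq_len(ncol(values)))
  new("OmicsMatrix", values = values, modality = modality, layer = layer)
}

#' @describeIn OmicsMatrix-class display a short summary
#' @param object an OmicsMatrix
#' @export
setMethod("show", "OmicsMatrix", function(object) {
  v <- object@values
  nz <- if (inherits(v, "sparseMatrix")) Matrix::nnzero(v) else sum(v != 0)
  cat(sprintf("OmicsMatrix [%s/%s]: %d cells x %d features (%.1f%% nonzero)\n",
              object@modality, object@layer, nrow(v), ncol(v),
              100 * nz / max(1, length(v))))
})

#' @rdname omics-accessors
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))
#' @rdname omics-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname omics-accessors
#' @export
setGeneric("layerType", function(x) standardGeneric("layerType"))
#' @rdname omics-accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname omics-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' Accessors for OmicsMatrix and LatentEmbedding
#'
#' `omicsValues()` returns the underlying matrix, `modality()` the assay
#' modality, `layerType()` the processing layer, `cellIds()`/`featureIds()`
#' the row/column identifiers.
#'
#' @param x an `OmicsMatrix` or `LatentEmbedding`
#' @name omics-accessors
NULL

#' @rdname omics-accessors
#' @export
setMethod("omicsValues", "OmicsMatrix", function(x) x@values)
#' @rdname omics-accessors
#' @export
setMethod("modality", "OmicsMatrix", function(x) x@modality)
#' @rdname omics-accessors
#' @export
setMethod("layerType", "OmicsMatrix", function(x) x@layer)
#' @rdname omics-accessors
#' @export
setMethod("cellIds", "OmicsMatrix", function(x) rownames(x@values))
#' @rdname omics-accessors
#' @export
setMethod("featureIds", "OmicsMatrix", function(x) colnames(x@values))

#' LatentEmbedding: per-cell latent vectors
#'
#' N x d matrix of cell embeddings with a tag recording which stage produced
#' it (`rna`/`atac` encoder or linear reduction, `fused` cross-attention
#' output, or a raw attention `head`).
#'
#' @slot values numeric matrix, cells x dimensions
#' @slot source one of `"rna"`, `"atac"`, `"fused"`, `"head"`
#' @export
setClass("LatentEmbedding",
  representation(values = "matrix", source = "character"))

setValidity("LatentEmbedding", function(object) {
  msg <- character()
  if (!object@source %in% c("rna", "atac", "fused", "head"))
    msg <- c(msg, "source must be one of 'rna','atac','fused','head'")
  if (length(object@values) && !all(is.finite(object@values)))
    msg <- c(msg, "embedding values must be finite")
  if (is.null(rownames(object@values)))
    msg <- c(msg, "embedding must carry cell ids as rownames")
  if (length(msg)) msg else TRUE
})

#' Construct a LatentEmbedding
#' @param values cells x dims numeric matrix
#' @param source provenance tag (`"rna"`, `"atac"`, `"fused"`, `"head"`)
#' @return a [LatentEmbedding-class]
#' @export
LatentEmbedding <- function(values, source) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("cell%d", seq_len(nrow(values)))
  new("LatentEmbedding", values = values, source = source)
}

#' @describeIn LatentEmbedding-class display a short summary
#' @param object a LatentEmbedding
#' @export
setMethod("show", "LatentEmbedding", function(object) {
  cat(sprintf("LatentEmbedding [%s]: %d cells x %d dims\n",
              object@source, nrow(object@values), ncol(object@values)))
})

#' @rdname omics-accessors
#' @export
setMethod("omicsValues", "LatentEmbedding", function(x) x@values)
#' @rdname omics-accessors
#' @export
setMethod("cellIds", "LatentEmbedding", function(x) rownames(x@values))

#' @rdname omics-accessors
#' @export
setGeneric("embeddingSource", function(x) standardGeneric("embeddingSource"))
#' @rdname omics-accessors
#' @export
setMethod("embeddingSource", "LatentEmbedding", function(x) x@source)

#' SimilarityBundle: per-modality and fused cell similarity kernels
#'
#' Holds, for each modality, the affinity matrix W, the row-stochastic full
#' kernel P (diagonal 1/2), the sparse kNN kernel S, and the cross-diffused
#' fused similarity matrix used as the GCN adjacency.
#'
#' @slot W list of N x N affinity matrices
#' @slot P list of N x N full kernels
#' @slot S list of N x N sparse kNN kernels
#' @slot fused N x N fused similarity matrix
#' @export
setClass("SimilarityBundle",
  representation(W = "list", P = "list", S = "list", fused = "matrix"))

setValidity("SimilarityBundle", function(object) {
  msg <- character()
  for (W in object@W) {
    if (min(W) < 0) msg <- c(msg, "affinity matrices must be nonnegative")
    if (max(abs(W - t(W))) > 1e-8) msg <- c(msg, "affinity matrices must be symmetric")
  }
  for (P in object@P)
    if (max(abs(Matrix::rowSums(P) - 1)) > 1e-10)
      msg <- c(msg, "full-kernel rows must sum to 1")
  for (S in object@S)
    if (max(abs(Matrix::rowSums(S) - 1)) > 1e-10)
      msg <- c(msg, "kNN-kernel rows must sum to 1")
  if (length(object@fused) &&
      max(abs(object@fused - t(object@fused))) > 1e-8)
    msg <- c(msg, "fused matrix must be symmetric")
  if (length(msg)) unique(msg) else TRUE
})

#' @describeIn SimilarityBundle-class display a short summary
#' @param object a SimilarityBundle
#' @export
setMethod("show", "SimilarityBundle", function(object) {
  n <- if (length(object@W)) nrow(object@W[[1]]) else nrow(object@fused)
  cat(sprintf("SimilarityBundle: %d modalities, %d cells, fused: %s\n",
              length(object@W), n,
              if (length(object@fused)) "yes" else "no"))
})

#' @rdname similarity-accessors
#' @export
setGeneric("fusedSimilarity", function(x) standardGeneric("fusedSimilarity"))
#' Accessors for SimilarityBundle
#' @param x a `SimilarityBundle`
#' @name similarity-accessors
#' @export
setMethod("fusedSimilarity", "SimilarityBundle", function(x) x@fused)

#' GraphTask: a transductive node-classification problem
#'
#' Bundles the fused-similarity adjacency, node features (fused embedding),
#' integer labels (`NA` where unknown), and disjoint train/test masks.
#' Test-mask labels are carried for evaluation only; training code never
#' reads them.
#'
#' @slot adjacency N x N symmetric nonnegative matrix
#' @slot features N x d node feature matrix
#' @slot labels integer vector length N; NA = unknown
#' @slot trainMask,testMask disjoint logical vectors length N
#' @slot nClasses number of classes
#' @export
setClass("GraphTask",
  representation(adjacency = "matrix", features = "matrix",
                 labels = "integer", trainMask = "logical",
                 testMask = "logical", nClasses = "integer"))

setValidity("GraphTask", function(object) {
  msg <- character()
  n <- nrow(object@adjacency)
  if (ncol(object@adjacency) != n) msg <- c(msg, "adjacency must be square")
  if (nrow(object@features) != n) msg <- c(msg, "features rows must match adjacency")
  if (length(object@labels) != n || length(object@trainMask) != n ||
      length(object@testMask) != n)
    msg <- c(msg, "labels and masks must have one entry per node")
  if (any(object@trainMask & object@testMask))
    msg <- c(msg, "train and test masks must be disjoint")
  if (any(object@trainMask & is.na(object@labels)))
    msg <- c(msg, "every train-mask node needs a label")
  if (n && min(object@adjacency) < 0) msg <- c(msg, "adjacency must be nonnegative")
  if (n && max(abs(object@adjacency - t(object@adjacency))) > 1e-8)
    msg <- c(msg, "adjacency must be symmetric")
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && (min(lab) < 1L || max(lab) > object@nClasses))
    msg <- c(msg, "labels must lie in 1..nClasses")
  if (length(msg)) msg else TRUE
})

#' Construct a GraphTask
#'
#' @param adjacency symmetric nonnegative N x N matrix
#' @param features N x d node feature matrix
#' @param labels integer labels in 1..nClasses, NA where unknown
#' @param trainMask,testMask disjoint logical masks
#' @param nClasses number of classes (default `max(labels)`)
#' @return a [GraphTask-class]
#' @export
GraphTask <- function(adjacency, features, labels, trainMask, testMask,
                      nClasses = max(labels, na.rm = TRUE)) {
  new("GraphTask", adjacency = as.matrix(adjacency),
      features = as.matrix(features), labels = as.integer(labels),
      trainMask = as.logical(trainMask), testMask = as.logical(testMask),
      nClasses = as.integer(nClasses))
}

#' @describeIn GraphTask-class display a short summary
#' @param object a GraphTask
#' @export
setMethod("show", "GraphTask", function(object) {
  cat(sprintf("GraphTask: %d nodes, %d classes, %d train / %d test\n",
              nrow(object@adjacency), object@nClasses,
              sum(object@trainMask), sum(object@testMask)))
})
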