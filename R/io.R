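# Readers and writers: 10x-style MatrixMarket triplets (matrix.mtx +
# barcodes.tsv + features.tsv, features x cells on disk) and dense CSV
# (cells x features, header row = feature ids, first column = cell ids).

#' Read a 10x-style MTX triplet
#'
#' Expects `matrix.mtx` (or `.mtx.gz`), `barcodes.tsv` and `features.tsv`
#' in `dir`; the on-disk matrix is features x cells and is transposed to
#' the cells x features convention.
#'
#' @param dir directory containing the triplet
#' @param modality `"rna"` or `"atac"`
#' @return a counts-layer [OmicsMatrix-class]
#' @export
readTenxMatrix <- function(dir, modality) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) mtx <- paste0(mtx, ".gz")
  if (!file.exists(mtx)) stop("no matrix.mtx[.gz] in ", dir)
  m <- Matrix::readMM(mtx)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(features) || ncol(m) != length(barcodes))
    stop("matrix dimensions do not match features/barcodes")
  v <- Matrix::t(m)
  dimnames(v) <- list(barcodes, features)
  OmicsMatrix(methods::as(v, "CsparseMatrix"), modality = modality)
}

#' Write an OmicsMatrix as a 10x-style MTX triplet
#'
#' @param x an [OmicsMatrix-class]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
writeTenxMatrix <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- omicsValues(x)
  sp <- methods::as(Matrix::t(Matrix::Matrix(v, sparse = TRUE)), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(cellIds(x), file.path(dir, "barcodes.tsv"))
  writeLines(featureIds(x), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Write a full synthetic dataset to disk
#'
#' One MTX triplet per modality (`rna/`, `atac/`) plus `labels.tsv` and
#' `donors.tsv` (cell_id, value).
#'
#' @param dataset a [generatePaired()] result
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
writeTenxDataset <- function(dataset, dir) {
  writeTenxMatrix(dataset$rna, file.path(dir, "rna"))
  writeTenxMatrix(dataset$atac, file.path(dir, "atac"))
  ids <- cellIds(dataset$rna)
  utils::write.table(data.frame(cell_id = ids, label = dataset$labels),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell_id = ids, donor = dataset$donors),
                     file.path(dir, "donors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a dense CSV matrix (cells x features)
#'
#' @param path CSV path; header row holds feature ids, first column cell ids
#' @param modality `"rna"` or `"atac"`
#' @param layer processing layer tag (default `"counts"`)
#' @return an [OmicsMatrix-class]
#' @export
readOmicsCSV <- function(path, modality, layer = "counts") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  OmicsMatrix(as.matrix(df), modality = modality, layer = layer)
}

#' Write an OmicsMatrix or LatentEmbedding as dense CSV
#'
#' @param x an [OmicsMatrix-class] or [LatentEmbedding-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeOmicsCSV <- function(x, path) {
  utils::write.csv(asDense(extractMatrix(x)), path, quote = FALSE)
  invisible(path)
}

#' Write a per-cell QC report as TSV
#'
#' Evaluates the modality-relevant thresholds for each cell and writes the
#' metrics together with a `pass` column.
#'
#' @param qc per-cell QC data.frame (see [filterCells()])
#' @param modality `"rna"` or `"atac"`; selects which bounds apply
#' @param path output TSV path
#' @param thresholds a list from [qcThresholds()]
#' @return the report data.frame, invisibly
#' @export
writeQCReport <- function(qc, modality, path, thresholds = qcThresholds()) {
  if (modality == "rna") {
    pass <- qc$n_genes_detected >= thresholds$rna_genes_min &
      qc$n_genes_detected <= thresholds$rna_genes_max &
      qc$pct_mito < thresholds$rna_mito_max
  } else {
    pass <- qc$n_fragments_in_peaks >= thresholds$atac_frag_min &
      qc$n_fragments_in_peaks <= thresholds$atac_frag_max &
      qc$blacklist_fraction < thresholds$atac_blacklist_max &
      qc$nucleosome_signal < thresholds$atac_nucleosome_max &
      qc$tss_enrichment > thresholds$atac_tss_min
  }
  report <- cbind(qc, pass = ifelse(is.na(pass), FALSE, pass))
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}

#' Save / load trained parameters
#'
#' Checkpoints are plain RDS files holding the nested parameter lists of
#' the autoencoders, fusion module or GCN.
#'
#' @param params any parameter list (e.g. `trainDualAE()$params`)
#' @param path checkpoint path
#' @return `path` invisibly; `readCheckpoint()` returns the parameter list
#' @export
writeCheckpoint <- function(params, path) {
  saveRDS(params, path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) readRDS(path)
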