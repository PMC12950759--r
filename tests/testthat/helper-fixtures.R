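# Shared small fixtures, built in code at load time.

# tiny paired dataset with clear structure, cached per session
tinyPaired <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generatePaired(syntheticSpec(
        nCells = 120, nTypes = 3, nGenes = 200, nPeaks = 400,
        nDonors = 4, seed = 42))
    cache
  }
})

# well-separated 2-D gaussian blobs
makeBlobs <- function(n, k, d = 2, sep = 8, seed = 1) {
  set.seed(seed)
  labels <- rep(seq_len(k), length.out = n)
  centers <- matrix(stats::rnorm(k * d), k, d) * sep
  X <- centers[labels, , drop = FALSE] + matrix(stats::rnorm(n * d), n, d)
  rownames(X) <- sprintf("c%03d", seq_len(n))
  list(X = X, labels = labels)
}

# QC table where every cell passes the default thresholds
passingQC <- function(ids) {
  data.frame(cell_id = ids, n_genes_detected = 1000, pct_mito = 0.01,
             n_fragments_in_peaks = 5000, blacklist_fraction = 0.01,
             nucleosome_signal = 1, tss_enrichment = 5)
}

randomCounts <- function(n, d, modality = "rna", seed = 1, lambda = 3) {
  set.seed(seed)
  m <- matrix(stats::rpois(n * d, lambda), n, d,
              dimnames = list(sprintf("c%d", seq_len(n)),
                              sprintf("f%d", seq_len(d))))
  OmicsMatrix(m, modality = modality)
}
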