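# Synthetic paired scRNA/scATAC generator with planted cell types, donor
# structure and tunable separability. RNA counts are negative binomial with
# type-specific marker programs; ATAC peaks are Bernoulli-thinned small
# counts with type-linked open probabilities, emulating the high sparsity
# and near-binary nature of chromatin accessibility profiles.

#' SyntheticSpec: parameters of the paired-omics generator
#'
#' @slot nCells,nTypes,nGenes,nPeaks,nDonors problem dimensions
#' @slot rnaDispersion negative-binomial dispersion (size = 1/dispersion)
#' @slot peakOpenProbOn,peakOpenProbOff open probability of a marker peak in
#'   its own type (at full signal) and elsewhere
#' @slot typeSignalStrength s >= 0; scales the RNA marker log-fold-change
#'   and ramps the ATAC marker open probability (`min(s, 1)` of the way from
#'   off to on), so s = 0 removes class signal from both modalities
#' @slot modalityNoiseRna,modalityNoiseAtac per-entry log-normal (RNA) and
#'   logit-normal (ATAC) noise standard deviations
#' @slot crossModalCoupling fraction of marker peaks whose accessibility is
#'   tied to the expression of a same-type marker gene
#' @slot donorEffect log-sd of per-donor multiplicative factors
#' @slot seed RNG seed; all draws are reproducible from it
#' @export
setClass("SyntheticSpec",
  representation(nCells = "integer", nTypes = "integer", nGenes = "integer",
                 nPeaks = "integer", nDonors = "integer",
                 rnaDispersion = "numeric", peakOpenProbOn = "numeric",
                 peakOpenProbOff = "numeric", typeSignalStrength = "numeric",
                 modalityNoiseRna = "numeric", modalityNoiseAtac = "numeric",
                 crossModalCoupling = "numeric", donorEffect = "numeric",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nTypes > object@nCells) msg <- c(msg, "nTypes must be <= nCells")
  probs <- c(object@peakOpenProbOn, object@peakOpenProbOff,
             object@crossModalCoupling)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must lie in [0,1]")
  if (object@rnaDispersion <= 0) msg <- c(msg, "rnaDispersion must be > 0")
  if (object@typeSignalStrength < 0) msg <- c(msg, "typeSignalStrength must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticSpec
#'
#' Defaults define the benchmark condition: 1000 cells, 5 types, 2000
#' genes, 5000 peaks, 4 donors, full marker signal.
#'
#' @param nCells,nTypes,nGenes,nPeaks,nDonors problem dimensions
#' @param rnaDispersion NB dispersion (default 0.5)
#' @param peakOpenProbOn,peakOpenProbOff marker-peak open probabilities
#'   (defaults 0.4 / 0.02)
#' @param typeSignalStrength planted signal strength s (default 1)
#' @param modalityNoiseRna,modalityNoiseAtac modality-specific noise sds
#'   (defaults 0.3 / 0.5)
#' @param crossModalCoupling fraction of marker peaks tied to marker genes
#'   (default 0.5)
#' @param donorEffect per-donor factor log-sd (default 0.3)
#' @param seed RNG seed
#' @return a [SyntheticSpec-class]
#' @export
syntheticSpec <- function(nCells = 1000, nTypes = 5, nGenes = 2000,
                          nPeaks = 5000, nDonors = 4, rnaDispersion = 0.5,
                          peakOpenProbOn = 0.4, peakOpenProbOff = 0.02,
                          typeSignalStrength = 1, modalityNoiseRna = 0.3,
                          modalityNoiseAtac = 0.5, crossModalCoupling = 0.5,
                          donorEffect = 0.3, seed = 0) {
  new("SyntheticSpec", nCells = as.integer(nCells), nTypes = as.integer(nTypes),
      nGenes = as.integer(nGenes), nPeaks = as.integer(nPeaks),
      nDonors = as.integer(nDonors), rnaDispersion = rnaDispersion,
      peakOpenProbOn = peakOpenProbOn, peakOpenProbOff = peakOpenProbOff,
      typeSignalStrength = typeSignalStrength,
      modalityNoiseRna = modalityNoiseRna,
      modalityNoiseAtac = modalityNoiseAtac,
      crossModalCoupling = crossModalCoupling, donorEffect = donorEffect,
      seed = as.integer(seed))
}

#' @describeIn SyntheticSpec-class display a short summary
#' @param object a SyntheticSpec
#' @export
setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d cells, %d types, %d genes, %d peaks, ",
                     "%d donors, signal %.2f, seed %d\n"),
              object@nCells, object@nTypes, object@nGenes, object@nPeaks,
              object@nDonors, object@typeSignalStrength, object@seed))
})

markersPerType <- function(nFeatures, nTypes, floorCount) {
  m <- max(floorCount, round(0.02 * nFeatures))
  if (nTypes * m > nFeatures)
    stop("infeasible marker allocation: ", nTypes, " types x ", m,
         " markers > ", nFeatures, " features")
  m
}

#' Generate a paired synthetic scRNA/scATAC dataset
#'
#' Cell types are assigned near-balanced, donors at random. RNA counts are
#' negative binomial around log-normal baseline means, with marker genes
#' up-regulated `exp(s * effect)`-fold in their own type, cell size
#' factors, per-donor factors and per-entry log-normal noise. ATAC counts
#' are Bernoulli-opened peaks (times a small Poisson amplitude) whose
#' marker open probability ramps from `peakOpenProbOff` to `peakOpenProbOn`
#' with the signal; a `crossModalCoupling` fraction of marker peaks open
#' only when their linked same-type marker gene is expressed in that cell.
#' Fully reproducible from the spec seed.
#'
#' @param spec a [syntheticSpec()]
#' @return list with `rna` and `atac` count [OmicsMatrix-class]s, `labels`
#'   (factor), `donors` (factor), the `spec`, and `truth` (marker indices
#'   and the expected type-by-gene RNA mean matrix)
#' @export
generatePaired <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  n <- spec@nCells; k <- spec@nTypes
  g <- spec@nGenes; p <- spec@nPeaks
  s <- spec@typeSignalStrength
  withSeed(spec@seed, {
    labels <- sample(rep_len(seq_len(k), n))
    donors <- sample(rep_len(seq_len(spec@nDonors), n))

    mGene <- markersPerType(g, k, 5L)
    mPeak <- markersPerType(p, k, 10L)
    markerGenes <- lapply(seq_len(k), function(t) ((t - 1) * mGene + 1):(t * mGene))
    markerPeaks <- lapply(seq_len(k), function(t) ((t - 1) * mPeak + 1):(t * mPeak))

    # --- RNA ---------------------------------------------------------------
    baseMean <- exp(stats::rnorm(g, log(1), 1))
    effect <- stats::runif(g, 1, 2)
    typeLogFC <- matrix(0, k, g)
    for (t in seq_len(k)) typeLogFC[t, markerGenes[[t]]] <- s * effect[markerGenes[[t]]]
    sizeFac <- exp(stats::rnorm(n, 0, 0.3))
    donorFacRna <- matrix(exp(stats::rnorm(spec@nDonors * g, 0, spec@donorEffect)),
                          spec@nDonors, g)
    mu <- sweep(exp(typeLogFC[labels, , drop = FALSE]), 2L, baseMean, `*`)
    mu <- mu * donorFacRna[donors, , drop = FALSE] * sizeFac
    if (spec@modalityNoiseRna > 0)
      mu <- mu * exp(matrix(stats::rnorm(n * g, 0, spec@modalityNoiseRna), n, g))
    rnaCounts <- matrix(stats::rnbinom(n * g, size = 1 / spec@rnaDispersion,
                                       mu = mu), n, g)
    dimnames(rnaCounts) <- list(sprintf("cell%04d", seq_len(n)),
                                sprintf("gene%04d", seq_len(g)))

    # --- ATAC --------------------------------------------------------------
    ramp <- min(s, 1)
    pOn <- spec@peakOpenProbOff + (spec@peakOpenProbOn - spec@peakOpenProbOff) * ramp
    prob <- matrix(spec@peakOpenProbOff, n, p)
    for (t in seq_len(k))
      prob[labels == t, markerPeaks[[t]]] <- pOn
    # cross-modal coupling: tie some marker peaks to a same-type marker gene
    nCoup <- floor(spec@crossModalCoupling * mPeak)
    if (nCoup > 0) {
      for (t in seq_len(k)) {
        own <- labels == t
        pk <- markerPeaks[[t]][seq_len(nCoup)]
        gn <- markerGenes[[t]][((seq_len(nCoup) - 1) %% mGene) + 1]
        expressed <- rnaCounts[own, gn, drop = FALSE] > 0
        sub <- prob[own, pk, drop = FALSE]
        sub[!expressed] <- spec@peakOpenProbOff
        prob[own, pk] <- sub
      }
    }
    donorShift <- matrix(stats::rnorm(spec@nDonors * p, 0, spec@donorEffect),
                         spec@nDonors, p)
    lo <- stats::qlogis(pmin(pmax(prob, 1e-6), 1 - 1e-6)) +
      donorShift[donors, , drop = FALSE]
    if (spec@modalityNoiseAtac > 0)
      lo <- lo + matrix(stats::rnorm(n * p, 0, spec@modalityNoiseAtac), n, p)
    open <- matrix(stats::rbinom(n * p, 1L, stats::plogis(lo)), n, p)
    amp <- matrix(1L + stats::rpois(n * p, 0.5), n, p)
    atacCounts <- open * amp
    dimnames(atacCounts) <- list(rownames(rnaCounts),
                                 sprintf("peak%05d", seq_len(p)))

    expectedRnaMean <- sweep(exp(typeLogFC), 2L, baseMean, `*`)
    list(rna = OmicsMatrix(rnaCounts, modality = "rna"),
         atac = OmicsMatrix(Matrix::Matrix(atacCounts, sparse = TRUE),
                            modality = "atac"),
         labels = factor(labels), donors = factor(donors), spec = spec,
         truth = list(markerGenes = markerGenes, markerPeaks = markerPeaks,
                      expectedRnaMean = expectedRnaMean))
  })
}

#' Generate a ladder of datasets varying only the signal strength
#'
#' All levels share the base spec's seed, so labels, donors and every other
#' draw are identical across levels; only `typeSignalStrength` differs.
#'
#' @param base a [syntheticSpec()]
#' @param levels numeric vector (length >= 2) of signal strengths
#' @return named list of [generatePaired()] results, one per level
#' @export
separabilityLadder <- function(base, levels) {
  stopifnot(is(base, "SyntheticSpec"), length(levels) >= 2)
  out <- lapply(levels, function(s) {
    sp <- base
    sp@typeSignalStrength <- s
    generatePaired(sp)
  })
  names(out) <- sprintf("signal_%g", levels)
  out
}
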