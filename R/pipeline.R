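# Pipeline orchestration: a nested YAML-serialisable configuration, a
# single-call runner executing preprocess -> AE -> cross-attention fusion ->
# SNF -> GCN -> metrics, and a hyperparameter sweep driver.

#' Default pipeline configuration
#'
#' Nested sections `synth` / `input` / `preprocess` / `ae` / `fusion` /
#' `snf` / `gcn` / `eval` plus a global `seed`, `outdir` and `log_level`.
#' Unknown keys are rejected at validation; the config round-trips through
#' YAML unchanged.
#'
#' @return nested configuration list
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 0L,
    outdir = "sccrossfuse_out",
    log_level = "info",
    synth = list(enabled = TRUE, n_cells = 1000L, n_types = 5L,
                 n_genes = 2000L, n_peaks = 5000L, n_donors = 4L,
                 rna_dispersion = 0.5, peak_open_prob_on = 0.4,
                 peak_open_prob_off = 0.02, type_signal_strength = 1,
                 modality_noise_rna = 0.3, modality_noise_atac = 0.5,
                 cross_modal_coupling = 0.5, donor_effect = 0.3),
    input = list(rna_dir = "", atac_dir = "", labels_tsv = "",
                 donors_tsv = ""),
    preprocess = list(n_hvg = 2000L, top_peak_fraction = 0.25,
                      n_pcs = 50L, n_lsi = 50L, tfidf_variant = "log"),
    ae = list(hidden_dim = 512L, latent_dim = 128L, epochs = 100L,
              lr = 0.001, alpha = 0.5, beta = 0.5),
    fusion = list(method = "mhca", heads = 4L, temperature = 0.5,
                  lambda_contrastive = 1, epochs = 50L, lr = 0.001,
                  ffn_hidden = 256L, finetune_encoders = FALSE),
    snf = list(k = 9L, mu = 0.5, iterations = 20L),
    gcn = list(hidden_dim = 64L, dropout = 0.5, lr = 0.001,
               weight_decay = 0.01, epochs = 150L),
    eval = list(scheme = "stratified_kfold", n_folds = 5L, n_seeds = 1L,
                kmeans_restarts = 10L, cluster_on = "all"))
}

validateConfig <- function(config, template = defaultPipelineConfig(),
                           path = "") {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(config[[nm]]))
      validateConfig(config[[nm]], template[[nm]], paste0(path, nm, "."))
  }
  invisible(TRUE)
}

# Merge user config over defaults (recursively).
mergeConfig <- function(user, template) {
  for (nm in names(user)) {
    if (is.list(template[[nm]]) && is.list(user[[nm]]))
      template[[nm]] <- mergeConfig(user[[nm]], template[[nm]])
    else template[[nm]] <- user[[nm]]
  }
  template
}

#' Read and validate a pipeline configuration from YAML
#'
#' Keys omitted from the file take their defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file path
#' @return validated full configuration list
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  validateConfig(user)
  mergeConfig(user, defaultPipelineConfig())
}

pipeLog <- function(config, stage, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, paste0(...)))
}

configToExperiment <- function(config) {
  experimentConfig(
    nHvg = config$preprocess$n_hvg,
    topPeakFraction = config$preprocess$top_peak_fraction,
    nPcs = config$preprocess$n_pcs, nLsi = config$preprocess$n_lsi,
    aeEpochs = config$ae$epochs, fusionEpochs = config$fusion$epochs,
    gcnEpochs = config$gcn$epochs, fusionMethod = config$fusion$method,
    nHeads = config$fusion$heads, latentDim = config$ae$latent_dim,
    hiddenDim = config$ae$hidden_dim,
    temperature = config$fusion$temperature,
    lambda = config$fusion$lambda_contrastive,
    snfK = config$snf$k, snfMu = config$snf$mu,
    snfIterations = config$snf$iterations,
    gcnHidden = config$gcn$hidden_dim, gcnDropout = config$gcn$dropout,
    gcnLr = config$gcn$lr, gcnWeightDecay = config$gcn$weight_decay,
    clusterOn = config$eval$cluster_on)
}

loadPipelineInputs <- function(config) {
  if (isTRUE(config$synth$enabled)) {
    sy <- config$synth
    spec <- syntheticSpec(
      nCells = sy$n_cells, nTypes = sy$n_types, nGenes = sy$n_genes,
      nPeaks = sy$n_peaks, nDonors = sy$n_donors,
      rnaDispersion = sy$rna_dispersion,
      peakOpenProbOn = sy$peak_open_prob_on,
      peakOpenProbOff = sy$peak_open_prob_off,
      typeSignalStrength = sy$type_signal_strength,
      modalityNoiseRna = sy$modality_noise_rna,
      modalityNoiseAtac = sy$modality_noise_atac,
      crossModalCoupling = sy$cross_modal_coupling,
      donorEffect = sy$donor_effect, seed = config$seed)
    generatePaired(spec)
  } else {
    inp <- config$input
    unset <- function(x) is.null(x) || !nzchar(x)
    if (unset(inp$rna_dir) || unset(inp$atac_dir))
      stop("input.rna_dir and input.atac_dir are required when synth is disabled")
    rna <- readTenxMatrix(inp$rna_dir, "rna")
    atac <- readTenxMatrix(inp$atac_dir, "atac")
    labels <- donors <- NULL
    if (!unset(inp$labels_tsv)) {
      lab <- utils::read.table(inp$labels_tsv, header = TRUE, sep = "\t")
      labels <- factor(lab[[2]][match(cellIds(rna), lab[[1]])])
    }
    if (!unset(inp$donors_tsv)) {
      don <- utils::read.table(inp$donors_tsv, header = TRUE, sep = "\t")
      donors <- factor(don[[2]][match(cellIds(rna), don[[1]])])
    }
    list(rna = rna, atac = atac, labels = labels, donors = donors)
  }
}

#' Run the full pipeline from a configuration
#'
#' Executes preprocess, autoencoder, cross-attention/contrastive fusion,
#' similarity network fusion, GCN classification and metric evaluation in
#' order across the configured CV folds and seeds. Writes `metrics.csv`
#' (one row per seed x fold), `summary.csv`, and `manifest.yaml` (config
#' hash, seed, versions) to the output directory. Rerunning with an
#' unchanged config and `resume = TRUE` returns the cached results.
#'
#' @param config a configuration list ([defaultPipelineConfig()] shape) or
#'   a YAML path
#' @param resume skip recomputation when a matching manifest and metrics
#'   file already exist (default `FALSE`)
#' @return (invisibly) list with `records`, `summary` and output `paths`
#' @export
runPipeline <- function(config = defaultPipelineConfig(), resume = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validateConfig(config)
  config <- mergeConfig(config, defaultPipelineConfig())
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- fnv1a(paste(deparse(config), collapse = "\n"))
  paths <- list(metrics = file.path(config$outdir, "metrics.csv"),
                summary = file.path(config$outdir, "summary.csv"),
                manifest = file.path(config$outdir, "manifest.yaml"))
  if (resume && file.exists(paths$manifest) && file.exists(paths$metrics)) {
    man <- yaml::read_yaml(paths$manifest)
    if (identical(man$config_hash, hash)) {
      pipeLog(config, "resume", "config unchanged; returning cached metrics")
      return(invisible(list(
        records = utils::read.csv(paths$metrics),
        summary = utils::read.csv(paths$summary), paths = paths)))
    }
  }
  pipeLog(config, "input", "loading inputs")
  data <- loadPipelineInputs(config)
  if (is.null(data$labels))
    stop("pipeline evaluation requires cell-type labels")
  seeds <- config$seed + seq_len(config$eval$n_seeds) - 1L
  plan <- makeCVPlan(data$labels, data$donors,
                     scheme = config$eval$scheme,
                     nFolds = config$eval$n_folds, seed = config$seed)
  pipeLog(config, "run", sprintf("%d seeds x %d folds, fusion=%s",
                                 length(seeds), plan$nFolds,
                                 config$fusion$method))
  res <- runExperiment(data$rna, data$atac, data$labels, data$donors,
                       config = configToExperiment(config),
                       plan = plan, seeds = seeds)
  utils::write.csv(res$records, paths$metrics, row.names = FALSE)
  utils::write.csv(res$summary, paths$summary, row.names = FALSE)
  yaml::write_yaml(list(config_hash = hash, seed = config$seed,
                        package_version = as.character(
                          utils::packageVersion("scCrossFuse")),
                        r_version = R.version.string,
                        timestamp = format(Sys.time())),
                   paths$manifest)
  pipeLog(config, "done", "metrics written to ", paths$metrics)
  invisible(list(records = res$records, summary = res$summary, paths = paths))
}

#' Sweep one hyperparameter across values
#'
#' Runs the pipeline once per value of `parameter` (attention heads or SNF
#' neighbourhood size K), holding everything else fixed. A value that fails
#' (for example a head count that does not divide the latent dimension) is
#' recorded as an error row and the sweep continues.
#'
#' @param config base configuration list or YAML path
#' @param parameter `"heads"` or `"snf_k"`
#' @param values numeric vector of values to sweep
#' @return data.frame with one row per value: the value, mean metrics (or
#'   `NA`) and an `error` column
#' @export
sweepParameter <- function(config, parameter = c("heads", "snf_k"), values) {
  parameter <- match.arg(parameter)
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- mergeConfig(config, defaultPipelineConfig())
  base_out <- config$outdir
  rows <- lapply(values, function(v) {
    cfg <- config
    if (parameter == "heads") cfg$fusion$heads <- as.integer(v)
    else cfg$snf$k <- as.integer(v)
    cfg$outdir <- file.path(base_out, sprintf("%s_%g", parameter, v))
    res <- tryCatch(runPipeline(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(value = v, ari = NA_real_, nmi = NA_real_, ami = NA_real_,
                 acc = NA_real_, weighted_f1 = NA_real_,
                 precision = NA_real_, error = conditionMessage(res))
    } else {
      s <- res$summary
      m <- stats::setNames(s$mean, s$metric)
      data.frame(value = v, ari = m[["ari"]], nmi = m[["nmi"]],
                 ami = m[["ami"]], acc = m[["acc"]],
                 weighted_f1 = m[["weighted_f1"]],
                 precision = m[["precision"]], error = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(base_out, sprintf("sweep_%s.csv", parameter)),
                   row.names = FALSE)
  out
}
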