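# scCrossFuse

Cell-type discovery and classification from **paired single-cell
multi-omics**: scRNA-seq gene counts and scATAC-seq peak counts measured in
the same cells. The package integrates the two modalities into one per-cell
embedding and classifies cell types on a fused cell-similarity graph,
aimed at analysts working with 10x Multiome / SHARE-seq style data who
need donor-robust cell-type calls and a clusterable joint latent space.

## The method

Given row-matched matrices $X_i \in \mathbb{R}^{N\times D_1}$ (RNA) and
$X_j \in \mathbb{R}^{N\times D_2}$ (ATAC):

1. **Dual autoencoders** compress each modality to $Z_i, Z_j \in
   \mathbb{R}^{N\times d}$ ($d = 128$), trained jointly on
   $L = \alpha\,\mathrm{MSE}(X_i, X_i') + \beta\,\mathrm{MSE}(X_j, X_j')$,
   $\alpha + \beta = 1$.
2. **Bidirectional multi-head cross-attention** exchanges information
   between modalities: per head,
   $\mathrm{head}_i = \mathrm{softmax}(Q_i K_i^\top / \sqrt{d_k})\,V_i$
   with $Q_i = Z_i W_Q$, $K_i = Z_j W_K$, $V_i = Z_j W_V$ (and the
   converse for the ATAC direction); heads are concatenated, projected,
   residual-layer-normalised, and fused by a feed-forward network into
   $Z = \mathrm{FFN}([\mathrm{head}_i' \,\|\, \mathrm{head}_j'])$.
   A **supervised contrastive loss** (cosine similarity, $\tau = 0.5$)
   on training-fold labels sharpens class structure in $Z$.
3. **Similarity network fusion** cross-diffuses per-modality cell kernels
   ($P^{(1)} \leftarrow S^{(1)} P^{(2)} S^{(1)\top}$ and symmetrically)
   into one consensus similarity matrix, and a **two-layer GCN**
   ($H^{(l)} = \sigma(\tilde A H^{(l-1)} W^{(l)})$,
   $\tilde A = D^{-1/2} A D^{-1/2}$) classifies cells on that graph
   transductively — held-out labels are masked, features and edges are not.

Evaluation utilities cover the full protocol: k-means with k-means++
seeding on the fused embedding (ARI / NMI / AMI), accuracy / weighted-F1 /
precision for classification, stratified and donor-grouped k-fold CV,
seed averaging, and paired t / Wilcoxon signed-rank comparisons. A
synthetic paired-omics generator with planted cell types, donors and a
tunable signal strength makes the whole pipeline testable end to end
without downloads.

## Worked example

```r
library(scCrossFuse)

# paired synthetic benchmark: 1000 cells, 5 types, 2000 genes, 5000 peaks
ds  <- generatePaired(syntheticSpec(nDonors = 10, seed = 2))
plan <- makeCVPlan(ds$labels, ds$donors, "grouped_kfold", nFolds = 5, seed = 1)
res <- runExperiment(ds$rna, ds$atac, ds$labels, ds$donors,
                     plan = plan, seeds = 1)
res$summary
```

```
       metric mean sd min max
1         ari    1  0   1   1
2         nmi    1  0   1   1
3         ami    1  0   1   1
4         acc    1  0   1   1
5 weighted_f1    1  0   1   1
6   precision    1  0   1   1
```

Each row summarises the per-fold results: `ari`/`nmi`/`ami` score k-means
clusterings of the fused embedding against the planted cell types, and
`acc`/`weighted_f1`/`precision` score the GCN's predictions on held-out
donors. At the benchmark's default (full) signal strength the planted
types are cleanly separated, so all metrics reach 1.0; lower
`typeSignalStrength` values give graded difficulty
(see `separabilityLadder()`).

The same workflow is available as a single call behind a YAML config —
`runPipeline("config.yaml")` — which writes `metrics.csv`, `summary.csv`
and a reproducibility manifest, and as a thin CLI at
`inst/cli/sccrossfuse.R` (`run` / `sweep` / `synth` subcommands).
`sweepParameter()` scans attention heads or the SNF neighbourhood size.

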