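# RFsubtypes

Prior-knowledge-guided discovery of cancer subtypes from high-dimensional
gene expression data.

## What it does

Cancers with an accepted subtype system (e.g. the PAM50 classes for breast
cancer) still hide finer structure. RFsubtypes uses the known labels to
*supervise gene selection only*, then discovers new subtypes unsupervised:

1. **Consensus selection** — ten independent random forests, each trained
   on its own shuffled 80/20 split of the samples to predict the prior
   labels, score every gene by Gini (mean decrease in impurity)
   importance: for node *e*,
   `NI_e = w_e Gini(S_e) − w_l Gini(S_l) − w_r Gini(S_r)`, and gene *E*
   takes `FI_E = Σ_{e∈R(E)} NI_e / Σ_e NI_e` per tree, averaged over
   trees. Genes with importance > β (default 0.001) in a forest form that
   forest's set `F_i`; the consensus panel is `F = ∩ F_i`.
2. **Condensation** — a symmetric deep autoencoder
   (1024–512–256–128–64–32 encoder, 2-unit linear core, mirrored decoder)
   compresses the standardised panel to two core features per sample,
   trained under mean squared reconstruction error
   `L = Σ_i ||f(x'_i) − x'_i||² / Z`.
3. **Clustering** — k-means++ on the core embedding
   (`D = Σ_k Σ_{h∈cluster_i} ||h − u_i||²`), with k chosen by silhouette
   width over a range, optionally gated on a baseline width.

Quality is reported as purity and NMI against the prior labels, silhouette
width and Davies–Bouldin internally, and adjusted Rand against planted
truth in simulations. A synthetic-data generator with planted subtype
structure makes every stage testable offline, and an exact t-SNE helper
renders the standard two-panel (cluster / prior-label) view.

## Worked example

```r
library(RFsubtypes)

# 300 samples, 1000 genes, 15 informative; 3 planted subtypes hidden
# beneath 2 prior classes
sim <- simulateSubtypeData(simulationSpec(
  m = 300, nGenes = 1000, nInformative = 15, nPriorClasses = 2,
  kTrue = 3, effectSize = 2.5, seed = 1))
se <- filterLowExpression(sim$se, minExpressedSamples = 15)

panel <- selectConsensusFeatures(se, baseSeed = 101)
panel
#> FeaturePanel: 17 consensus genes from 10 forests (beta = 0.001 )
#>   per-forest set sizes: 207, 197, 191, 214, 189, 188, 231, 195, 226, 202
#>   consensus: gene00032, gene00129, gene00187, gene00270, ...

scaler <- standardizeFeatures(sampleMatrix(consensusMatrix(panel)))
ae <- fitAutoencoder(scaler$x, autoencoderConfig(epochs = 500,
                                                 learningRate = 3e-3,
                                                 seed = 201))
coords <- encodeSamples(ae, scaler$x)
ksel <- selectK(coords, kBase = 2, kMax = 8, seed = 301)
chosenK(ksel)
#> [1] 3
adjustedRand(clusterAssignments(ksel), sim$truth$latentClusters)
#> [1] 0.891
evaluateClustering(coords, clusterAssignments(ksel), priorLabels(se))
#> silhouette 0.488 | DBI 0.724 | purity 0.963 | NMI 0.597 (k = 3, N = 300)
```

The ten per-forest sets each carry ~200 genes; their intersection cuts
that to 17, of which all 15 planted informative genes are present
(precision 0.88, recall 1.0). The two core features separate the three
planted subtypes, the silhouette search picks k = 3, and the clustering
agrees with the planted structure at ARI 0.89 — while purity against the
*prior* two-class labels is 0.96, i.e. the finer clusters nest cleanly
inside the known classes. On real cohorts, `runPipeline()` drives the
same stages end to end (and can apply the trained selection/scaler/encoder
to a held-out cohort via its `test` argument), persisting all
intermediates plus a JSON report; `inst/scripts/rfsubtypes.R` is a
command-line wrapper with `simulate`/`run`/`select`/`evaluate`
subcommands.

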