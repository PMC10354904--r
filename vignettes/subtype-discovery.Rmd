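---
title: "Prior-knowledge-guided subtype discovery with parallel random forests"
author: "RFsubtypes authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-knowledge-guided subtype discovery with parallel random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RFsubtypes)
```

## The problem

Expression cohorts for a cancer typically carry a few hundred to a couple of
thousand samples and tens of thousands of genes, of which only a small
fraction is informative about disease subtype. Several cancers already have
accepted subtype systems (for breast cancer, the PAM50 classes Basal, Her2,
LumA, LumB, Normal). Those labels are coarse, but they are valuable prior
knowledge: genes that discriminate the known classes are enriched for genes
that also resolve finer, clinically meaningful structure. RFsubtypes uses
the known labels to supervise *gene selection only*, then discovers new
subtypes unsupervised in the reduced space. The pipeline is

1. **Consensus gene selection.** Ten random forests are trained to predict
   the prior labels, each on its own reshuffled 80/20 split of the samples
   (the "Pareto" split: shuffle the sample order, take the first 80% for
   training). Each forest scores every gene by Gini importance and keeps
   the genes whose importance exceeds a threshold $\beta$; the consensus
   panel $F$ is the intersection of the ten gene sets.
2. **Feature condensation.** A symmetric deep autoencoder compresses the
   panel matrix $\bar X$ (samples $\times$ $|F|$ genes, standardised) to a
   two-dimensional core embedding $X_{CL}$.
3. **Clustering.** k-means++ clusters $X_{CL}$; the number of clusters is
   chosen by silhouette width, optionally gated on a baseline width from a
   reference method.

## The importance machinery

For a node $e$ holding sample set $S_e$ with class proportions $p_i$ over
the $n$ prior classes, the impurity is the Gini index
$\mathrm{Gini}(S) = 1 - \sum_i p_i^2$. A candidate split on gene $A$ at
value $a$ sends samples with $A < a$ left and scores
$\frac{|S_1|}{|S|}\mathrm{Gini}(S_1) + \frac{|S_2|}{|S|}\mathrm{Gini}(S_2)$;
trees greedily minimise this over a random subset of $\sqrt{|C|}$ genes per
node (candidate thresholds are midpoints between consecutive distinct
values). A node's importance is its weighted impurity decrease

$$NI_e = w_e\,\mathrm{Gini}(S_e) - w_{l}\,\mathrm{Gini}(S_{l}) -
  w_{r}\,\mathrm{Gini}(S_{r}),$$

with $w_e$ the fraction of the tree's samples reaching $e$. A gene's
importance in a tree is its share of the total decrease,
$FI_E = \sum_{e \in R(E)} NI_e \,/\, \sum_e NI_e$ (so each tree's vector
sums to one), and the forest importance is the unweighted mean over trees —
the classical mean-decrease-in-impurity. The per-tree denominator and the
unweighted forest mean are our choices where the aggregation is genuinely
open; they match how mainstream random-forest libraries report MDI, which
is also what the stated hyperparameters (100 estimators, depth 14,
square-root feature sampling) presume. Likewise, trees may reuse a gene at
different thresholds along a path — standard CART on continuous features —
while `removeUsedFeature = TRUE` reproduces the stricter variant in which a
split gene is withheld from its children.

Why *ten* forests and an intersection? A single forest's importance ranking
on $m \ll |C|$ data is noisy: a noise gene can ride one lucky split past
$\beta$. Requiring a gene to clear $\beta$ in ten independently reshuffled
forests suppresses exactly that noise while keeping genuinely informative
genes, which clear it every time.

Tie-breaking is deterministic throughout (lowest gene index, then lowest
threshold), and every random draw — bootstrap resampling, per-node gene
subsampling, shuffled splits — comes from R's RNG, so a base seed fully
determines the consensus panel.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `beta` | 0.001 | importance threshold per forest. Calibrated against cohorts with $\sim$20k genes, where the uniform-importance floor $1/|C|$ is $\sim 5\times10^{-5}$; on a toy matrix with 100 genes the floor is 0.01 and `beta` should be raised accordingly. |
| `nForests` | 10 | consensus strictness; the panel shrinks as it grows. |
| `nTrees`, `maxDepth`, `mtry` | 100, 14, $\lceil\sqrt{|C|}\rceil$ | forest capacity. |
| `trainFraction` | 0.8 | Pareto split, ceiling on the training side. |
| `minExpressedSamples` | 500 (filter) / 0 (pipeline) | a gene must have expression $> 0$ in at least this many samples; "expressed" means strictly positive. Scale to the cohort: the default suits 1000+ samples. |
| `encoderWidths` | 1024, 512, 256, 128, 64, 32 | encoder widths, mirrored in the decoder; the core layer has 2 linear units. |
| `epochs`, `batchSize`, `learningRate` | 10000, 128, $10^{-3}$ | autoencoder training budget (Adam). |
| `kBase`, `swBase`, `kMax` | 2, $-1$, 20 | silhouette search range and baseline gate. |

Unstated details of the autoencoder are filled with standard practice for
MSE autoencoders and exposed in `autoencoderConfig()`: rectified-linear
hidden activations (with `tanh` and `sigmoid` selectable), linear core and
output (a bounded `tanh` core is selectable), Adam with learning rate
$10^{-3}$, optional decoupled weight decay (off by default), He/Glorot
initialisation, per-gene standardisation fitted on training samples
(constant genes map to zero; the raw scale can be kept by skipping
`standardizeFeatures`). The loss is the per-sample squared error summed
over genes and averaged over samples; training runs a fixed epoch count
with no early stopping, and convergence is judged from `lossTrace()`, not
from the epoch count. If the panel is wider than the first hidden layer
the architecture is used as-is (the first layer then compresses
immediately); nothing special is done.

Two practical notes on training this architecture on small panels. First,
the network has far more capacity than a panel of tens of genes needs, and
a long-trained model starts encoding per-sample noise into the core
coordinates ("memorisation"): reconstruction loss keeps falling while the
embedding's cluster geometry degrades. Judge an embedding by what it is
for — cluster structure — not by the loss alone. Second, when the epoch
budget is cut well below the 10000-epoch default (our planted-structure
study trains 500 epochs), scale the Adam step up to keep total training
progress comparable; the study uses $3\times10^{-3}$. In our benchmarks
the rectified-linear default yields compact, blob-like embeddings on which
the silhouette search behaves well, while `tanh` sometimes separates
distant clusters better at the cost of elongated clusters and an unstable
silhouette maximiser — worth trying when the default merges clusters you
expect to be distinct.

## Choosing k

The silhouette search evaluates every $k$ in `kBase:kMax` and picks the
silhouette maximiser among candidates that beat `swBase`; if none does, the
overall maximiser is returned with a warning. The gating phrase in the
underlying procedure ("increase k, stop when the width exceeds the
baseline") is ambiguous between first-passage and maximisation; we evaluate
the whole range and maximise, which honours the gate and cannot do worse
than stopping early. During Lloyd iterations an emptied cluster is
re-seeded with the farthest member of the largest cluster; k-means++
seeding uses squared-distance weighting.

## Validity metrics

External, against reference labels: purity (mean over clusters of the
largest class overlap, divided by $N$) and NMI (mutual information
normalised by the arithmetic mean of the partition entropies; `max` and
`sqrt` normalisations are available, and the variant is a function
argument, so reports can state it). Internal: mean silhouette width
(singletons score 0; all-zero distances score 0) and the Davies–Bouldin
index, implemented exactly as the mean over clusters of the worst-case
$(\bar\Omega_i + \bar\Omega_j)/\lVert\Psi_i - \Psi_j\rVert_2$ — note DBI is
*not* bounded by 1, despite occasional claims; we do not clamp it.
Adjusted Rand is included for scoring recovery of planted structure in
simulations. All distances are Euclidean.

## The synthetic generator

`simulateSubtypeData()` emulates the structure the pipeline assumes:
`kTrue` equally sized latent clusters; informative genes up-regulated by
`effectSize * noiseSd` in exactly one cluster (clusters cycled over genes
so each carries markers); noise genes flat at a baseline mean of 5 on a
log-like continuous scale with Gaussian noise (SD 1); a `dropoutRate`
fraction of genes expressed in only 2% of samples, which the
low-expression filter should remove exactly; and prior labels formed by a
deterministic many-to-one coarsening of the latent clusters (cluster
$c \mapsto c \bmod n_{prior}$), emulating known subtypes that hide finer
structure. A Gaussian mixture is deliberately minimal: it exercises every
stage but does not model counts, overdispersion, batch effects,
gene–gene correlation, or class imbalance, so passing tests demonstrate
algorithmic correctness, not robustness to those real-data features.

## Numerical and testing choices

The tree builder is compiled code, but all of its randomness draws from
R's RNG, so results are reproducible from `set.seed()` alone. The test
suite validates the importance computation against a brute-force oracle
that re-routes each tree's bootstrap sample from the root and re-derives
every node's weight and impurity; metric implementations are checked
against plain-loop oracles and, where available, against independent
reference implementations (`cluster::silhouette`,
`mclust::adjustedRandIndex`); small k-means instances are checked against
exhaustive enumeration of all partitions. Tests and the acceptance study
use reduced budgets chosen for the fixture sizes (forests of 20–100 trees,
autoencoder runs of a few hundred to 2000 epochs on panels of 6–30 genes,
a 400-sample, 2000-gene recovery study with the autoencoder at 500
epochs); these are the package's own study sizes, and the spec-scale
defaults remain the documented ones. The one global pipeline seed fans out
to stage seeds by fixed offsets, so each stage is also independently
reproducible.

## Known limitations

- Selection is supervised by the prior labels: genes that separate latent
  subtypes *within* a single prior class but are flat *across* prior
  classes can be missed; the method's premise is that such genes are rare.
- The 2-D core embedding is convenient for k-means and plotting but can
  fold distant clusters together when the cluster centroids span more than
  two dimensions. The hardest case is near-equidistant centroids (k
  clusters spanning k−1 dimensions): a near-linear code must fold a pair,
  and escaping that requires substantially nonlinear training without
  crossing into memorisation. On our planted 4-cluster study this caps
  recovery around ARI 0.8–0.9 at reduced training budgets (an independent
  reference autoencoder implementation shows the same envelope). Inspect
  the embedding (and the t-SNE view) before trusting a small silhouette
  difference.
- On very small cohorts (tens of samples) the deep autoencoder overfits;
  reduce the widths or epochs, or skip straight to clustering the
  standardised panel.
- The k-selection silhouette is computed on the embedding the autoencoder
  produced, so it inherits any distortion of that embedding.

## A worked run

```{r, eval = FALSE}
sim <- simulateSubtypeData(simulationSpec(
  m = 400, nGenes = 2000, nInformative = 20, nPriorClasses = 2,
  kTrue = 4, effectSize = 2, seed = 1))
se <- filterLowExpression(sim$se, minExpressedSamples = 20)
panel <- selectConsensusFeatures(se, baseSeed = 101)
scaler <- standardizeFeatures(sampleMatrix(consensusMatrix(panel)))
ae <- fitAutoencoder(scaler$x, autoencoderConfig(epochs = 500,
                                                 learningRate = 3e-3,
                                                 seed = 201))
coords <- encodeSamples(ae, scaler$x)
ksel <- selectK(coords, kBase = 2, kMax = 8, seed = 301)
evaluateClustering(coords, clusterAssignments(ksel), priorLabels(se))
adjustedRand(clusterAssignments(ksel), sim$truth$latentClusters)
```

`scripts/acceptance.R` runs exactly this study end to end and writes the
quantities it computes (selection precision/recall, panel size, chosen k,
ARI against the planted subtypes, purity/NMI against the prior labels,
silhouette, Davies–Bouldin, final loss) as JSON.
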