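#' Specification of a synthetic labeled expression dataset
#'
#' Describes a Gaussian-mixture expression dataset on a log-like continuous
#' scale with planted subtype structure: \code{kTrue} latent clusters of
#' equal size, a small set of informative genes whose class-conditional
#' means differ, a majority of pure-noise genes, and a fraction of sparse
#' (dropout) genes expressed in almost no samples, there to exercise the
#' low-expression filter. Prior labels are a deterministic many-to-one
#' coarsening of the latent clusters onto \code{nPriorClasses} classes,
#' emulating known subtypes that hide finer structure.
#'
#' @param m number of samples.
#' @param nGenes total number of genes.
#' @param nInformative genes with a cluster-dependent mean shift.
#' @param nPriorClasses number of known (prior) classes, >= 2.
#' @param kTrue number of planted latent clusters, >= nPriorClasses.
#' @param effectSize mean shift of an informative gene in its up-regulated
#'   cluster, in units of \code{noiseSd}; must be positive.
#' @param noiseSd Gaussian noise standard deviation, default 1.
#' @param dropoutRate fraction of genes made sparse, default 0.05.
#' @param baseline mean expression of the background, default 5 (keeps
#'   non-dropout values essentially always positive).
#' @param seed integer seed.
#' @return a validated spec list for \code{\link{simulateSubtypeData}}.
#' @export
simulationSpec <- function(m = 400, nGenes = 2000, nInformative = 20,
                           nPriorClasses = 2, kTrue = 4, effectSize = 2,
                           noiseSd = 1, dropoutRate = 0.05, baseline = 5,
                           seed = 1) {
  spec <- list(m = as.integer(m), nGenes = as.integer(nGenes),
               nInformative = as.integer(nInformative),
               nPriorClasses = as.integer(nPriorClasses),
               kTrue = as.integer(kTrue), effectSize = effectSize,
               noiseSd = noiseSd, dropoutRate = dropoutRate,
               baseline = baseline, seed = as.integer(seed))
  nDropout <- round(spec$dropoutRate * spec$nGenes)
  if (spec$nInformative > spec$nGenes - nDropout)
    stop("nInformative plus dropout genes exceed nGenes")
  if (spec$kTrue < spec$nPriorClasses)
    stop("kTrue must be at least nPriorClasses")
  if (spec$nPriorClasses < 2) stop("need at least two prior classes")
  if (spec$effectSize <= 0 && spec$effectSize != 0)
    stop("effectSize must be non-negative")
  if (spec$m < spec$kTrue) stop("need at least one sample per cluster")
  spec
}

#' Generate a labeled expression dataset with known ground truth
#'
#' Draws the dataset described by a \code{\link{simulationSpec}}. Samples
#' are assigned round-robin to the \code{kTrue} latent clusters (so cluster
#' sizes are as equal as possible). Each informative gene is up-regulated
#' by \code{effectSize * noiseSd} in exactly one latent cluster (clusters
#' cycled over genes, so every cluster carries markers); noise genes share
#' the baseline mean everywhere. Dropout genes are expressed (positive) in
#' only \code{max(1, floor(0.02 m))} samples and zero elsewhere, so any
#' filter threshold above 2\% of the samples removes exactly them. Gene
#' columns are randomly permuted so informativeness is not positional.
#' Byte-identical output for a fixed seed.
#'
#' @param spec a list from \code{\link{simulationSpec}}.
#' @return list with \code{se} (a \code{SummarizedExperiment} with prior
#'   labels) and \code{truth}: \code{latentClusters} (named integer
#'   vector), \code{informativeGenes}, \code{dropoutGenes},
#'   \code{upCluster} (per informative gene), and the spec.
#' @export
simulateSubtypeData <- function(spec = simulationSpec()) {
  set.seed(spec$seed)
  m <- spec$m
  nDropout <- round(spec$dropoutRate * spec$nGenes)
  nNoise <- spec$nGenes - spec$nInformative - nDropout
  sampleIds <- sprintf("sample%04d", seq_len(m))
  latent <- rep_len(seq_len(spec$kTrue), m)
  prior <- ((latent - 1) %% spec$nPriorClasses) + 1

  geneIds <- sprintf("gene%05d", seq_len(spec$nGenes))
  perm <- sample.int(spec$nGenes)  # permute gene columns
  infIdx <- perm[seq_len(spec$nInformative)]
  dropIdx <- if (nDropout > 0)
    perm[spec$nInformative + seq_len(nDropout)] else integer(0)

  x <- matrix(stats::rnorm(m * spec$nGenes, mean = spec$baseline,
                           sd = spec$noiseSd),
              nrow = m, dimnames = list(sampleIds, geneIds))

  upCluster <- rep_len(seq_len(spec$kTrue), spec$nInformative)
  shift <- spec$effectSize * spec$noiseSd
  for (g in seq_len(spec$nInformative)) {
    rows <- latent == upCluster[g]
    x[rows, infIdx[g]] <- x[rows, infIdx[g]] + shift
  }

  nExpr <- max(1L, floor(0.02 * m))
  for (j in dropIdx) {
    col <- numeric(m)
    on <- sample.int(m, nExpr)
    col[on] <- abs(stats::rnorm(nExpr, mean = spec$baseline,
                                sd = spec$noiseSd))
    x[, j] <- col
  }

  labels <- setNames(factor(paste0("P", prior)), sampleIds)
  se <- makeSubtypeExperiment(x, labels)
  list(se = se,
       truth = list(latentClusters = setNames(latent, sampleIds),
                    informativeGenes = geneIds[infIdx],
                    dropoutGenes = geneIds[dropIdx],
                    upCluster = setNames(upCluster, geneIds[infIdx]),
                    spec = spec))
}
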