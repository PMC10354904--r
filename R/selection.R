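#' Consensus gene selection by parallel random forests
#'
#' Runs \code{nForests} independent random forests. Forest i reshuffles the
#' samples and takes a fresh Pareto (80/20 by default) split with seed
#' \code{baseSeed + i}, trains on the training side against the prior
#' subtype labels, computes Gini importances, and keeps the genes whose
#' importance strictly exceeds \code{beta}. The consensus panel is the
#' intersection of the per-forest gene sets; intersecting independent
#' reshuffled runs suppresses the selection noise a single forest is prone
#' to on high-dimensional data.
#'
#' @param se a \code{SummarizedExperiment} with prior labels in
#'   \code{colData(se)$subtype}.
#' @param nForests number of parallel forests, default 10.
#' @param beta importance threshold, default 0.001; a gene enters a
#'   forest's set when its importance is strictly greater.
#' @param trainFraction per-forest training fraction, default 0.8.
#' @param nTrees,maxDepth,mtry forest hyperparameters (defaults 100, 14,
#'   square root of the gene count), passed to \code{\link{trainForest}}.
#' @param baseSeed integer; forest i uses seed \code{baseSeed + i}.
#' @param removeUsedFeature passed to \code{\link{trainForest}}.
#' @return a \linkS4class{FeaturePanel}.
#' @export
selectConsensusFeatures <- function(se, nForests = 10, beta = 0.001,
                                    trainFraction = 0.8, nTrees = 100,
                                    maxDepth = 14, mtry = NULL,
                                    baseSeed = 0,
                                    removeUsedFeature = FALSE) {
  stopifnot(nForests >= 1, beta >= 0)
  genes <- rownames(se)
  if (length(genes) < 1) stop("no genes in the input")
  imp <- matrix(0, nrow = length(genes), ncol = nForests,
                dimnames = list(genes, paste0("forest", seq_len(nForests))))
  sets <- vector("list", nForests)
  for (i in seq_len(nForests)) {
    split <- shuffleSplit(se, trainFraction = trainFraction,
                          seed = baseSeed + i)
    forest <- trainForest(split$train, nTrees = nTrees, maxDepth = maxDepth,
                          mtry = mtry, removeUsedFeature = removeUsedFeature,
                          seed = baseSeed + i)
    imp[, i] <- forestImportance(forest)
    sets[[i]] <- genes[imp[, i] > beta]
  }
  consensus <- Reduce(intersect, sets)
  if (length(consensus) == 0)
    stop("empty consensus gene set; use a smaller beta")
  methods::new("FeaturePanel", importances = imp, perForestSets = sets,
               consensus = consensus, beta = beta,
               baseSeed = as.integer(baseSeed),
               trainFraction = trainFraction,
               xbar = se[consensus, ])
}
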