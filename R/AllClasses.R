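#' Random forest of Gini-minimising CART trees
#'
#' Holds the trees of one forest trained on prior subtype labels, together
#' with the bootstrap resample that grew each tree, so that node statistics
#' (sample counts, class counts, impurities) can be re-derived from the raw
#' sample routing. Trees are stored as node tables: one row per node with
#' columns \code{feature} (1-based split gene, \code{NA} at leaves),
#' \code{threshold}, \code{left}/\code{right} child ids, \code{depth},
#' \code{n} (samples reaching the node, bootstrap multiplicity counted) and
#' \code{gini}.
#'
#' @slot trees list of per-tree records (\code{nodes}, \code{counts},
#'   \code{bootstrap}).
#' @slot geneIds character vector of gene identifiers (column order of the
#'   training matrix).
#' @slot classes character vector of prior subtype class names.
#' @slot nTrees,maxDepth,mtry integer hyperparameters.
#' @slot bootstrap logical; whether trees were grown on bootstrap resamples.
#' @slot seed integer seed that grew the forest.
#' @exportClass GiniForest
setClass("GiniForest",
  representation(
    trees = "list",
    geneIds = "character",
    classes = "character",
    nTrees = "integer",
    maxDepth = "integer",
    mtry = "integer",
    bootstrap = "logical",
    seed = "integer"
  )
)

setValidity("GiniForest", function(object) {
  if (length(object@trees) != object@nTrees)
    return("number of stored trees does not match nTrees")
  depths <- vapply(object@trees, function(t) max(t$nodes[, "depth"]), 0)
  if (any(depths > object@maxDepth))
    return("a tree exceeds maxDepth")
  TRUE
})

#' Consensus gene panel selected by parallel random forests
#'
#' The result of running several independent random forests, each on its own
#' shuffled 80/20 split of the data, thresholding every forest's Gini
#' importances at \code{beta} and intersecting the per-forest gene sets.
#'
#' @slot importances genes x forests numeric matrix of Gini importances
#'   (each column sums to 1).
#' @slot perForestSets list of per-forest selected gene-id sets.
#' @slot consensus character vector: the intersection of the per-forest sets.
#' @slot beta numeric importance threshold (genes kept when importance
#'   strictly exceeds it).
#' @slot baseSeed integer; forest i used seed \code{baseSeed + i}.
#' @slot trainFraction numeric fraction of samples in each forest's
#'   training split.
#' @slot xbar \linkS4class{SummarizedExperiment} restricted to the consensus
#'   genes (all samples).
#' @exportClass FeaturePanel
setClass("FeaturePanel",
  representation(
    importances = "matrix",
    perForestSets = "list",
    consensus = "character",
    beta = "numeric",
    baseSeed = "integer",
    trainFraction = "numeric",
    xbar = "ANY"
  )
)

setValidity("FeaturePanel", function(object) {
  for (s in object@perForestSets)
    if (!all(object@consensus %in% s))
      return("consensus is not contained in every per-forest set")
  if (any(object@importances < 0))
    return("importances must be non-negative")
  TRUE
})

#' Symmetric autoencoder model
#'
#' A fully-connected autoencoder with mirrored encoder/decoder widths and a
#' low-dimensional linear core layer, trained by minibatch Adam on
#' mean-squared reconstruction error (mean over samples of the per-sample
#' squared error summed over genes).
#'
#' @slot weights list of layer parameter pairs (\code{W}, \code{b}).
#' @slot config list of architecture/training settings (see
#'   \code{\link{autoencoderConfig}}).
#' @slot trace numeric vector of per-epoch training losses.
#' @slot inputDim integer number of input genes.
#' @slot geneIds character identifiers of the input genes.
#' @exportClass AutoencoderModel
setClass("AutoencoderModel",
  representation(
    weights = "list",
    config = "list",
    trace = "numeric",
    inputDim = "integer",
    geneIds = "character"
  )
)

setValidity("AutoencoderModel", function(object) {
  if (any(!is.finite(object@trace)))
    return("loss trace contains non-finite values")
  if (any(object@trace < 0))
    return("losses must be non-negative")
  TRUE
})

#' k-means++ clustering model
#'
#' @slot k integer number of clusters (>= 2).
#' @slot centroids k x d numeric matrix.
#' @slot assignments integer vector of 1-based cluster ids, one per sample.
#' @slot objective numeric; total within-cluster squared Euclidean distance.
#' @slot nInit,maxIter integer restart/iteration caps.
#' @slot tol numeric convergence tolerance on centroid movement.
#' @slot seed integer seed.
#' @exportClass KMeansModel
setClass("KMeansModel",
  representation(
    k = "integer",
    centroids = "matrix",
    assignments = "integer",
    objective = "numeric",
    nInit = "integer",
    maxIter = "integer",
    tol = "numeric",
    seed = "integer"
  )
)

setValidity("KMeansModel", function(object) {
  if (!all(seq_len(object@k) %in% object@assignments))
    return("every cluster must be non-empty")
  if (nrow(object@centroids) != object@k)
    return("centroid count must equal k")
  TRUE
})

#' Silhouette-guided choice of the cluster number
#'
#' Records the silhouette width of k-means++ for every candidate k and the
#' chosen k: the silhouette maximiser among candidates whose width exceeds
#' the baseline \code{swBase} (all candidates, with a warning, when none
#' does).
#'
#' @slot kBase,kMax integer search range.
#' @slot swBase numeric baseline silhouette width (gate).
#' @slot table data.frame with columns \code{k} and \code{sw}.
#' @slot chosenK integer.
#' @slot model \linkS4class{KMeansModel} refitted at \code{chosenK}.
#' @exportClass KSelection
setClass("KSelection",
  representation(
    kBase = "integer",
    kMax = "integer",
    swBase = "numeric",
    table = "data.frame",
    chosenK = "integer",
    model = "KMeansModel"
  )
)

setValidity("KSelection", function(object) {
  if (object@chosenK < object@kBase)
    return("chosenK must be at least kBase")
  if (anyDuplicated(object@table$k))
    return("each candidate k may appear only once")
  TRUE
})

setMethod("show", "GiniForest", function(object) {
  cat("GiniForest:", object@nTrees, "trees, max depth", object@maxDepth,
      ", mtry", object@mtry, "\n")
  cat("  ", length(object@geneIds), "genes,",
      length(object@classes), "classes:",
      paste(object@classes, collapse = ", "), "\n")
})

setMethod("show", "FeaturePanel", function(object) {
  sizes <- vapply(object@perForestSets, length, 0L)
  cat("FeaturePanel:", length(object@consensus),
      "consensus genes from", length(object@perForestSets),
      "forests (beta =", object@beta, ")\n")
  cat("  per-forest set sizes:", paste(sizes, collapse = ", "), "\n")
  cat("  consensus:", paste(head(object@consensus, 8), collapse = ", "),
      if (length(object@consensus) > 8) "..." else "", "\n")
})

setMethod("show", "AutoencoderModel", function(object) {
  widths <- object@config$encoderWidths
  cat("AutoencoderModel:", object@inputDim, "->",
      paste(widths, collapse = "-"), "->", object@config$coreDim,
      "-> (mirror) ->", object@inputDim, "\n")
  cat("  trained", length(object@trace), "epochs; final loss",
      format(object@trace[length(object@trace)], digits = 6), "\n")
})

setMethod("show", "KMeansModel", function(object) {
  cat("KMeansModel: k =", object@k, ", N =", length(object@assignments),
      ", objective D =", format(object@objective, digits = 6), "\n")
  cat("  cluster sizes:", paste(tabulate(object@assignments, object@k),
                                collapse = ", "), "\n")
})

setMethod("show", "KSelection", function(object) {
  cat("KSelection: chose k =", object@chosenK, "in [", object@kBase, ",",
      object@kMax, "] (baseline SW =", object@swBase, ")\n")
  print(object@table, row.names = FALSE)
})
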