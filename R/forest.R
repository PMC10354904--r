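#' Gini impurity of a class-count vector
#'
#' \code{Gini(S) = 1 - sum(p_i^2)} with \code{p_i} the class proportions of
#' the sample set. Zero for a pure node; at most \code{1 - 1/n} for n
#' classes.
#'
#' @param classCounts non-negative integer vector of per-class counts, at
#'   least one positive.
#' @return Gini impurity in [0, 1 - 1/n].
#' @export
giniIndex <- function(classCounts) {
  if (any(classCounts < 0)) stop("class counts must be non-negative")
  total <- sum(classCounts)
  if (total == 0) stop("all class counts are zero")
  p <- classCounts / total
  1 - sum(p^2)
}

#' Size-weighted Gini impurity of a candidate split
#'
#' Splits the samples into \code{S1 = {values < threshold}} and \code{S2}
#' (the rest) and returns \code{|S1|/|S| Gini(S1) + |S2|/|S| Gini(S2)}. When
#' either side is empty the split is degenerate and the unsplit impurity
#' \code{Gini(S)} is returned.
#'
#' @param values numeric feature values of the samples in S.
#' @param labels class labels aligned with \code{values}.
#' @param threshold split point a.
#' @return weighted post-split Gini impurity.
#' @export
splitGini <- function(values, labels, threshold) {
  stopifnot(length(values) == length(labels), length(values) > 0)
  labels <- factor(labels)
  left <- values < threshold
  if (!any(left) || all(left))
    return(giniIndex(table(labels)))
  n <- length(values)
  nl <- sum(left)
  (nl * giniIndex(table(labels[left])) +
    (n - nl) * giniIndex(table(labels[!left]))) / n
}

#' Train a random forest of Gini-minimising CART trees
#'
#' Grows \code{nTrees} binary trees, each on a bootstrap resample of the
#' training samples. At every node a random subset of \code{mtry} genes is
#' drawn and the (gene, threshold) pair minimising the size-weighted
#' post-split Gini impurity is chosen; candidate thresholds are midpoints
#' between consecutive distinct sorted values. Growth stops at
#' \code{maxDepth}, at pure nodes, and at single-sample nodes.
#'
#' @param x numeric samples x genes matrix (or a
#'   \code{SummarizedExperiment}, in which case \code{y} defaults to its
#'   prior labels).
#' @param y factor of prior subtype labels, one per sample.
#' @param nTrees number of trees, default 100.
#' @param maxDepth maximum tree depth (root at depth 0), default 14.
#' @param mtry genes sampled per node; default \code{ceiling(sqrt(p))}.
#' @param bootstrap draw each tree's sample with replacement (default).
#' @param removeUsedFeature if \code{TRUE}, a gene used for a split is
#'   withheld from both child subtrees. Off by default: standard CART
#'   reuses continuous features at different thresholds.
#' @param seed integer seed; fully determines the forest.
#' @return a \linkS4class{GiniForest}.
#' @export
trainForest <- function(x, y = NULL, nTrees = 100, maxDepth = 14,
                        mtry = NULL, bootstrap = TRUE,
                        removeUsedFeature = FALSE, seed = 1) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (is.null(y)) y <- priorLabels(x)
    x <- sampleMatrix(x)
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  y <- factor(y)
  stopifnot(length(y) == nrow(x), nlevels(y) >= 1)
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(x)))
  mtry <- max(1L, min(as.integer(mtry), ncol(x)))
  set.seed(seed)
  trees <- cppTrainForest(x, as.integer(y) - 1L, nlevels(y),
                          as.integer(nTrees), as.integer(maxDepth),
                          mtry, bootstrap, removeUsedFeature)
  methods::new("GiniForest", trees = trees, geneIds = colnames(x),
               classes = levels(y), nTrees = as.integer(nTrees),
               maxDepth = as.integer(maxDepth), mtry = mtry,
               bootstrap = bootstrap, seed = as.integer(seed))
}

#' Node importances of one tree
#'
#' For every internal node e, the weighted impurity decrease
#' \code{NI_e = w_e Gini(S_e) - w_l Gini(S_l) - w_r Gini(S_r)}, where the
#' weight \code{w_e} is the fraction of the tree's (bootstrap) samples
#' reaching the node. Non-negative for splits chosen by Gini minimisation.
#'
#' @param tree one element of \code{GiniForest@trees}: a list with a
#'   \code{nodes} table.
#' @return numeric vector of NI values indexed by node id; \code{NA} at
#'   leaves.
#' @export
nodeImportances <- function(tree) {
  nodes <- tree$nodes
  nTotal <- nodes[1, "n"]
  w <- nodes[, "n"] / nTotal
  ni <- rep(NA_real_, nrow(nodes))
  internal <- which(!is.na(nodes[, "feature"]))
  for (e in internal) {
    l <- nodes[e, "left"]
    r <- nodes[e, "right"]
    ni[e] <- w[e] * nodes[e, "gini"] - w[l] * nodes[l, "gini"] -
      w[r] * nodes[r, "gini"]
  }
  ni
}

#' Per-tree normalised feature importance
#'
#' Importance of gene E is the sum of node importances over the nodes that
#' split on E, divided by the total node importance of the tree, so the
#' vector sums to one. A tree that is a single leaf (no splits) yields the
#' zero vector with a warning.
#'
#' @param tree one element of \code{GiniForest@trees}.
#' @param nGenes total number of genes (vector length).
#' @return numeric importance vector of length \code{nGenes}.
#' @export
treeImportance <- function(tree, nGenes) {
  ni <- nodeImportances(tree)
  internal <- which(!is.na(tree$nodes[, "feature"]))
  out <- numeric(nGenes)
  if (length(internal) == 0) {
    warning("tree is a single leaf; zero importance vector")
    return(out)
  }
  total <- sum(ni[internal])
  if (total <= 0) return(out)
  for (e in internal) {
    f <- tree$nodes[e, "feature"]
    out[f] <- out[f] + ni[e]
  }
  out / total
}

#' Forest-level Gini feature importance
#'
#' The unweighted mean over trees of the per-tree normalised importance
#' vectors (mean decrease in impurity); sums to one when any tree splits.
#'
#' @param forest a \linkS4class{GiniForest}.
#' @return named numeric vector over the forest's genes.
#' @export
forestImportance <- function(forest) {
  p <- length(forest@geneIds)
  mats <- vapply(forest@trees, treeImportance, numeric(p), nGenes = p)
  setNames(rowMeans(mats), forest@geneIds)
}

#' Predict prior classes by majority vote (diagnostic)
#'
#' Each tree votes the majority class of the leaf a sample lands in; the
#' forest returns the majority over trees. Ties break to the lowest class
#' index. Exposed as a diagnostic only -- subtype discovery uses the
#' importances, not the predictions.
#'
#' @param object a \linkS4class{GiniForest}.
#' @param x samples x genes matrix over the forest's genes (or a
#'   \code{SummarizedExperiment}).
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
setMethod("predict", "GiniForest", function(object, x, ...) {
  if (methods::is(x, "SummarizedExperiment")) x <- sampleMatrix(x)
  x <- as.matrix(x)
  if (ncol(x) != length(object@geneIds))
    stop("column count does not match the forest's gene space")
  votes <- cppPredictForest(object@trees, x)
  pred <- apply(votes, 2, function(v) which.max(tabulate(v,
    nbins = length(object@classes))))
  factor(object@classes[pred], levels = object@classes)
})
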