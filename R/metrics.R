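.checkPair <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference partitions differ in length")
  if (length(predicted) == 0) stop("empty partitions")
}

#' Clustering purity
#'
#' For each predicted cluster, the size of its largest overlap with any
#' reference class; summed and divided by N. In (0, 1], 1 for a clustering
#' in which every cluster is class-pure.
#'
#' @param predicted cluster assignment vector.
#' @param reference true class vector of the same length.
#' @return purity in (0, 1].
#' @export
clusterPurity <- function(predicted, reference) {
  .checkPair(predicted, reference)
  cont <- table(predicted, reference)
  sum(apply(cont, 1, max)) / length(predicted)
}

#' Normalised mutual information of two partitions
#'
#' Mutual information of the contingency table normalised into [0, 1]. The
#' default normaliser is the arithmetic mean of the two partition
#' entropies; \code{"max"} and \code{"sqrt"} (geometric mean) variants are
#' available. When either partition has a single class (zero entropy) the
#' value is defined as 1 when the two partitions induce identical groupings
#' and 0 otherwise, with a message.
#'
#' @param predicted,reference partition vectors of equal length.
#' @param normalization \code{"arithmetic"} (default), \code{"max"} or
#'   \code{"sqrt"}.
#' @return NMI in [0, 1].
#' @export
clusterNMI <- function(predicted, reference,
                       normalization = c("arithmetic", "max", "sqrt")) {
  .checkPair(predicted, reference)
  normalization <- match.arg(normalization)
  n <- length(predicted)
  cont <- table(predicted, reference)
  pi <- rowSums(cont) / n
  pj <- colSums(cont) / n
  hU <- -sum(ifelse(pi > 0, pi * log(pi), 0))
  hV <- -sum(ifelse(pj > 0, pj * log(pj), 0))
  if (hU == 0 || hV == 0) {
    same <- identical(unname(as.integer(factor(predicted))),
                      unname(as.integer(factor(reference))))
    message("a partition has zero entropy; NMI defined as ",
            if (same) 1 else 0, " by convention")
    return(if (same) 1 else 0)
  }
  pij <- cont / n
  mi <- 0
  for (i in seq_len(nrow(cont)))
    for (j in seq_len(ncol(cont)))
      if (pij[i, j] > 0)
        mi <- mi + pij[i, j] * log(pij[i, j] / (pi[i] * pj[j]))
  denom <- switch(normalization,
                  arithmetic = (hU + hV) / 2,
                  max = max(hU, hV),
                  sqrt = sqrt(hU * hV))
  min(1, max(0, mi / denom))
}

#' Mean silhouette width
#'
#' For sample i, \code{zeta_i} is the mean Euclidean distance to the other
#' members of its own cluster and \code{eta_i} the minimum over other
#' clusters of the mean distance to that cluster's members; the per-sample
#' score is \code{(eta_i - zeta_i) / max(zeta_i, eta_i)}, defined as 0 for
#' singletons and when both quantities are zero. Returns the mean over
#' samples, in [-1, 1].
#'
#' @param coords numeric N x d coordinate matrix.
#' @param assignments cluster vector with 2 <= k <= N - 1 clusters.
#' @return mean silhouette width.
#' @export
silhouetteWidth <- function(coords, assignments) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  cl <- as.integer(factor(assignments))
  k <- max(cl)
  if (length(assignments) != n) stop("assignments length mismatch")
  if (k < 2 || k > n - 1)
    stop("silhouette needs between 2 and N-1 clusters")
  d <- as.matrix(stats::dist(coords))
  sizes <- tabulate(cl, k)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl[i]
    if (sizes[own] == 1) { s[i] <- 0; next }
    zeta <- sum(d[i, cl == own]) / (sizes[own] - 1)
    eta <- min(vapply(setdiff(seq_len(k), own),
                      function(j) mean(d[i, cl == j]), 0))
    mx <- max(zeta, eta)
    s[i] <- if (mx == 0) 0 else (eta - zeta) / mx
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' With \code{Omega_i} the mean Euclidean distance of cluster i's samples
#' to their centroid and \code{Psi_i} the centroid, returns the mean over
#' clusters of \code{max_{j != i} (Omega_i + Omega_j) / ||Psi_i - Psi_j||}.
#' Non-negative; lower is better. Coincident centroids make the ratio
#' undefined and raise an error naming the pair.
#'
#' @param coords numeric N x d coordinate matrix.
#' @param assignments cluster vector with k >= 2 non-empty clusters.
#' @return the index (>= 0).
#' @export
daviesBouldinIndex <- function(coords, assignments) {
  coords <- as.matrix(coords)
  cl <- as.integer(factor(assignments))
  k <- max(cl)
  if (k < 2) stop("Davies-Bouldin needs at least 2 clusters")
  cents <- t(vapply(seq_len(k), function(j)
    colMeans(coords[cl == j, , drop = FALSE]), numeric(ncol(coords))))
  scatter <- vapply(seq_len(k), function(j) {
    mean(sqrt(rowSums(sweep(coords[cl == j, , drop = FALSE], 2,
                            cents[j, ], "-")^2)))
  }, 0)
  ratios <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      sep <- sqrt(sum((cents[i, ] - cents[j, ])^2))
      if (sep == 0)
        stop("clusters ", i, " and ", j, " have coincident centroids")
      ratios[i, j] <- (scatter[i] + scatter[j]) / sep
    }
  }
  mean(apply(ratios, 1, max, na.rm = TRUE))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement of two partitions; 1 iff identical up to
#' relabeling, about 0 for independent partitions. Used to score recovery
#' of planted cluster structure in simulations.
#'
#' @param predicted,reference partition vectors of equal length.
#' @return ARI in [-1, 1].
#' @export
adjustedRand <- function(predicted, reference) {
  .checkPair(predicted, reference)
  cont <- table(predicted, reference)
  n <- length(predicted)
  sumIJ <- sum(choose(cont, 2))
  sumI <- sum(choose(rowSums(cont), 2))
  sumJ <- sum(choose(colSums(cont), 2))
  expected <- sumI * sumJ / choose(n, 2)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(if (sumIJ == expected) 1 else 0)
  (sumIJ - expected) / (maxIdx - expected)
}

#' Clustering evaluation report
#'
#' Convenience wrapper computing the external metrics (purity, NMI,
#' adjusted Rand) against reference labels and the internal metrics
#' (silhouette width, Davies-Bouldin) on the coordinates.
#'
#' @param coords numeric N x d coordinate matrix.
#' @param assignments predicted cluster vector.
#' @param reference optional true labels for the external metrics.
#' @return named list: \code{k}, \code{N}, \code{silhouette}, \code{dbi},
#'   and (given \code{reference}) \code{purity}, \code{nmi}, \code{ari}.
#' @export
evaluateClustering <- function(coords, assignments, reference = NULL) {
  out <- list(k = length(unique(assignments)),
              N = length(assignments),
              silhouette = silhouetteWidth(coords, assignments),
              dbi = daviesBouldinIndex(coords, assignments))
  if (!is.null(reference)) {
    out$purity <- clusterPurity(assignments, reference)
    out$nmi <- clusterNMI(assignments, reference)
    out$ari <- adjustedRand(assignments, reference)
  }
  out
}
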