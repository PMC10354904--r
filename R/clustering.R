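.sqDistToCentroids <- function(x, centroids) {
  # N x k matrix of squared Euclidean distances
  xx <- rowSums(x^2)
  cc <- rowSums(centroids^2)
  outer(xx, cc, "+") - 2 * x %*% t(centroids)
}

.kppSeed <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ], "-")^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 <= 0)) {
      centers[j + 1] <- sample.int(n, 1)
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = pmax(d2, 0))
    }
    dNew <- rowSums(sweep(x, 2, x[centers[j + 1], ], "-")^2)
    d2 <- pmin(d2, dNew)
  }
  x[centers, , drop = FALSE]
}

.lloyd <- function(x, centroids, maxIter, tol) {
  n <- nrow(x)
  k <- nrow(centroids)
  assign <- integer(n)
  for (iter in seq_len(maxIter)) {
    d2 <- .sqDistToCentroids(x, centroids)
    assign <- max.col(-d2, ties.method = "first")
    newC <- centroids
    for (j in seq_len(k)) {
      members <- which(assign == j)
      if (length(members) == 0) {
        # empty cluster: seize the farthest point of the largest cluster
        big <- which.max(tabulate(assign, k))
        cand <- which(assign == big)
        far <- cand[which.max(d2[cbind(cand, assign[cand])])]
        assign[far] <- j
        members <- far
      }
      newC[j, ] <- colMeans(x[members, , drop = FALSE])
    }
    move <- sqrt(max(rowSums((newC - centroids)^2)))
    centroids <- newC
    if (move < tol) break
  }
  d2 <- .sqDistToCentroids(x, centroids)
  assign <- max.col(-d2, ties.method = "first")
  # final guard: keep every cluster populated
  for (j in seq_len(k)) {
    if (!any(assign == j)) {
      big <- which.max(tabulate(assign, k))
      cand <- which(assign == big)
      far <- cand[which.max(d2[cbind(cand, assign[cand])])]
      assign[far] <- j
      centroids[j, ] <- x[far, ]
    }
  }
  obj <- sum(d2[cbind(seq_len(n), assign)])
  # recompute objective against final centroids after any reseat
  d2 <- .sqDistToCentroids(x, centroids)
  obj <- sum(d2[cbind(seq_len(n), assign)])
  list(centroids = centroids, assign = assign, objective = obj)
}

#' k-means++ clustering
#'
#' Clusters samples (typically the two-dimensional core embedding) with
#' k-means++ seeding -- first center uniform over the points, each further
#' center sampled with probability proportional to the squared Euclidean
#' distance to its nearest chosen center -- followed by Lloyd iterations
#' until the largest centroid movement drops below \code{tol} or
#' \code{maxIter} is reached. The best of \code{nInit} restarts by the
#' objective D (total within-cluster squared distance) is returned. An
#' emptied cluster is re-seeded with the farthest point of the largest
#' cluster.
#'
#' @param x numeric N x d matrix of sample coordinates.
#' @param k number of clusters, 2 <= k <= N.
#' @param nInit independent restarts, default 10.
#' @param maxIter Lloyd iteration cap, default 300.
#' @param tol convergence threshold on centroid movement, default 1e-4.
#' @param seed integer seed; identical seed and data give identical
#'   assignments.
#' @return a \linkS4class{KMeansModel}.
#' @export
kmeansPP <- function(x, k, nInit = 10, maxIter = 300, tol = 1e-4,
                     seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k cannot exceed the number of samples")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nInit)) {
    fit <- .lloyd(x, .kppSeed(x, k), maxIter, tol)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  methods::new("KMeansModel", k = as.integer(k),
               centroids = best$centroids,
               assignments = as.integer(best$assign),
               objective = best$objective, nInit = as.integer(nInit),
               maxIter = as.integer(maxIter), tol = tol,
               seed = as.integer(seed))
}

#' Silhouette-guided choice of the cluster number
#'
#' Runs k-means++ for every k from \code{kBase} to \code{kMax} and records
#' the silhouette width. The chosen k maximises the silhouette width among
#' candidates whose width strictly exceeds the baseline \code{swBase}
#' (e.g. the width achieved by a reference method at its own k). When no
#' candidate beats the baseline, the overall silhouette maximiser is
#' returned with a warning.
#'
#' @param x numeric N x d coordinate matrix.
#' @param kBase lower limit of the search (>= 2), default 2.
#' @param swBase baseline silhouette width to beat; default -1 disables
#'   the gate.
#' @param kMax upper limit of the search, default 20 (capped at N - 1).
#' @param nInit,maxIter,tol,seed passed to \code{\link{kmeansPP}}.
#' @return a \linkS4class{KSelection}.
#' @export
selectK <- function(x, kBase = 2, swBase = -1, kMax = 20, nInit = 10,
                    maxIter = 300, tol = 1e-4, seed = 1) {
  x <- as.matrix(x)
  stopifnot(kBase >= 2, kMax >= kBase)
  kMax <- min(kMax, nrow(x) - 1)
  if (kMax < kBase) stop("too few samples for the requested kBase")
  ks <- kBase:kMax
  models <- vector("list", length(ks))
  sw <- numeric(length(ks))
  for (i in seq_along(ks)) {
    models[[i]] <- kmeansPP(x, ks[i], nInit = nInit, maxIter = maxIter,
                            tol = tol, seed = seed + ks[i])
    sw[i] <- silhouetteWidth(x, clusterAssignments(models[[i]]))
  }
  beating <- which(sw > swBase)
  if (length(beating) > 0) {
    chosen <- beating[which.max(sw[beating])]
  } else {
    warning("no candidate k exceeded the baseline silhouette width; ",
            "returning the overall maximiser")
    chosen <- which.max(sw)
  }
  methods::new("KSelection", kBase = as.integer(kBase),
               kMax = as.integer(kMax), swBase = swBase,
               table = data.frame(k = ks, sw = sw),
               chosenK = as.integer(ks[chosen]), model = models[[chosen]])
}
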