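# Independent brute-force oracles used to validate the fast implementations.
# Everything here re-derives quantities from first principles (explicit
# loops, raw sample routing, exhaustive enumeration) and stays independent
# of the package's computation paths.

# --- tree importance oracle: re-derive node weights, impurities and the
# weighted impurity decreases by routing the tree's bootstrap sample from
# the root, then normalise per-feature sums.
oracleTreeImportance <- function(tree, x, y, nGenes) {
  y <- as.integer(factor(y))
  boot <- tree$bootstrap
  nodes <- tree$nodes
  nRoot <- length(boot)
  ni <- rep(NA_real_, nrow(nodes))
  gini <- function(idx) {
    p <- tabulate(y[idx], max(y)) / length(idx)
    1 - sum(p^2)
  }
  route <- function(nodeId, idx) {
    f <- nodes[nodeId, "feature"]
    stopifnot(length(idx) == nodes[nodeId, "n"])  # routing must agree
    if (is.na(f)) return(invisible(NULL))
    thr <- nodes[nodeId, "threshold"]
    leftIdx <- idx[x[idx, f] < thr]
    rightIdx <- idx[x[idx, f] >= thr]
    ni[nodeId] <<- (length(idx) / nRoot) * gini(idx) -
      (length(leftIdx) / nRoot) * gini(leftIdx) -
      (length(rightIdx) / nRoot) * gini(rightIdx)
    route(nodes[nodeId, "left"], leftIdx)
    route(nodes[nodeId, "right"], rightIdx)
  }
  route(1, boot)
  fi <- numeric(nGenes)
  internal <- which(!is.na(nodes[, "feature"]))
  if (length(internal) == 0) return(fi)
  for (e in internal) fi[nodes[e, "feature"]] <- fi[nodes[e, "feature"]] +
    ni[e]
  fi / sum(ni[internal])
}

oracleForestImportance <- function(forest, x, y) {
  p <- ncol(x)
  rowMeans(vapply(forest@trees, oracleTreeImportance, numeric(p),
                  x = x, y = y, nGenes = p))
}

# --- clustering validity oracles, written as plain loops over the raw
# pairwise distances / contingency counts.
oraclePurity <- function(pred, ref) {
  acc <- 0
  for (g in unique(pred)) {
    members <- ref[pred == g]
    acc <- acc + max(vapply(unique(ref), function(d) sum(members == d), 0))
  }
  acc / length(pred)
}

oracleNMI <- function(pred, ref) {
  n <- length(pred)
  uP <- unique(pred)
  uR <- unique(ref)
  hP <- 0
  for (g in uP) { p <- sum(pred == g) / n; hP <- hP - p * log(p) }
  hR <- 0
  for (d in uR) { p <- sum(ref == d) / n; hR <- hR - p * log(p) }
  mi <- 0
  for (g in uP) for (d in uR) {
    pij <- sum(pred == g & ref == d) / n
    if (pij > 0)
      mi <- mi + pij * log(pij / ((sum(pred == g) / n) * (sum(ref == d) / n)))
  }
  mi / ((hP + hR) / 2)
}

oracleSilhouette <- function(coords, cl) {
  n <- nrow(coords)
  s <- numeric(n)
  euclid <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    zeta <- mean(vapply(own, euclid, 0, i = i))
    eta <- Inf
    for (g in setdiff(unique(cl), cl[i])) {
      others <- which(cl == g)
      eta <- min(eta, mean(vapply(others, euclid, 0, i = i)))
    }
    mx <- max(zeta, eta)
    s[i] <- if (mx == 0) 0 else (eta - zeta) / mx
  }
  mean(s)
}

oracleDBI <- function(coords, cl) {
  groups <- sort(unique(cl))
  k <- length(groups)
  cents <- lapply(groups, function(g)
    colMeans(coords[cl == g, , drop = FALSE]))
  omega <- vapply(seq_len(k), function(i) {
    pts <- coords[cl == groups[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cents[[i]], "-")^2)))
  }, 0)
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      sep <- sqrt(sum((cents[[i]] - cents[[j]])^2))
      worst <- max(worst, (omega[i] + omega[j]) / sep)
    }
    total <- total + worst
  }
  total / k
}

# --- exhaustive k-means optimum: enumerate every surjective assignment of
# N points to k clusters and minimise the within-cluster squared distance
# to the cluster means.
oracleKmeansOptimum <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      obj <- 0
      for (j in seq_len(k)) {
        pts <- x[assign == j, , drop = FALSE]
        obj <- obj + sum(sweep(pts, 2, colMeans(pts), "-")^2)
      }
      if (obj < best) best <- obj
    }
    i <- 1
    while (i <= n && assign[i] == k) { assign[i] <- 1L; i <- i + 1 }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# small labelled Gaussian blob fixture in d dimensions
makeBlobs <- function(n, centers, sd = 0.2, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  cl <- rep_len(seq_len(k), n)
  coords <- centers[cl, , drop = FALSE] +
    matrix(rnorm(n * ncol(centers), sd = sd), n)
  list(coords = coords, clusters = cl)
}
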