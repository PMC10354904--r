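# Exact (O(N^2)) t-SNE, sufficient for the cohort sizes this package
# visualises. Conditional-distribution precisions are set by bisection to
# match the requested perplexity; the embedding is optimised by gradient
# descent with adaptive gains, early exaggeration, and momentum switching.

.tsneP <- function(x, perplexity, tolBits = 1e-5) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    betaMin <- -Inf
    betaMax <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP == 0) { p <- rep(1 / length(di), length(di)); sumP <- 1 }
      H <- log(sumP) + beta * sum(di * p) / sumP
      diff <- H - logU
      if (abs(diff) < tolBits) break
      if (diff > 0) {
        betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else {
        betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding of samples
#'
#' Computes an exact two-dimensional t-SNE embedding, deterministic under
#' \code{seed}. Inputs with more than 50 columns are first reduced to 50
#' principal components, the usual preprocessing for t-SNE on expression
#' data.
#'
#' @param x numeric samples x features matrix (high- or low-dimensional).
#' @param perplexity effective neighbour count; must be below the sample
#'   count. Default 30, capped where needed.
#' @param maxIter gradient iterations, default 500.
#' @param seed integer seed for the random initialisation.
#' @return samples x 2 coordinate matrix (columns \code{tsne1},
#'   \code{tsne2}).
#' @export
tsneEmbed <- function(x, perplexity = 30, maxIter = 500, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least three samples")
  if (perplexity >= n)
    stop("perplexity (", perplexity, ") must be below the sample count (",
         n, "); try ", max(2, floor((n - 1) / 3)))
  if (ncol(x) > 50) {
    x <- stats::prcomp(x, rank. = 50, center = TRUE, scale. = FALSE)$x
  }
  P <- .tsneP(x, perplexity)
  set.seed(seed)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gains <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  eta <- 200
  exagUntil <- max(50, round(maxIter / 4))
  for (iter in seq_len(maxIter)) {
    Pe <- if (iter <= exagUntil) P * 12 else P
    num <- 1 / (1 + as.matrix(stats::dist(y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% y
    momentum <- if (iter < 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y), "-")
  }
  dimnames(y) <- list(rownames(x), c("tsne1", "tsne2"))
  y
}
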