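smallConfig <- function(epochs = 200, seed = 1, widths = c(16, 8),
                        lr = 1e-2, batch = 32) {
  autoencoderConfig(encoderWidths = widths, coreDim = 2, epochs = epochs,
                    batchSize = batch, learningRate = lr, seed = seed)
}

test_that("standardisation centers and scales on training statistics only", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  rownames(x) <- paste0("s", 1:3)
  sc <- standardizeFeatures(x)
  expect_equal(unname(colMeans(sc$x)), c(0, 0, 0))
  expect_equal(unname(apply(sc$x[, c(1, 3)], 2, sd)), c(1, 1))
  expect_equal(unname(sc$x[, "b"]), c(0, 0, 0))  # constant gene -> zeros

  # held-out samples are transformed with the training statistics
  xt <- cbind(a = 4, b = 7, c = 30)
  out <- applyStandardization(sc, xt)
  expect_equal(unname(out[1, "a"]), (4 - mean(x[, "a"])) / sd(x[, "a"]))
})

test_that("reconstruction loss is the per-sample squared error mean", {
  expect_equal(reconstructionLoss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(reconstructionLoss(matrix(c(1, 1), 1), matrix(c(0, 0), 1)),
               2)
  a <- matrix(rnorm(12), 3)
  b <- a + 0.5
  expect_equal(reconstructionLoss(a, a + 1), 4 * reconstructionLoss(a, b))
  expect_error(reconstructionLoss(a, t(b)), "shapes differ")
})

test_that("training reduces the loss and is deterministic under seed", {
  blobs <- makeBlobs(60, rbind(c(0, 0, 0, 0), c(4, 4, 4, 4)), sd = 0.3,
                     seed = 5)
  x <- standardizeFeatures(blobs$coords)$x
  fit1 <- fitAutoencoder(x, smallConfig(epochs = 150, seed = 3))
  tr <- lossTrace(fit1)
  expect_length(tr, 150)
  expect_lt(tr[150], tr[1])
  fit2 <- fitAutoencoder(x, smallConfig(epochs = 150, seed = 3))
  expect_equal(tr[150], lossTrace(fit2)[150])
  expect_equal(fit1@weights, fit2@weights)
})

test_that("encoding yields one 2-D coordinate per sample, single samples included", {
  set.seed(8)
  x <- matrix(rnorm(40 * 6), 40, dimnames = list(paste0("s", 1:40), NULL))
  fit <- fitAutoencoder(x, smallConfig(epochs = 30))
  emb <- encodeSamples(fit, x)
  expect_equal(dim(emb), c(40, 2))
  expect_identical(rownames(emb), rownames(x))
  expect_true(all(is.finite(emb)))

  one <- encodeSamples(fit, x[1, , drop = FALSE])
  expect_equal(dim(one), c(1, 2))
  expect_equal(unname(one), unname(emb[1, , drop = FALSE]))

  expect_error(encodeSamples(fit, x[, 1:3]), "expects")
})

test_that("the embedding preserves well-separated cluster structure", {
  centers <- rbind(c(0, 0, 0, 0, 0, 0), c(6, 6, 0, 0, 6, 6),
                   c(0, 6, 6, 6, 0, 6))
  blobs <- makeBlobs(90, centers, sd = 0.4, seed = 12)
  x <- standardizeFeatures(blobs$coords)$x
  fit <- fitAutoencoder(x, smallConfig(epochs = 400, widths = c(32, 16),
                                       seed = 2))
  emb <- encodeSamples(fit, x)
  km <- kmeansPP(emb, 3, nInit = 10, seed = 4)
  expect_gte(adjustedRand(clusterAssignments(km), blobs$clusters), 0.9)
})

test_that("a rank-2 manifold is reconstructed close to the noise floor", {
  set.seed(31)
  m <- 120; p <- 12; sigma <- 0.05
  u <- matrix(rnorm(m * 2), m)
  v <- matrix(rnorm(2 * p), 2)
  x <- u %*% v + matrix(rnorm(m * p, sd = sigma), m)
  noiseFloor <- p * sigma^2  # expected per-sample squared noise norm
  fit <- fitAutoencoder(x, smallConfig(epochs = 2000, widths = c(32, 16),
                                       lr = 3e-3, seed = 7))
  recon <- reconstructSamples(fit, x)
  expect_lt(reconstructionLoss(x, recon), 10 * noiseFloor)
  expect_lt(lossTrace(fit)[2000], lossTrace(fit)[1])
})
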