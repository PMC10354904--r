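test_that("purity matches hand-evaluated overlaps and is relabel-invariant", {
  ref <- c("A", "A", "B", "B", "B")
  pred <- c(1, 1, 1, 2, 2)  # clusters {A,A,B} and {B,B}
  expect_equal(clusterPurity(pred, ref), 0.8)
  expect_equal(clusterPurity(ref, ref), 1)

  # everything in one cluster with balanced labels: majority share 1/n
  expect_equal(clusterPurity(rep(1, 6), rep(c("x", "y", "z"), 2)), 1 / 3)

  # invariance to relabeling either partition
  relab <- c(7, 7, 7, 3, 3)
  expect_equal(clusterPurity(relab, ref), clusterPurity(pred, ref))
  expect_error(clusterPurity(1:3, 1:4), "length")
})

test_that("NMI matches the entropy-formula oracle and handles degeneracies", {
  # printed 2x2 contingency [[2,0],[1,1]]
  pred <- c(1, 1, 2, 2)
  ref <- c(1, 1, 1, 2)
  expect_equal(clusterNMI(pred, ref), oracleNMI(pred, ref),
               tolerance = 1e-12)
  expect_equal(clusterNMI(pred, pred), 1)

  # statistically independent partitions (product contingency)
  predI <- rep(c(1, 2), each = 4)
  refI <- rep(c(1, 2, 1, 2), 2)
  expect_equal(clusterNMI(predI, refI), 0)

  # symmetry
  expect_equal(clusterNMI(pred, ref), clusterNMI(ref, pred))

  # zero-entropy convention: 1 when identical, 0 otherwise, with message
  expect_message(v1 <- clusterNMI(rep(1, 4), rep(1, 4)))
  expect_equal(v1, 1)
  expect_message(v0 <- clusterNMI(rep(1, 4), c(1, 1, 2, 2)))
  expect_equal(v0, 0)
})

test_that("silhouette width matches a brute-force pairwise oracle", {
  # points {0,1} in cluster A, {10,11} in cluster B on a line
  coords <- matrix(c(0, 1, 10, 11), 4)
  cl <- c(1, 1, 2, 2)
  expect_equal(silhouetteWidth(coords, cl), oracleSilhouette(coords, cl),
               tolerance = 1e-12)
  # closed form: edge points score 9.5/10.5, inner points 8.5/9.5
  expect_equal(silhouetteWidth(coords, cl),
               (2 * (9.5 / 10.5) + 2 * (8.5 / 9.5)) / 4)

  # separation limit: tight clusters far apart approach 1
  blobs <- makeBlobs(20, rbind(c(0, 0), c(100, 0)), sd = 0.01, seed = 2)
  expect_gt(silhouetteWidth(blobs$coords, blobs$clusters), 0.99)

  # all points identical: zeta = eta = 0 convention gives 0
  same <- matrix(1, 6, 2)
  expect_equal(silhouetteWidth(same, rep(c(1, 2), 3)), 0)

  expect_error(silhouetteWidth(coords, rep(1, 4)), "between 2 and")
})

test_that("Davies-Bouldin matches its definition on constructed fixtures", {
  # clusters collapsed onto their centroids: zero scatter, zero index
  tight <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_equal(daviesBouldinIndex(tight, c(1, 1, 2, 2)), 0)

  # two clusters at centroid distance 2 with mean scatter 0.5 each
  coords <- rbind(c(-0.5, 0), c(0.5, 0), c(1.5, 0), c(2.5, 0))
  expect_equal(daviesBouldinIndex(coords, c(1, 1, 2, 2)), 0.5)

  # shrinking within-cluster scatter with fixed centroids lowers the index
  wide <- rbind(c(-1, 0), c(1, 0), c(9, 0), c(11, 0))
  narrow <- rbind(c(-0.2, 0), c(0.2, 0), c(9.8, 0), c(10.2, 0))
  expect_lt(daviesBouldinIndex(narrow, c(1, 1, 2, 2)),
            daviesBouldinIndex(wide, c(1, 1, 2, 2)))

  # coincident centroids are undefined
  expect_error(daviesBouldinIndex(rbind(c(0, 1), c(0, -1), c(1, 0),
                                        c(-1, 0)), c(1, 1, 2, 2)),
               "coincident")
})

test_that("adjusted Rand rewards identity up to relabeling and corrects chance", {
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # symmetry
  p <- c(1, 1, 2, 2, 3, 3)
  r <- c(1, 2, 2, 2, 3, 1)
  expect_equal(adjustedRand(p, r), adjustedRand(r, p))
  # near zero in expectation for independent random partitions
  set.seed(10)
  vals <- replicate(300, {
    adjustedRand(sample(1:3, 30, TRUE), sample(1:3, 30, TRUE))
  })
  expect_lt(abs(mean(vals)), 0.03)
})

test_that("adjusted Rand agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(4)
  for (i in 1:25) {
    p <- sample(1:4, 15, TRUE)
    r <- sample(1:3, 15, TRUE)
    expect_equal(adjustedRand(p, r), mclust::adjustedRandIndex(p, r),
                 tolerance = 1e-12)
  }
})

test_that("silhouette agrees with the cluster-package reference", {
  skip_if_not_installed("cluster")
  set.seed(6)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    coords <- matrix(rnorm(n * 2), n)
    cl <- sample(1:3, n, TRUE)
    if (length(unique(cl)) < 2) next
    ours <- silhouetteWidth(coords, cl)
    ref <- mean(cluster::silhouette(as.integer(factor(cl)),
                                    dist(coords))[, "sil_width"])
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})
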