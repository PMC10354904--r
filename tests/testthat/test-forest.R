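test_that("Gini impurity matches hand-evaluated class proportions", {
  expect_equal(giniIndex(c(5, 0, 0)), 0)
  expect_equal(giniIndex(c(3, 3)), 0.5)
  expect_equal(giniIndex(c(2, 3, 1)), 1 - (4 + 9 + 1) / 36)
  expect_error(giniIndex(c(0, 0)), "zero")
  expect_error(giniIndex(c(-1, 2)), "non-negative")
})

test_that("split impurity is the size-weighted child Gini sum", {
  vals <- c(1, 2, 9, 10)
  labs <- c("A", "A", "B", "B")
  # both children pure
  expect_equal(splitGini(vals, labs, 5), 0)
  # S1 = {1} (A), S2 = {2,9,10} (A,B,B): 1/4 * 0 + 3/4 * (1 - 5/9) = 1/3
  expect_equal(splitGini(vals, labs, 2), (3 / 4) * (1 - 5 / 9))
  # threshold below all values: degenerate split returns Gini(S)
  expect_equal(splitGini(vals, labs, 0), 0.5)
})

test_that("tree growth splits perfectly separable data and respects stopping rules", {
  x <- matrix(c(1, 2, 9, 10), 4, 1,
              dimnames = list(paste0("s", 1:4), "g1"))
  y <- factor(c("A", "A", "B", "B"))
  f <- trainForest(x, y, nTrees = 1, maxDepth = 5, mtry = 1,
                   bootstrap = FALSE, seed = 1)
  nodes <- f@trees[[1]]$nodes
  expect_equal(nrow(nodes), 3)          # one split, two leaves
  expect_equal(unname(nodes[1, "feature"]), 1)
  children <- nodes[c(nodes[1, "left"], nodes[1, "right"]), "gini"]
  expect_equal(unname(children), c(0, 0))

  # pure labels: a single leaf
  fPure <- trainForest(x, factor(rep("A", 4)), nTrees = 1,
                       bootstrap = FALSE, seed = 1)
  expect_equal(nrow(fPure@trees[[1]]$nodes), 1)

  # depth cap 0: a single leaf regardless of data
  f0 <- trainForest(x, y, nTrees = 1, maxDepth = 0, bootstrap = FALSE,
                    seed = 1)
  expect_equal(nrow(f0@trees[[1]]$nodes), 1)
})

test_that("node importances equal the weighted impurity decrease", {
  x <- matrix(c(1, 2, 9, 10), 4, 1, dimnames = list(NULL, "g1"))
  y <- factor(c("A", "A", "B", "B"))
  f <- trainForest(x, y, nTrees = 1, maxDepth = 5, mtry = 1,
                   bootstrap = FALSE, seed = 1)
  ni <- nodeImportances(f@trees[[1]])
  # root splits [A,A,B,B] into two pure halves: 1 * 0.5 - 0.5*0 - 0.5*0
  expect_equal(ni[1], 0.5)
  expect_true(all(is.na(ni[2:3])))

  # a split that leaves both children with the parent's class mix has NI 0
  toy <- list(nodes = rbind(
    c(feature = 1, threshold = 0.5, left = 2, right = 3, depth = 0,
      n = 4, gini = 0.5),
    c(NA, NA, NA, NA, 1, 2, 0.5),
    c(NA, NA, NA, NA, 1, 2, 0.5)))
  colnames(toy$nodes) <- c("feature", "threshold", "left", "right",
                           "depth", "n", "gini")
  expect_equal(nodeImportances(toy)[1], 0)
})

test_that("per-tree importance normalises node importances per feature", {
  # toy node table with NI(g1) = 0.5 and NI(g2) = 0.125
  nodes <- rbind(
    c(feature = 1, threshold = 0, left = 2, right = 3, depth = 0,
      n = 8, gini = 0.625),
    c(NA, NA, NA, NA, 1, 4, 0),
    c(2, 0, 4, 5, 1, 4, 0.25),
    c(NA, NA, NA, NA, 2, 2, 0),
    c(NA, NA, NA, NA, 2, 2, 0))
  colnames(nodes) <- c("feature", "threshold", "left", "right", "depth",
                       "n", "gini")
  toy <- list(nodes = nodes)
  ni <- nodeImportances(toy)
  expect_equal(ni[1], 0.5)
  expect_equal(ni[3], 0.125)
  expect_equal(treeImportance(toy, 3), c(0.8, 0.2, 0))

  # single split: the lone splitter takes importance 1
  x <- matrix(c(1, 2, 9, 10), 4, 1, dimnames = list(NULL, "g1"))
  y <- factor(c("A", "A", "B", "B"))
  f <- trainForest(x, y, nTrees = 1, maxDepth = 5, mtry = 1,
                   bootstrap = FALSE, seed = 1)
  expect_equal(treeImportance(f@trees[[1]], 1), 1)

  # leaf-only tree: zero vector, flagged
  fLeaf <- trainForest(x, factor(rep("A", 4)), nTrees = 1,
                       bootstrap = FALSE, seed = 1)
  expect_warning(v <- treeImportance(fLeaf@trees[[1]], 1), "single leaf")
  expect_equal(v, 0)
})

test_that("forest importance is the mean of per-tree vectors and sums to 1", {
  # identical trees (no bootstrap, all features considered) equal one tree
  set.seed(9)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("g", 1:3)))
  y <- factor(rep(c("A", "B"), 10))
  f <- trainForest(x, y, nTrees = 5, maxDepth = 3, mtry = 3,
                   bootstrap = FALSE, seed = 2)
  fi <- forestImportance(f)
  expect_equal(unname(fi), treeImportance(f@trees[[1]], 3))
  expect_equal(sum(fi), 1)
  expect_true(all(fi >= 0))

  # hand-built forest with per-tree vectors (1,0) and (0,1)
  t1 <- list(nodes = rbind(c(1, 0, 2, 3, 0, 4, 0.5),
                           c(NA, NA, NA, NA, 1, 2, 0),
                           c(NA, NA, NA, NA, 1, 2, 0)))
  t2 <- list(nodes = rbind(c(2, 0, 2, 3, 0, 4, 0.5),
                           c(NA, NA, NA, NA, 1, 2, 0),
                           c(NA, NA, NA, NA, 1, 2, 0)))
  colnames(t1$nodes) <- colnames(t2$nodes) <-
    c("feature", "threshold", "left", "right", "depth", "n", "gini")
  f2 <- methods::new("GiniForest", trees = list(t1, t2),
                     geneIds = c("g1", "g2"), classes = c("A", "B"),
                     nTrees = 2L, maxDepth = 14L, mtry = 1L,
                     bootstrap = FALSE, seed = 1L)
  expect_equal(unname(forestImportance(f2)), c(0.5, 0.5))
})

test_that("planted informative genes rank above noise genes", {
  sim <- simulateSubtypeData(simulationSpec(
    m = 100, nGenes = 150, nInformative = 8, nPriorClasses = 2,
    kTrue = 2, effectSize = 2.5, dropoutRate = 0, seed = 11))
  f <- trainForest(sim$se, nTrees = 100, maxDepth = 8, seed = 5)
  fi <- forestImportance(f)
  top <- names(sort(fi, decreasing = TRUE))[1:8]
  expect_gte(length(intersect(top, sim$truth$informativeGenes)), 6)
})

test_that("tree depth never exceeds the cap and weights add up", {
  sim <- simulateSubtypeData(simulationSpec(
    m = 40, nGenes = 25, nInformative = 5, nPriorClasses = 2, kTrue = 2,
    dropoutRate = 0, seed = 4))
  f <- trainForest(sim$se, nTrees = 10, maxDepth = 3, seed = 6)
  for (tr in f@trees) {
    nodes <- tr$nodes
    expect_lte(max(nodes[, "depth"]), 3)
    internal <- which(!is.na(nodes[, "feature"]))
    for (e in internal)
      expect_equal(nodes[e, "n"],
                   nodes[nodes[e, "left"], "n"] +
                     nodes[nodes[e, "right"], "n"])
  }
})

test_that("feature-removal switch prevents reuse along a path", {
  set.seed(13)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("g1", "g2")))
  y <- factor(rep(c("A", "B"), each = 10))
  f <- trainForest(x, y, nTrees = 20, maxDepth = 6, mtry = 2,
                   removeUsedFeature = TRUE, seed = 3)
  pathFeatures <- function(nodes, id, seen) {
    f0 <- nodes[id, "feature"]
    if (is.na(f0)) return(TRUE)
    if (f0 %in% seen) return(FALSE)
    pathFeatures(nodes, nodes[id, "left"], c(seen, f0)) &&
      pathFeatures(nodes, nodes[id, "right"], c(seen, f0))
  }
  for (tr in f@trees)
    expect_true(pathFeatures(tr$nodes, 1, integer(0)))
})

test_that("majority-vote prediction recovers separable prior classes", {
  sim <- simulateSubtypeData(simulationSpec(
    m = 80, nGenes = 40, nInformative = 10, nPriorClasses = 2, kTrue = 2,
    effectSize = 3, dropoutRate = 0, seed = 21))
  x <- sampleMatrix(sim$se)
  y <- priorLabels(sim$se)
  f <- trainForest(x, y, nTrees = 50, maxDepth = 6, seed = 8)
  pred <- predict(f, x)
  expect_gte(mean(pred == y), 0.95)
})
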