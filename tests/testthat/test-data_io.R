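makeToyMatrix <- function(m = 3, p = 2, seed = 1) {
  set.seed(seed)
  matrix(round(runif(m * p, 0, 10), 3), m,
         dimnames = list(paste0("s", seq_len(m)), paste0("g", seq_len(p))))
}

test_that("delimited expression tables round-trip and normalise orientation", {
  x <- makeToyMatrix(3, 2)
  se <- makeSubtypeExperiment(x)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTable(se, path)
  se2 <- readExpressionTable(path)
  expect_equal(sampleMatrix(se2), x)

  # transposed file with the orientation flag flipped gives the same matrix
  tpath <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = colnames(x), t(x), check.names = FALSE)
  write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  se3 <- readExpressionTable(tpath, samplesInRows = FALSE)
  expect_equal(sampleMatrix(se3), x)
})

test_that("malformed tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tg1\tg2", "s1\t1.0\toops", "s2\t2\t3"), path)
  expect_error(readExpressionTable(path), "non-numeric cell.*g2")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tg1", "s1\t1", "s1\t2"), dup)
  expect_error(readExpressionTable(dup), "duplicate")

  x <- makeToyMatrix()
  x[1, 1] <- NA
  expect_error(makeSubtypeExperiment(x), "missing")
})

test_that("low-expression filter keeps genes expressed in enough samples", {
  # genes expressed (value > 0) in 2, 5 and 10 of 10 samples
  x <- cbind(g1 = c(rep(1, 2), rep(0, 8)),
             g2 = c(rep(2, 5), rep(0, 5)),
             g3 = rep(3, 10))
  rownames(x) <- paste0("s", 1:10)
  se <- makeSubtypeExperiment(x)

  expect_equal(rownames(filterLowExpression(se, 5)), c("g2", "g3"))
  expect_equal(rownames(filterLowExpression(se, 0)), c("g1", "g2", "g3"))
  expect_error(filterLowExpression(se, 11), "lower minExpressedSamples")

  # idempotence
  once <- filterLowExpression(se, 5)
  expect_equal(rownames(filterLowExpression(once, 5)), rownames(once))

  # a gene expressed in 499 of 1211 samples is removed at threshold 500
  big <- matrix(1, 1211, 2,
                dimnames = list(sprintf("s%04d", 1:1211), c("ga", "gb")))
  big[500:1211, "ga"] <- 0  # ga expressed in 499 samples
  seBig <- makeSubtypeExperiment(big)
  expect_equal(rownames(filterLowExpression(seBig, 500)), "gb")
})

test_that("shuffled Pareto split is deterministic and partitions samples", {
  x <- makeToyMatrix(10, 3)
  labels <- factor(rep(c("A", "B"), each = 5))
  se <- makeSubtypeExperiment(x, labels)

  sp <- shuffleSplit(se, 0.8, seed = 42)
  expect_equal(ncol(sp$train), 8)
  expect_equal(ncol(sp$test), 2)
  expect_setequal(c(colnames(sp$train), colnames(sp$test)), rownames(x))
  expect_length(intersect(colnames(sp$train), colnames(sp$test)), 0)

  sp2 <- shuffleSplit(se, 0.8, seed = 42)
  expect_identical(colnames(sp$train), colnames(sp2$train))
  sp3 <- shuffleSplit(se, 0.8, seed = 43)
  expect_false(identical(colnames(sp$train), colnames(sp3$train)))

  # labels travel with their samples
  expect_equal(unname(as.character(priorLabels(sp$train))),
               as.character(labels[match(colnames(sp$train), rownames(x))]))

  # a class entirely absent from training warns but does not error
  rare <- factor(c("A", rep("B", 9)))
  seRare <- makeSubtypeExperiment(x, rare)
  found <- FALSE
  for (s in 1:30) {
    w <- tryCatch({shuffleSplit(seRare, 0.8, seed = s); NULL},
                  warning = function(w) w)
    if (!is.null(w)) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("gene-space intersection restricts both matrices identically", {
  a <- makeToyMatrix(4, 3)
  colnames(a) <- c("a", "b", "c")
  b <- makeToyMatrix(5, 3, seed = 2)
  colnames(b) <- c("b", "c", "d")
  out <- intersectGeneSpaces(makeSubtypeExperiment(a),
                             makeSubtypeExperiment(b))
  expect_identical(rownames(out$a), c("b", "c"))
  expect_identical(rownames(out$a), rownames(out$b))

  same <- intersectGeneSpaces(makeSubtypeExperiment(a),
                              makeSubtypeExperiment(a))
  expect_setequal(rownames(same$a), colnames(a))

  d <- makeToyMatrix(4, 2)
  colnames(d) <- c("x", "y")
  expect_error(intersectGeneSpaces(makeSubtypeExperiment(a),
                                   makeSubtypeExperiment(d)), "disjoint")
})

test_that("one-hot label matrix has exactly one 1 per row in the right place", {
  labels <- factor(c("LumA", "Basal", "LumA", "Her2"))
  B <- labelOnehot(labels)
  expect_equal(unname(rowSums(B)), rep(1, 4))
  for (i in seq_along(labels))
    expect_equal(unname(B[i, as.character(labels[i])]), 1L)
})
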