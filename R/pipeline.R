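.stageSeeds <- function(seed) {
  # one global seed fans out to stage seeds by fixed offsets, so each
  # stage is independently reproducible
  list(select = seed, ae = seed + 101L, cluster = seed + 202L,
       tsne = seed + 303L)
}

.logStage <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}

#' Run the full subtype-discovery pipeline
#'
#' Executes, in order: the low-expression gene filter, consensus gene
#' selection by parallel random forests against the prior labels,
#' per-gene standardisation, autoencoder compression to a two-dimensional
#' core embedding, silhouette-guided k-means++ clustering, and metric
#' evaluation. Optionally applies the trained selection, scaler and
#' encoder to a held-out dataset sharing the gene space and clusters its
#' embedding at the chosen k. All stages are deterministic under
#' \code{seed}.
#'
#' @param se training \code{SummarizedExperiment} with prior labels.
#' @param test optional held-out \code{SummarizedExperiment}; it is
#'   restricted to the consensus genes (which must all be present).
#' @param minExpressedSamples low-expression filter threshold; 0 (default)
#'   keeps all genes. Use ~500 for thousand-sample cohorts.
#' @param nForests,beta,nTrees,maxDepth,mtry selection parameters, see
#'   \code{\link{selectConsensusFeatures}}.
#' @param aeConfig autoencoder settings from
#'   \code{\link{autoencoderConfig}}; its seed is overridden by the
#'   pipeline seed fan-out.
#' @param kBase,swBase,kMax k-selection parameters, see
#'   \code{\link{selectK}}.
#' @param seed global integer seed.
#' @param outDir optional directory; when given, all intermediates
#'   (consensus genes, importances, embedding, assignments, k table), the
#'   JSON report and the resolved configuration are written there.
#' @param verbose log stage progress, default \code{TRUE}.
#' @return a list of class \code{"subtypeRun"}: \code{panel},
#'   \code{scaler}, \code{autoencoder}, \code{embedding},
#'   \code{kSelection}, \code{assignments}, \code{metrics},
#'   \code{report} (plain-value summary), and \code{testEmbedding} /
#'   \code{testAssignments} / \code{testMetrics} when \code{test} is given.
#' @export
runPipeline <- function(se, test = NULL, minExpressedSamples = 0,
                        nForests = 10, beta = 0.001, nTrees = 100,
                        maxDepth = 14, mtry = NULL,
                        aeConfig = autoencoderConfig(),
                        kBase = 2, swBase = -1, kMax = 20,
                        seed = 0, outDir = NULL, verbose = TRUE) {
  seeds <- .stageSeeds(as.integer(seed))
  t0 <- Sys.time()

  if (minExpressedSamples > 0) {
    se <- filterLowExpression(se, minExpressedSamples)
    .logStage(verbose, "filter: ", nrow(se), " genes kept")
  }

  panel <- selectConsensusFeatures(se, nForests = nForests, beta = beta,
                                   nTrees = nTrees, maxDepth = maxDepth,
                                   mtry = mtry, baseSeed = seeds$select)
  .logStage(verbose, "selection: |F| = ", length(consensusFeatures(panel)),
            " consensus genes (per-forest sizes ",
            paste(vapply(perForestSets(panel), length, 0L),
                  collapse = ","), ")")

  xbar <- sampleMatrix(consensusMatrix(panel))
  scaler <- standardizeFeatures(xbar)
  aeConfig$seed <- seeds$ae
  ae <- fitAutoencoder(scaler$x, aeConfig)
  coords <- encodeSamples(ae, scaler$x)
  .logStage(verbose, "autoencoder: final loss ",
            format(lossTrace(ae)[length(lossTrace(ae))], digits = 6))

  ksel <- selectK(coords, kBase = kBase, swBase = swBase, kMax = kMax,
                  seed = seeds$cluster)
  assignments <- setNames(clusterAssignments(ksel), rownames(coords))
  .logStage(verbose, "clustering: chose k = ", chosenK(ksel))

  metrics <- evaluateClustering(coords, assignments, priorLabels(se))
  run <- list(panel = panel, scaler = scaler, autoencoder = ae,
              embedding = coords, kSelection = ksel,
              assignments = assignments, metrics = metrics,
              seed = as.integer(seed))

  if (!is.null(test)) {
    genes <- consensusFeatures(panel)
    missing <- setdiff(genes, rownames(test))
    if (length(missing) > 0)
      stop("held-out data lacks ", length(missing), " consensus genes; ",
           "intersect the gene spaces first (intersectGeneSpaces)")
    xt <- applyStandardization(scaler, sampleMatrix(test[genes, ]))
    testCoords <- encodeSamples(ae, xt)
    testModel <- kmeansPP(testCoords, chosenK(ksel),
                          seed = seeds$cluster)
    testAssign <- setNames(clusterAssignments(testModel),
                           rownames(testCoords))
    testLabels <- tryCatch(priorLabels(test), error = function(e) NULL)
    run$testEmbedding <- testCoords
    run$testAssignments <- testAssign
    run$testMetrics <- evaluateClustering(testCoords, testAssign,
                                          testLabels)
    .logStage(verbose, "held-out: clustered ", nrow(testCoords),
              " samples at k = ", chosenK(ksel))
  }

  run$report <- list(
    nSamples = ncol(se), nGenes = nrow(se),
    nConsensusGenes = length(consensusFeatures(panel)),
    perForestSetSizes = vapply(perForestSets(panel), length, 0L),
    finalLoss = lossTrace(ae)[length(lossTrace(ae))],
    chosenK = chosenK(ksel), metrics = metrics,
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(run) <- "subtypeRun"

  if (!is.null(outDir)) .persistRun(run, se, outDir,
                                    minExpressedSamples, nForests, beta,
                                    nTrees, maxDepth, aeConfig, kBase,
                                    swBase, kMax, seed)
  run
}

.persistRun <- function(run, se, outDir, minExpressedSamples, nForests,
                        beta, nTrees, maxDepth, aeConfig, kBase, swBase,
                        kMax, seed) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeLines(consensusFeatures(run$panel),
             file.path(outDir, "consensus_genes.txt"))
  utils::write.table(
    data.frame(gene_id = rownames(importanceMatrix(run$panel)),
               importanceMatrix(run$panel), check.names = FALSE),
    file.path(outDir, "importances.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(run$embedding), run$embedding),
    file.path(outDir, "embedding.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(run$assignments),
               cluster = unname(run$assignments)),
    file.path(outDir, "assignments.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(run$kSelection@table,
                     file.path(outDir, "k_selection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(epoch = seq_along(lossTrace(run$autoencoder)),
               loss = lossTrace(run$autoencoder)),
    file.path(outDir, "loss_trace.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(run$report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(
    list(minExpressedSamples = minExpressedSamples, nForests = nForests,
         beta = beta, nTrees = nTrees, maxDepth = maxDepth,
         autoencoder = aeConfig[setdiff(names(aeConfig), "seed")],
         kBase = kBase, swBase = swBase, kMax = kMax, seed = seed),
    file.path(outDir, "config.yaml"))
  invisible(outDir)
}

#' Run the pipeline from a configuration file
#'
#' Reads a YAML configuration naming the expression table, the label
#' table, the output directory and any tunable of \code{\link{runPipeline}}
#' (\code{minExpressedSamples}, \code{nForests}, \code{beta},
#' \code{nTrees}, \code{maxDepth}, \code{autoencoder:} settings,
#' \code{kBase}, \code{swBase}, \code{kMax}, \code{seed}), then runs the
#' pipeline. A re-run from the configuration written into a run's output
#' directory reproduces that run.
#'
#' @param path YAML configuration file. Required keys: \code{expression}
#'   (delimited matrix path) and \code{labels} (two-column label table);
#'   optional: \code{delimiter}, \code{samplesInRows}, \code{outDir}, and
#'   the tunables above.
#' @return the \code{"subtypeRun"} list, see \code{\link{runPipeline}}.
#' @export
runPipelineFromConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$expression) || is.null(cfg$labels))
    stop("config must name 'expression' and 'labels' files")
  delim <- if (is.null(cfg$delimiter)) "\t" else cfg$delimiter
  rows <- if (is.null(cfg$samplesInRows)) TRUE else cfg$samplesInRows
  se <- readExpressionTable(cfg$expression, delimiter = delim,
                            samplesInRows = rows)
  labels <- readLabels(cfg$labels, delimiter = delim)
  se <- makeSubtypeExperiment(sampleMatrix(se), labels)
  aeArgs <- if (is.null(cfg$autoencoder)) list() else cfg$autoencoder
  aeCfg <- do.call(autoencoderConfig, aeArgs)
  take <- function(name, default) if (is.null(cfg[[name]])) default
                                  else cfg[[name]]
  runPipeline(se,
              minExpressedSamples = take("minExpressedSamples", 0),
              nForests = take("nForests", 10),
              beta = take("beta", 0.001),
              nTrees = take("nTrees", 100),
              maxDepth = take("maxDepth", 14),
              aeConfig = aeCfg,
              kBase = take("kBase", 2),
              swBase = take("swBase", -1),
              kMax = take("kMax", 20),
              seed = take("seed", 0),
              outDir = cfg$outDir)
}

#' @export
print.subtypeRun <- function(x, ...) {
  r <- x$report
  cat("Subtype discovery run\n")
  cat("  samples:", r$nSamples, " genes:", r$nGenes, "\n")
  cat("  consensus genes |F|:", r$nConsensusGenes, "\n")
  cat("  autoencoder final loss:", format(r$finalLoss, digits = 6), "\n")
  cat("  chosen k:", r$chosenK, "\n")
  cat("  silhouette:", round(r$metrics$silhouette, 4),
      " DBI:", round(r$metrics$dbi, 4), "\n")
  if (!is.null(r$metrics$purity))
    cat("  purity:", round(r$metrics$purity, 4),
        " NMI:", round(r$metrics$nmi, 4), "\n")
  invisible(x)
}
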