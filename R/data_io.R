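#' Assemble an expression experiment from a matrix and prior labels
#'
#' Builds the \linkS4class{SummarizedExperiment} container the pipeline
#' works on: genes in rows, samples in columns, assay named \code{"exprs"},
#' with the prior subtype labels (e.g. PAM50 classes) as a factor in
#' \code{colData(se)$subtype}.
#'
#' @param values numeric samples x genes matrix with unique sample row
#'   names and unique gene column names; no missing values.
#' @param labels optional per-sample labels: a factor/character vector
#'   either unnamed in row order of \code{values} or named by sample id.
#' @return a \code{SummarizedExperiment}.
#' @export
makeSubtypeExperiment <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have sample row names and gene column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene identifiers")
  if (anyNA(values))
    stop("expression matrix contains missing values")
  if (!is.numeric(values))
    stop("expression values must be numeric")
  cd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      if (!all(rownames(values) %in% names(labels)))
        stop("labels are missing for some samples")
      labels <- labels[rownames(values)]
    } else if (length(labels) != nrow(values)) {
      stop("labels length does not match the number of samples")
    }
    cd$subtype <- factor(as.character(labels))
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = t(values)), colData = cd)
}

#' Read a delimited expression table
#'
#' Reads a delimited text file with one header line of identifiers and the
#' first column holding the other axis' identifiers, and normalises the
#' orientation to samples x genes (stored genes x samples in the returned
#' container). Non-numeric cells and duplicate identifiers are errors.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @param samplesInRows if \code{TRUE} (default) rows are samples and the
#'   header holds gene ids; if \code{FALSE} the file is transposed.
#' @return a \code{SummarizedExperiment} (assay \code{"exprs"}).
#' @export
readExpressionTable <- function(path, delimiter = "\t",
                                samplesInRows = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("expected an identifier column plus data columns")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate identifiers in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate identifiers in header")
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 ids[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]))
  if (anyNA(num)) stop("expression table contains missing values")
  dimnames(num) <- list(ids, colnames(vals))
  if (!samplesInRows) num <- t(num)
  makeSubtypeExperiment(num)
}

#' Read per-sample subtype labels
#'
#' Reads a two-column delimited file (sample identifier, class) with a
#' header line.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return a named factor of class labels, names = sample ids.
#' @export
readLabels <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected two columns: sample id and class")
  if (anyDuplicated(df[[1]])) stop("duplicate sample identifiers")
  setNames(factor(as.character(df[[2]])), df[[1]])
}

#' Write an expression experiment as a delimited table
#'
#' @param se a \code{SummarizedExperiment} from this package.
#' @param path output file path.
#' @param delimiter field separator, default tab.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(se, path, delimiter = "\t") {
  x <- sampleMatrix(se)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extract the samples x genes matrix
#'
#' @param se a \code{SummarizedExperiment} with an \code{"exprs"} assay.
#' @return numeric samples x genes matrix.
#' @export
sampleMatrix <- function(se) {
  t(SummarizedExperiment::assay(se, "exprs"))
}

#' Extract the prior subtype labels
#'
#' @param se a \code{SummarizedExperiment} with \code{colData(se)$subtype}.
#' @return factor of per-sample labels, named by sample id.
#' @export
priorLabels <- function(se) {
  lab <- SummarizedExperiment::colData(se)$subtype
  if (is.null(lab)) stop("no prior subtype labels attached (colData$subtype)")
  setNames(lab, colnames(se))
}

#' One-hot membership matrix of a label vector
#'
#' @param labels factor or character vector of length m with n distinct
#'   classes.
#' @return m x n binary matrix B with \code{B[i, j] = 1} iff sample i
#'   belongs to class j; each row sums to one.
#' @export
labelOnehot <- function(labels) {
  labels <- factor(labels)
  B <- matrix(0L, nrow = length(labels), ncol = nlevels(labels),
              dimnames = list(names(labels), levels(labels)))
  B[cbind(seq_along(labels), as.integer(labels))] <- 1L
  B
}

#' Drop sparsely expressed genes
#'
#' Removes every gene expressed (value strictly greater than zero) in fewer
#' than \code{minExpressedSamples} samples. Gene order is preserved and the
#' sample set is untouched.
#'
#' @param se a \code{SummarizedExperiment}.
#' @param minExpressedSamples non-negative integer; a gene is kept when its
#'   number of samples with expression > 0 is at least this. Default 500,
#'   sized for cohorts of a thousand-plus samples -- lower it for small
#'   datasets.
#' @return the filtered \code{SummarizedExperiment}.
#' @export
filterLowExpression <- function(se, minExpressedSamples = 500) {
  stopifnot(minExpressedSamples >= 0)
  expressed <- rowSums(SummarizedExperiment::assay(se, "exprs") > 0)
  keep <- expressed >= minExpressedSamples
  if (!any(keep))
    stop("all genes removed by the low-expression filter; ",
         "use a lower minExpressedSamples")
  se[keep, ]
}

#' Shuffle samples and split them by Pareto's law
#'
#' Randomises the sample order under \code{seed} and assigns the first
#' \code{ceiling(trainFraction * m)} shuffled samples to the training
#' partition, the rest to the test partition. Labels travel with their
#' samples. A prior class absent from the training partition triggers a
#' warning, not an error.
#'
#' @param se a \code{SummarizedExperiment} (labels optional).
#' @param trainFraction fraction of samples to train on, in (0, 1);
#'   default 0.8 (the 80/20 Pareto split).
#' @param seed integer seed controlling the shuffle.
#' @return list with elements \code{train} and \code{test}, both
#'   \code{SummarizedExperiment}s.
#' @export
shuffleSplit <- function(se, trainFraction = 0.8, seed = 1) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  m <- ncol(se)
  if (m < 2) stop("need at least two samples to split")
  set.seed(seed)
  ord <- sample.int(m)
  nTrain <- ceiling(trainFraction * m)
  if (nTrain >= m) nTrain <- m - 1  # both partitions non-empty
  trainIdx <- ord[seq_len(nTrain)]
  testIdx <- ord[(nTrain + 1):m]
  lab <- SummarizedExperiment::colData(se)$subtype
  if (!is.null(lab)) {
    missing <- setdiff(levels(factor(lab)), as.character(lab[trainIdx]))
    if (length(missing) > 0)
      warning("prior class(es) absent from the training partition: ",
              paste(missing, collapse = ", "))
  }
  list(train = se[, trainIdx], test = se[, testIdx])
}

#' Restrict two experiments to their shared genes
#'
#' Both returned experiments contain exactly the genes present in both
#' inputs, in one canonical (lexicographic) order, so a model selected or
#' trained on one can be applied to the other.
#'
#' @param a,b \code{SummarizedExperiment}s.
#' @return list with elements \code{a} and \code{b} restricted to the
#'   shared genes.
#' @export
intersectGeneSpaces <- function(a, b) {
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) == 0) stop("the gene sets are disjoint")
  shared <- sort(shared, method = "radix")
  list(a = a[shared, ], b = b[shared, ])
}
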