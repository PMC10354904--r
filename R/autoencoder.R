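#' Per-gene standardisation fitted on training samples
#'
#' Centers every gene to mean zero and scales it to unit variance using
#' statistics of the given (training) samples; constant genes are mapped to
#' zero. The returned scaler lets the identical transform be applied to
#' held-out samples, so no test-set statistics leak into the model.
#'
#' @param x samples x genes matrix or a \code{SummarizedExperiment}.
#' @return list with \code{x} (the transformed matrix), \code{center} and
#'   \code{scale} (per-gene statistics).
#' @export
standardizeFeatures <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) x <- sampleMatrix(x)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two samples to standardise")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- Inf  # constant genes -> all zeros
  out <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  list(x = out, center = center, scale = scale)
}

#' Apply a fitted standardisation to new samples
#'
#' @param scaler the list returned by \code{\link{standardizeFeatures}}.
#' @param x samples x genes matrix over the same genes.
#' @return transformed matrix.
#' @export
applyStandardization <- function(scaler, x) {
  if (methods::is(x, "SummarizedExperiment")) x <- sampleMatrix(x)
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$center))
    stop("column count does not match the fitted scaler")
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Mean-squared reconstruction error
#'
#' The per-sample squared error summed over genes, averaged over the Z
#' samples: \code{sum((f(x) - x)^2) / Z}.
#'
#' @param original,reconstructed matrices of identical shape.
#' @return non-negative scalar loss.
#' @export
reconstructionLoss <- function(original, reconstructed) {
  original <- as.matrix(original)
  reconstructed <- as.matrix(reconstructed)
  if (!identical(dim(original), dim(reconstructed)))
    stop("original and reconstructed shapes differ")
  sum((reconstructed - original)^2) / nrow(original)
}

#' Autoencoder architecture and training settings
#'
#' Defaults follow a deep symmetric design: six encoder hidden layers of
#' widths 1024, 512, 256, 128, 64, 32, a two-unit linear core, and a
#' mirrored decoder. Hidden layers are rectified-linear; core and output
#' are linear; training is minibatch Adam on the mean-squared
#' reconstruction error.
#'
#' @param encoderWidths integer vector of encoder hidden-layer widths; the
#'   decoder mirrors it.
#' @param coreDim width of the core (bottleneck) layer, default 2.
#' @param epochs training epochs, default 10000.
#' @param batchSize minibatch size, default 128 (the last batch may be
#'   partial).
#' @param learningRate Adam step size, default 1e-3.
#' @param activation hidden-layer activation: \code{"relu"} (default),
#'   \code{"tanh"} or \code{"sigmoid"}; the output layer is always linear.
#' @param coreActivation activation of the core (bottleneck) layer:
#'   \code{"linear"} (default) or \code{"tanh"} (bounds the embedding in
#'   \code{[-1, 1]^coreDim}).
#' @param weightDecay decoupled (AdamW-style) L2 penalty applied to the
#'   weight matrices each step; 0 (default) disables it.
#' @param seed integer seed for weight initialisation and batch shuffling.
#' @return a config list for \code{\link{fitAutoencoder}}.
#' @export
autoencoderConfig <- function(encoderWidths = c(1024, 512, 256, 128, 64, 32),
                              coreDim = 2, epochs = 10000, batchSize = 128,
                              learningRate = 1e-3,
                              activation = c("relu", "tanh", "sigmoid"),
                              coreActivation = c("linear", "tanh"),
                              weightDecay = 0, seed = 1) {
  stopifnot(coreDim >= 1, epochs >= 1, batchSize >= 1, learningRate > 0,
            weightDecay >= 0)
  list(encoderWidths = as.integer(encoderWidths),
       coreDim = as.integer(coreDim), epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), learningRate = learningRate,
       activation = match.arg(activation),
       coreActivation = match.arg(coreActivation),
       weightDecay = weightDecay, seed = as.integer(seed))
}

.aeAct <- function(z, activation) {
  switch(activation,
         relu = pmax(z, 0),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)))
}

# derivative of the activation expressed through its output a
.aeActGrad <- function(a, activation) {
  switch(activation,
         relu = (a > 0),
         tanh = 1 - a * a,
         sigmoid = a * (1 - a))
}

.aeLayerDims <- function(inputDim, config) {
  c(inputDim, config$encoderWidths, config$coreDim,
    rev(config$encoderWidths), inputDim)
}

.aeInit <- function(inputDim, config) {
  dims <- .aeLayerDims(inputDim, config)
  lapply(seq_len(length(dims) - 1), function(l) {
    fanIn <- dims[l]
    sdw <- if (identical(config$activation, "relu") ||
               is.null(config$activation))
      sqrt(2 / fanIn)                      # He for rectifiers
    else sqrt(2 / (fanIn + dims[l + 1]))   # Glorot for saturating units
    list(W = matrix(stats::rnorm(fanIn * dims[l + 1], sd = sdw),
                    nrow = fanIn),
         b = numeric(dims[l + 1]))
  })
}

# forward pass; returns list of post-activation outputs per layer
# (a[[1]] = input). Hidden layers relu; core (layer coreIdx) and final
# output linear.
.aeForward <- function(params, x, coreIdx, activation = "relu",
                       coreActivation = "linear") {
  nL <- length(params)
  a <- vector("list", nL + 1)
  a[[1]] <- x
  for (l in seq_len(nL)) {
    z <- a[[l]] %*% params[[l]]$W
    z <- z + rep(params[[l]]$b, each = nrow(z))
    a[[l + 1]] <-
      if (l == nL) z
      else if (l == coreIdx) {
        if (identical(coreActivation, "tanh")) tanh(z) else z
      } else .aeAct(z, activation)
  }
  a
}

#' Fit the symmetric autoencoder
#'
#' Trains on the given matrix (already scaled as desired -- see
#' \code{\link{standardizeFeatures}}) by minibatch Adam under the
#' mean-squared reconstruction loss, for a fixed number of epochs with no
#' early stopping. Fully deterministic under the config seed.
#'
#' @param x numeric samples x genes matrix.
#' @param config a list from \code{\link{autoencoderConfig}}.
#' @return an \linkS4class{AutoencoderModel} whose \code{lossTrace} holds
#'   the mean epoch training loss.
#' @export
fitAutoencoder <- function(x, config = autoencoderConfig()) {
  x <- as.matrix(x)
  m <- nrow(x)
  p <- ncol(x)
  stopifnot(m >= 1, p >= 1)
  set.seed(config$seed)
  if (is.null(config$activation)) config$activation <- "relu"
  if (is.null(config$coreActivation)) config$coreActivation <- "linear"
  if (is.null(config$weightDecay)) config$weightDecay <- 0
  act <- config$activation
  coreAct <- config$coreActivation
  wd <- config$weightDecay
  params <- .aeInit(p, config)
  nL <- length(params)
  coreIdx <- length(config$encoderWidths) + 1
  adamM <- lapply(params, function(pr) list(W = pr$W * 0, b = pr$b * 0))
  adamV <- adamM
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learningRate
  step <- 0
  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(m)
    sse <- 0
    for (start in seq(1, m, by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1, m)]
      xb <- x[idx, , drop = FALSE]
      nb <- nrow(xb)
      a <- .aeForward(params, xb, coreIdx, act, coreAct)
      resid <- a[[nL + 1]] - xb
      sse <- sse + sum(resid^2)
      delta <- 2 * resid / nb  # dL/d(output), L = sum resid^2 / nb
      step <- step + 1
      # bias-corrected Adam in fused form: W -= lrT * m / (sqrt(v) + epsT)
      # with lrT = lr*sqrt(1-b2^t)/(1-b1^t), epsT = eps*sqrt(1-b2^t),
      # algebraically identical to dividing m and v by their corrections
      bc2 <- sqrt(1 - b2^step)
      lrT <- lr * bc2 / (1 - b1^step)
      epsT <- eps * bc2
      for (l in nL:1) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- tcrossprod(delta, params[[l]]$W)
          if ((l - 1) == coreIdx) {
            if (identical(coreAct, "tanh"))
              delta <- delta * (1 - a[[l]] * a[[l]])
          } else if ((l - 1) != nL) {
            delta <- delta * .aeActGrad(a[[l]], act)
          }
        }
        adamM[[l]]$W <- b1 * adamM[[l]]$W + (1 - b1) * gW
        adamM[[l]]$b <- b1 * adamM[[l]]$b + (1 - b1) * gb
        adamV[[l]]$W <- b2 * adamV[[l]]$W + (1 - b2) * gW * gW
        adamV[[l]]$b <- b2 * adamV[[l]]$b + (1 - b2) * gb * gb
        params[[l]]$W <- params[[l]]$W -
          lrT * adamM[[l]]$W / (sqrt(adamV[[l]]$W) + epsT)
        params[[l]]$b <- params[[l]]$b -
          lrT * adamM[[l]]$b / (sqrt(adamV[[l]]$b) + epsT)
        if (wd > 0) params[[l]]$W <- params[[l]]$W * (1 - lr * wd)
      }
    }
    trace[epoch] <- sse / m
    if (!is.finite(trace[epoch]))
      stop("non-finite training loss at epoch ", epoch,
           "; lower the learning rate")
  }
  methods::new("AutoencoderModel", weights = params, config = config,
               trace = trace, inputDim = as.integer(p),
               geneIds = if (is.null(colnames(x))) character(0)
                         else colnames(x))
}

#' Core-layer embedding of samples
#'
#' Pushes samples through the trained encoder and returns the core-layer
#' activations: one low-dimensional coordinate vector per sample.
#'
#' @param model an \linkS4class{AutoencoderModel}.
#' @param x samples x genes matrix with the training input dimension
#'   (already transformed with the training scaler, if one was used).
#' @return numeric samples x coreDim matrix, row names preserved.
#' @export
encodeSamples <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model@inputDim)
    stop("input has ", ncol(x), " genes but the model expects ",
         model@inputDim)
  coreIdx <- length(model@config$encoderWidths) + 1
  act <- model@config$activation
  if (is.null(act)) act <- "relu"
  coreAct <- model@config$coreActivation
  a <- x
  for (l in seq_len(coreIdx)) {
    z <- a %*% model@weights[[l]]$W
    z <- z + rep(model@weights[[l]]$b, each = nrow(z))
    a <- if (l == coreIdx) {
      if (identical(coreAct, "tanh")) tanh(z) else z
    } else .aeAct(z, act)
  }
  rownames(a) <- rownames(x)
  colnames(a) <- paste0("dim", seq_len(ncol(a)))
  a
}

#' Reconstruct samples through the full autoencoder
#'
#' @param model an \linkS4class{AutoencoderModel}.
#' @param x samples x genes matrix with the training input dimension.
#' @return reconstructed matrix of the same shape.
#' @export
reconstructSamples <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model@inputDim)
    stop("input has ", ncol(x), " genes but the model expects ",
         model@inputDim)
  coreIdx <- length(model@config$encoderWidths) + 1
  act <- model@config$activation
  if (is.null(act)) act <- "relu"
  coreAct <- model@config$coreActivation
  if (is.null(coreAct)) coreAct <- "linear"
  a <- .aeForward(model@weights, x, coreIdx, act, coreAct)
  out <- a[[length(a)]]
  dimnames(out) <- dimnames(x)
  out
}
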