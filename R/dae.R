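# Denoising autoencoder layers and greedy layer-wise pretraining.
#
# A layer holds an encoder y = s(W x + b) and a decoder z = s(W' y + b'),
# with s the logistic sigmoid. Training corrupts the input (masking or
# gaussian noise, freshly per minibatch), encodes/decodes the corrupted
# copy, and minimizes the mean squared reconstruction error against the
# clean input. Stacking feeds each layer the *clean* encoding of the
# previous one.

#' Corrupt an input vector or matrix
#'
#' Two corruption modes: `"gaussian"` adds i.i.d. N(0, level^2) noise;
#' `"masking"` zeroes each component independently with probability
#' `level`. A fresh corruption is drawn on every call.
#'
#' @param x numeric vector or matrix.
#' @param mode `"masking"` or `"gaussian"`.
#' @param level masking probability (in `[0, 1]`) or gaussian standard
#'   deviation (`>= 0`).
#' @return corrupted copy of `x`, same shape.
#' @export
corruptInput <- function(x, mode = c("masking", "gaussian"), level) {
  mode <- match.arg(mode)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) || level < 0)
    stop("'level' must be a single non-negative number")
  if (mode == "masking") {
    if (level > 1) stop("masking level must be in [0, 1]")
    if (level == 0) return(x)
    x * (stats::runif(length(x)) >= level)
  } else {
    if (level == 0) return(x)
    x + stats::rnorm(length(x), sd = level)
  }
}

#' Denoising-autoencoder layer: construction, encode, decode
#'
#' `daeLayer()` initializes an untrained layer; `daeEncode()` computes the
#' hidden representation `y = sigmoid(W x + b)`; `daeDecode()` maps a
#' hidden representation back to a reconstruction
#' `z = sigmoid(W' y + b')`. The reconstruction approaches, but never
#' exactly equals, the input.
#'
#' @param inputDim,hiddenDim layer dimensions.
#' @return `daeLayer()`: a list with weight matrices `W` (input x hidden),
#'   `Wp` (hidden x input) and bias vectors `b`, `bp`.
#' @export
daeLayer <- function(inputDim, hiddenDim) {
  list(W = .glorot(inputDim, hiddenDim), b = numeric(hiddenDim),
       Wp = .glorot(hiddenDim, inputDim), bp = numeric(inputDim))
}

#' @param layer a DAE layer.
#' @param x input vector, or matrix with one row per sample.
#' @rdname daeLayer
#' @export
daeEncode <- function(layer, x) {
  if (is.null(dim(x))) {
    if (length(x) != nrow(layer$W)) stop("input dimension mismatch")
    as.vector(.sigmoid(drop(x %*% layer$W) + layer$b))
  } else {
    if (ncol(x) != nrow(layer$W)) stop("input dimension mismatch")
    .sigmoid(.addBias(x %*% layer$W, layer$b))
  }
}

#' @param y hidden vector, or matrix with one row per sample.
#' @rdname daeLayer
#' @export
daeDecode <- function(layer, y) {
  if (is.null(dim(y))) {
    if (length(y) != nrow(layer$Wp)) stop("hidden dimension mismatch")
    as.vector(.sigmoid(drop(y %*% layer$Wp) + layer$bp))
  } else {
    if (ncol(y) != nrow(layer$Wp)) stop("hidden dimension mismatch")
    .sigmoid(.addBias(y %*% layer$Wp, layer$bp))
  }
}

# One epoch-loop of denoising training for a single layer. X is the clean
# input matrix. Returns the layer plus per-epoch mean reconstruction loss.
.trainDaeLayer <- function(layer, X, cfg) {
  losses <- numeric(0)
  if (cfg@pretrainEpochs < 1L)
    return(list(layer = layer, losses = losses))
  p <- layer
  st <- .adamInit(p)
  n <- nrow(X)
  for (e in seq_len(cfg@pretrainEpochs)) {
    ord <- sample(n)
    tot <- 0
    nb <- 0L
    for (start in seq.int(1L, n, by = cfg@batchSize)) {
      bi <- ord[start:min(start + cfg@batchSize - 1L, n)]
      Xb <- X[bi, , drop = FALSE]
      Xc <- corruptInput(Xb, cfg@noiseMode, cfg@noiseLevel)
      Y <- .sigmoid(.addBias(Xc %*% p$W, p$b))
      Z <- .sigmoid(.addBias(Y %*% p$Wp, p$bp))
      diff <- Z - Xb
      loss <- mean(diff^2)
      if (!is.finite(loss)) stop("non-finite reconstruction loss")
      tot <- tot + loss
      nb <- nb + 1L
      dZ <- (2 / length(diff)) * diff * Z * (1 - Z)
      g <- list(W = crossprod(Xc, (tcrossprod(dZ, p$Wp) * Y * (1 - Y))),
                b = colSums(tcrossprod(dZ, p$Wp) * Y * (1 - Y)),
                Wp = crossprod(Y, dZ), bp = colSums(dZ))
      upd <- .adamStep(p, g, st, cfg@pretrainLr)
      p <- upd$p; st <- upd$st
    }
    losses[e] <- tot / nb
  }
  list(layer = p, losses = losses)
}

#' Greedy layer-wise pretraining of a denoising-autoencoder stack
#'
#' Trains the layers in order. Layer i is trained to reconstruct its clean
#' input from a corrupted copy; its *clean* (uncorrupted) encoding of the
#' data then serves as the input of layer i + 1. With
#' `pretrainEpochs = 0` the stack is returned at its random
#' initialization.
#'
#' @param X numeric matrix, one sample per row (values ideally in
#'   `[0, 1]`, the range of the sigmoid decoder).
#' @param widths hidden width of each layer, outermost first.
#' @param cfg a [TrainConfig-class]; uses the pretraining, noise, batch and
#'   seed settings.
#' @param seedOffset stream offset so that several stacks trained under one
#'   config get independent randomness.
#' @return list with `layers` (the trained stack) and `losses` (per-layer
#'   numeric vectors of per-epoch mean reconstruction loss).
#' @export
pretrainSdae <- function(X, widths, cfg, seedOffset = 11L) {
  stopifnot(is.matrix(X), nrow(X) > 0L)
  set.seed(.subSeed(cfg@seed, seedOffset))
  layers <- vector("list", length(widths))
  losses <- vector("list", length(widths))
  H <- X
  for (i in seq_along(widths)) {
    layer <- daeLayer(ncol(H), widths[i])
    fit <- .trainDaeLayer(layer, H, cfg)
    layers[[i]] <- fit$layer
    losses[[i]] <- fit$losses
    H <- daeEncode(fit$layer, H)
  }
  list(layers = layers, losses = losses)
}
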