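#' TrainConfig: hyperparameters for branch and ensemble training
#'
#' Captures every tunable of the training procedure: the two-phase
#' optimizer schedule (Adam for fast convergence, then plain SGD
#' fine-tuning), early stopping on validation loss, dropout on the
#' fully-connected head layers, denoising-autoencoder pretraining, and the
#' layer widths of both branches.
#'
#' @slot adamEpochs,sgdEpochs epoch budget of each optimization phase.
#' @slot adamLr,sgdLr learning rates of the two phases.
#' @slot batchSize minibatch size.
#' @slot patience early stopping: number of epochs without validation-loss
#'   improvement tolerated before training halts (best weights restored).
#' @slot dropout dropout probability on fully-connected hidden layers,
#'   disabled at inference. Default 0.5.
#' @slot pretrainEpochs,pretrainLr per-layer denoising-autoencoder
#'   pretraining budget (SDAE branch only).
#' @slot noiseMode `"masking"` (zero a component with probability
#'   `noiseLevel`) or `"gaussian"` (add N(0, noiseLevel^2)).
#' @slot noiseLevel corruption level; a probability in `[0, 1]` for
#'   masking, a standard deviation for gaussian.
#' @slot sdaeWidths hidden widths of each molecule's autoencoder stack.
#' @slot headWidths hidden widths of the fully-connected classifier head
#'   (a final 2-way softmax layer is appended).
#' @slot cnnFilters filters of the three convolution layers.
#' @slot kernelSize,poolSize 1-D convolution kernel width and max-pool
#'   width (pooling after conv-1 and conv-2).
#' @slot combinerEpochs,combinerLr training budget of the softmax ensemble
#'   combiner.
#' @slot seed RNG seed; all corruption, shuffling, dropout and
#'   initialization derive from it, so runs are reproducible.
#' @export
setClass("TrainConfig",
  representation(adamEpochs = "integer", sgdEpochs = "integer",
                 adamLr = "numeric", sgdLr = "numeric",
                 batchSize = "integer", patience = "integer",
                 dropout = "numeric",
                 pretrainEpochs = "integer", pretrainLr = "numeric",
                 noiseMode = "character", noiseLevel = "numeric",
                 sdaeWidths = "integer", headWidths = "integer",
                 cnnFilters = "integer", kernelSize = "integer",
                 poolSize = "integer",
                 combinerEpochs = "integer", combinerLr = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@adamEpochs < 0L || object@sgdEpochs < 0L ||
        object@adamEpochs + object@sgdEpochs < 1L)
      msg <- c(msg, "need a positive total epoch budget")
    if (object@dropout < 0 || object@dropout >= 1)
      msg <- c(msg, "dropout must be in [0, 1)")
    if (!object@noiseMode %in% c("masking", "gaussian"))
      msg <- c(msg, "noiseMode must be 'masking' or 'gaussian'")
    if (object@noiseLevel < 0)
      msg <- c(msg, "noiseLevel must be >= 0")
    if (object@noiseMode == "masking" && object@noiseLevel > 1)
      msg <- c(msg, "masking noiseLevel must be in [0, 1]")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be positive")
    if (object@patience < 1L) msg <- c(msg, "patience must be positive")
    if (length(object@cnnFilters) != 3L)
      msg <- c(msg, "cnnFilters must give three convolution layers")
    if (object@poolSize != 2L)
      msg <- c(msg, "only poolSize = 2 is supported")
    if (length(msg)) msg else TRUE
  })

#' @param adamEpochs,sgdEpochs,adamLr,sgdLr,batchSize,patience,dropout see
#'   slots.
#' @param pretrainEpochs,pretrainLr,noiseMode,noiseLevel see slots.
#' @param sdaeWidths,headWidths,cnnFilters,kernelSize,poolSize see slots.
#' @param combinerEpochs,combinerLr,seed see slots.
#' @return a validated [TrainConfig-class].
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(adamEpochs = 30L, sgdEpochs = 20L,
                        adamLr = 1e-3, sgdLr = 1e-4,
                        batchSize = 64L, patience = 5L, dropout = 0.5,
                        pretrainEpochs = 10L, pretrainLr = 1e-3,
                        noiseMode = "masking", noiseLevel = 0.2,
                        sdaeWidths = c(256L, 128L, 64L),
                        headWidths = c(128L, 64L),
                        cnnFilters = c(64L, 32L, 16L),
                        kernelSize = 5L, poolSize = 2L,
                        combinerEpochs = 200L, combinerLr = 0.05,
                        seed = 1L) {
  new("TrainConfig",
      adamEpochs = as.integer(adamEpochs), sgdEpochs = as.integer(sgdEpochs),
      adamLr = adamLr, sgdLr = sgdLr,
      batchSize = as.integer(batchSize), patience = as.integer(patience),
      dropout = dropout,
      pretrainEpochs = as.integer(pretrainEpochs), pretrainLr = pretrainLr,
      noiseMode = noiseMode, noiseLevel = noiseLevel,
      sdaeWidths = as.integer(sdaeWidths), headWidths = as.integer(headWidths),
      cnnFilters = as.integer(cnnFilters), kernelSize = as.integer(kernelSize),
      poolSize = as.integer(poolSize),
      combinerEpochs = as.integer(combinerEpochs), combinerLr = combinerLr,
      seed = as.integer(seed))
}

setMethod("show", "TrainConfig", function(object) {
  cat("TrainConfig\n")
  cat(sprintf("  schedule: %d Adam epochs (lr %g) then %d SGD epochs (lr %g), batch %d\n",
              object@adamEpochs, object@adamLr, object@sgdEpochs,
              object@sgdLr, object@batchSize))
  cat(sprintf("  early stopping patience %d, dropout %.2f\n",
              object@patience, object@dropout))
  cat(sprintf("  pretraining: %d epochs/layer, %s noise %.2f\n",
              object@pretrainEpochs, object@noiseMode, object@noiseLevel))
  cat(sprintf("  SDAE widths %s | CNN filters %s kernel %d | head %s\n",
              paste(object@sdaeWidths, collapse = "-"),
              paste(object@cnnFilters, collapse = "-"),
              object@kernelSize,
              paste(object@headWidths, collapse = "-")))
  cat(sprintf("  seed %d\n", object@seed))
})

# Derive a sub-seed for an independent stage; kept well below 2^31.
.subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97L + offset) %% 2147483629)
}
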