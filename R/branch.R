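# The two prediction branches. Each consumes an (RNA vector, protein
# vector) pair: a molecule-specific embedding tower per input, a
# concatenation, and a fully-connected softmax head with dropout.
#  - SDAE branch: three sigmoid dense layers per molecule, initialized by
#    greedy denoising-autoencoder pretraining, then fine-tuned end-to-end.
#  - CNN branch: three 1-D convolutions per molecule (ReLU) with max
#    pooling after conv-1 and conv-2, then a flatten.

#' Branch model classes
#'
#' Fitted prediction branches. `SdaeBranchModel` holds the pretrained and
#' fine-tuned autoencoder towers plus head; `CnnBranchModel` the
#' convolutional towers plus head. Both store the feature scaler, the
#' config used, and the per-epoch training history.
#'
#' @slot params flat named list of weight matrices and bias vectors.
#' @slot arch architecture metadata (input dims, widths, kernel, ...).
#' @slot scaler per-feature min-max scalers fitted on the training data.
#' @slot cfg the [TrainConfig-class] used.
#' @slot history data.frame of per-epoch train/validation loss.
#' @slot pretrainLosses per-layer reconstruction-loss traces (SDAE only).
#' @export
setClass("SdaeBranchModel",
  representation(params = "list", arch = "list", scaler = "list",
                 cfg = "TrainConfig", history = "data.frame",
                 pretrainLosses = "list"))

#' @rdname SdaeBranchModel-class
#' @export
setClass("CnnBranchModel",
  representation(params = "list", arch = "list", scaler = "list",
                 cfg = "TrainConfig", history = "data.frame"))

setMethod("show", "SdaeBranchModel", function(object) {
  cat(sprintf("SdaeBranchModel: RNA %d-dim, protein %d-dim, towers %s, head %s; %d epochs\n",
              object@arch$rDim, object@arch$pDim,
              paste(object@arch$widths, collapse = "-"),
              paste(object@arch$headWidths, collapse = "-"),
              nrow(object@history)))
})

setMethod("show", "CnnBranchModel", function(object) {
  cat(sprintf("CnnBranchModel: RNA %d-dim, protein %d-dim, filters %s kernel %d, head %s; %d epochs\n",
              object@arch$rDim, object@arch$pDim,
              paste(object@arch$filters, collapse = "-"),
              object@arch$kernel,
              paste(object@arch$headWidths, collapse = "-"),
              nrow(object@history)))
})

# ---- SDAE branch engine ----------------------------------------------------

.sdaeEngine <- function(arch) {
  nL <- length(arch$widths)
  nH <- length(arch$headWidths)
  dr <- arch$widths[nL]
  list(
    forward = function(p, Xr, Xp, training) {
      rAs <- .denseStackForward(p, "r", Xr, nL, "sigmoid")
      pAs <- .denseStackForward(p, "p", Xp, nL, "sigmoid")
      H <- cbind(rAs[[nL + 1L]], pAs[[nL + 1L]])
      hf <- .headForward(p, H, nH, arch$dropout, training)
      list(P = hf$P, rAs = rAs, pAs = pAs, hf = hf)
    },
    backward = function(p, fw, dLogits) {
      hb <- .headBackward(p, fw$hf, nH, arch$dropout, dLogits, list())
      rb <- .denseStackBackward(p, "r", fw$rAs, nL, "sigmoid",
                                hb$dH[, seq_len(dr), drop = FALSE], hb$grads)
      pb <- .denseStackBackward(p, "p", fw$pAs, nL, "sigmoid",
                                hb$dH[, -seq_len(dr), drop = FALSE], rb$grads)
      pb$grads
    })
}

.initHead <- function(p, inDim, headWidths) {
  prev <- inDim
  for (i in seq_along(headWidths)) {
    p[[paste0("hW", i)]] <- .glorot(prev, headWidths[i])
    p[[paste0("hb", i)]] <- numeric(headWidths[i])
    prev <- headWidths[i]
  }
  p$outW <- .glorot(prev, 2L)
  p$outb <- numeric(2L)
  p
}

# ---- CNN branch engine -----------------------------------------------------

# output length of one tower, used to size the flatten
.cnnTowerDims <- function(L, K, filters) {
  L1 <- L - K + 1L
  L1p <- L1 %/% 2L
  L2 <- L1p - K + 1L
  L2p <- L2 %/% 2L
  L3 <- L2p - K + 1L
  if (L3 < 1L) stop("input too short for the configured CNN tower")
  list(flat = L3 * filters[3L], L3 = L3)
}

.cnnTowerForward <- function(p, prefix, X, K) {
  dim(X) <- c(dim(X), 1L)
  cf1 <- .convForward(X, p[[paste0(prefix, "cW1")]], p[[paste0(prefix, "cb1")]], K)
  pf1 <- .poolForward(cf1$A)
  cf2 <- .convForward(pf1$A, p[[paste0(prefix, "cW2")]], p[[paste0(prefix, "cb2")]], K)
  pf2 <- .poolForward(cf2$A)
  cf3 <- .convForward(pf2$A, p[[paste0(prefix, "cW3")]], p[[paste0(prefix, "cb3")]], K)
  out <- cf3$A
  d3 <- dim(out)
  dim(out) <- c(d3[1L], d3[2L] * d3[3L])
  list(out = out, d3 = d3, cf1 = cf1, pf1 = pf1, cf2 = cf2, pf2 = pf2, cf3 = cf3)
}

.cnnTowerBackward <- function(p, prefix, tw, dOut, grads) {
  d3 <- dOut
  dim(d3) <- tw$d3
  b3 <- .convBackward(tw$cf3, p[[paste0(prefix, "cW3")]], d3)
  grads[[paste0(prefix, "cW3")]] <- b3$dW
  grads[[paste0(prefix, "cb3")]] <- b3$db
  d2 <- .poolBackward(tw$pf2, b3$dX)
  b2 <- .convBackward(tw$cf2, p[[paste0(prefix, "cW2")]], d2)
  grads[[paste0(prefix, "cW2")]] <- b2$dW
  grads[[paste0(prefix, "cb2")]] <- b2$db
  d1 <- .poolBackward(tw$pf1, b2$dX)
  b1 <- .convBackward(tw$cf1, p[[paste0(prefix, "cW1")]], d1, needDX = FALSE)
  grads[[paste0(prefix, "cW1")]] <- b1$dW
  grads[[paste0(prefix, "cb1")]] <- b1$db
  grads
}

.cnnEngine <- function(arch) {
  nH <- length(arch$headWidths)
  K <- arch$kernel
  list(
    forward = function(p, Xr, Xp, training) {
      tr <- .cnnTowerForward(p, "r", Xr, K)
      tp <- .cnnTowerForward(p, "p", Xp, K)
      H <- cbind(tr$out, tp$out)
      hf <- .headForward(p, H, nH, arch$dropout, training)
      list(P = hf$P, tr = tr, tp = tp, hf = hf)
    },
    backward = function(p, fw, dLogits) {
      hb <- .headBackward(p, fw$hf, nH, arch$dropout, dLogits, list())
      dr <- ncol(fw$tr$out)
      grads <- .cnnTowerBackward(p, "r", fw$tr,
                                 hb$dH[, seq_len(dr), drop = FALSE], hb$grads)
      .cnnTowerBackward(p, "p", fw$tp,
                        hb$dH[, -seq_len(dr), drop = FALSE], grads)
    })
}

# ---- training --------------------------------------------------------------

.checkTrainable <- function(pairs) {
  if (nPairs(pairs) == 0L) stop("no pairs to train on")
  y <- pairLabels(pairs)
  if (anyNA(y)) stop("all training pairs must be labeled")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  y
}

#' Train one prediction branch
#'
#' Fits either the stacked-denoising-autoencoder branch (greedy layer-wise
#' pretraining of both molecule towers, then end-to-end fine-tuning) or
#' the convolutional branch on encoded pairs. Optimization runs an Adam
#' phase followed by an SGD fine-tuning phase, with minibatch shuffling,
#' dropout on the head, and early stopping on a stratified validation
#' holdout (best weights restored). Fully reproducible given `cfg@seed`.
#'
#' @param type `"sdae"` or `"cnn"`.
#' @param pairs an [EncodedPairs-class] with 0/1 labels.
#' @param cfg a [TrainConfig-class].
#' @param validationFraction fraction of pairs held out (stratified) to
#'   monitor early stopping.
#' @return a fitted [SdaeBranchModel-class] or [CnnBranchModel-class].
#' @export
trainBranch <- function(type = c("sdae", "cnn"), pairs, cfg = trainConfig(),
                        validationFraction = 0.15) {
  type <- match.arg(type)
  stopifnot(is(pairs, "EncodedPairs"), is(cfg, "TrainConfig"))
  if (validationFraction <= 0 || validationFraction >= 1)
    stop("validationFraction must be in (0, 1)")
  y <- .checkTrainable(pairs)
  Xr0 <- featureMatrix(pairs, "rna")
  Xp0 <- featureMatrix(pairs, "protein")
  scaler <- list(rna = .fitScaler(Xr0), protein = .fitScaler(Xp0))
  Xr <- .applyScaler(scaler$rna, Xr0)
  Xp <- .applyScaler(scaler$protein, Xp0)

  if (type == "sdae") {
    arch <- list(rDim = ncol(Xr), pDim = ncol(Xp), widths = cfg@sdaeWidths,
                 headWidths = cfg@headWidths, dropout = cfg@dropout,
                 withStructure = pairs@withStructure)
    preR <- pretrainSdae(Xr, arch$widths, cfg, seedOffset = 11L)
    preP <- pretrainSdae(Xp, arch$widths, cfg, seedOffset = 12L)
    set.seed(.subSeed(cfg@seed, 13L))
    p <- list()
    for (i in seq_along(arch$widths)) {
      p[[paste0("rW", i)]] <- preR$layers[[i]]$W
      p[[paste0("rb", i)]] <- preR$layers[[i]]$b
      p[[paste0("pW", i)]] <- preP$layers[[i]]$W
      p[[paste0("pb", i)]] <- preP$layers[[i]]$b
    }
    p <- .initHead(p, 2L * arch$widths[length(arch$widths)], arch$headWidths)
    engine <- .sdaeEngine(arch)
    set.seed(.subSeed(cfg@seed, 14L))
    fit <- .trainSupervised(engine, p, Xr, Xp, y, cfg, validationFraction)
    new("SdaeBranchModel", params = fit$params, arch = arch, scaler = scaler,
        cfg = cfg, history = fit$history,
        pretrainLosses = list(rna = preR$losses, protein = preP$losses))
  } else {
    K <- cfg@kernelSize
    f <- cfg@cnnFilters
    rT <- .cnnTowerDims(ncol(Xr), K, f)
    pT <- .cnnTowerDims(ncol(Xp), K, f)
    arch <- list(rDim = ncol(Xr), pDim = ncol(Xp), filters = f, kernel = K,
                 headWidths = cfg@headWidths, dropout = cfg@dropout,
                 rFlat = rT$flat, pFlat = pT$flat,
                 withStructure = pairs@withStructure)
    set.seed(.subSeed(cfg@seed, 21L))
    p <- list()
    for (prefix in c("r", "p")) {
      cin <- 1L
      for (i in 1:3) {
        p[[paste0(prefix, "cW", i)]] <- .glorot(K * cin, f[i])
        p[[paste0(prefix, "cb", i)]] <- numeric(f[i])
        cin <- f[i]
      }
    }
    p <- .initHead(p, rT$flat + pT$flat, arch$headWidths)
    engine <- .cnnEngine(arch)
    set.seed(.subSeed(cfg@seed, 22L))
    fit <- .trainSupervised(engine, p, Xr, Xp, y, cfg, validationFraction)
    new("CnnBranchModel", params = fit$params, arch = arch, scaler = scaler,
        cfg = cfg, history = fit$history)
  }
}

# ---- prediction ------------------------------------------------------------

#' Class-probability predictions
#'
#' Returns, for each pair, the probability of the two classes
#' (column `interact` is class 1). Inference is deterministic: dropout is
#' disabled and rows sum to 1 (softmax).
#'
#' @param object a fitted branch or ensemble model.
#' @param pairs an [EncodedPairs-class] whose encoding mode matches the
#'   model (340/399-dim sequence-only or 370/438-dim with structure).
#' @param ... unused.
#' @return numeric matrix with columns `nonInteract`, `interact`.
#' @export
setGeneric("predictProb", function(object, pairs, ...)
  standardGeneric("predictProb"))

.checkPredictDims <- function(arch, pairs) {
  if (ncol(featureMatrix(pairs, "rna")) != arch$rDim ||
      ncol(featureMatrix(pairs, "protein")) != arch$pDim)
    stop(sprintf(paste0("encoded dimensions (%d, %d) do not match the ",
                        "trained model (%d, %d); check the structure mode"),
                 ncol(featureMatrix(pairs, "rna")),
                 ncol(featureMatrix(pairs, "protein")),
                 arch$rDim, arch$pDim))
}

.predictChunked <- function(engine, params, scaler, pairs, chunk = 128L) {
  Xr <- .applyScaler(scaler$rna, featureMatrix(pairs, "rna"))
  Xp <- .applyScaler(scaler$protein, featureMatrix(pairs, "protein"))
  n <- nrow(Xr)
  out <- matrix(NA_real_, n, 2L,
                dimnames = list(NULL, c("nonInteract", "interact")))
  for (start in seq.int(1L, n, by = chunk)) {
    i <- start:min(start + chunk - 1L, n)
    out[i, ] <- engine$forward(params, Xr[i, , drop = FALSE],
                               Xp[i, , drop = FALSE], training = FALSE)$P
  }
  out
}

#' @rdname predictProb
#' @export
setMethod("predictProb", "SdaeBranchModel", function(object, pairs, ...) {
  stopifnot(is(pairs, "EncodedPairs"))
  .checkPredictDims(object@arch, pairs)
  .predictChunked(.sdaeEngine(object@arch), object@params, object@scaler, pairs,
                  chunk = 1024L)
})

#' @rdname predictProb
#' @export
setMethod("predictProb", "CnnBranchModel", function(object, pairs, ...) {
  stopifnot(is(pairs, "EncodedPairs"))
  .checkPredictDims(object@arch, pairs)
  .predictChunked(.cnnEngine(object@arch), object@params, object@scaler, pairs)
})
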