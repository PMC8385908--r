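#' EnsembleModel: SDAE branch + CNN branch + softmax combiner
#'
#' The combiner is a single softmax layer over the concatenated class
#' probabilities of the two branches (4 inputs, 2 outputs), trained with
#' binary cross-entropy on the same labels as the branches.
#'
#' @slot sdae,cnn the fitted branches.
#' @slot combiner list with weight matrix `W` (4 x 2) and bias `b`.
#' @slot cfg the [TrainConfig-class] used.
#' @export
setClass("EnsembleModel",
  representation(sdae = "SdaeBranchModel", cnn = "CnnBranchModel",
                 combiner = "list", cfg = "TrainConfig"))

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel (SDAE branch + CNN branch + softmax combiner)\n")
  show(object@sdae)
  show(object@cnn)
})

#' Train the softmax ensemble combiner
#'
#' Fits a single 4-input, 2-output softmax layer on concatenated branch
#' probability pairs, minimizing binary cross-entropy with full-batch
#' Adam.
#'
#' @param P numeric matrix with 4 columns: the two branches' class
#'   probabilities, concatenated.
#' @param y 0/1 labels.
#' @param cfg a [TrainConfig-class]; uses `combinerEpochs`, `combinerLr`
#'   and the seed.
#' @return list with `W` (4 x 2) and `b` (length 2).
#' @export
trainCombiner <- function(P, y, cfg = trainConfig()) {
  stopifnot(is.matrix(P), ncol(P) == 4L, nrow(P) == length(y))
  set.seed(.subSeed(cfg@seed, 31L))
  Y <- .oneHot(y)
  p <- list(W = .glorot(4L, 2L), b = numeric(2L))
  st <- .adamInit(p)
  for (e in seq_len(cfg@combinerEpochs)) {
    Pr <- .softmaxRows(.addBias(P %*% p$W, p$b))
    dLogits <- (Pr - Y) / nrow(P)
    g <- list(W = crossprod(P, dLogits), b = colSums(dLogits))
    upd <- .adamStep(p, g, st, cfg@combinerLr)
    p <- upd$p; st <- upd$st
  }
  p
}

#' Train the full ensemble
#'
#' Trains the SDAE branch and the CNN branch on the same encoded pairs,
#' then fits the softmax combiner on the branches' predicted probability
#' pairs. By default the combiner is trained on in-sample branch
#' predictions; `combinerData = "heldout"` uses only the pairs of a
#' stratified holdout instead (a stacking-flavoured alternative).
#'
#' @param pairs an [EncodedPairs-class] with 0/1 labels.
#' @param cfg a [TrainConfig-class].
#' @param validationFraction early-stopping holdout fraction for each
#'   branch.
#' @param combinerData `"insample"` or `"heldout"`.
#' @return a fitted [EnsembleModel-class].
#' @export
trainEnsemble <- function(pairs, cfg = trainConfig(),
                          validationFraction = 0.15,
                          combinerData = c("insample", "heldout")) {
  combinerData <- match.arg(combinerData)
  y <- .checkTrainable(pairs)
  sdae <- trainBranch("sdae", pairs, cfg, validationFraction)
  cnn <- trainBranch("cnn", pairs, cfg, validationFraction)
  if (combinerData == "heldout") {
    set.seed(.subSeed(cfg@seed, 32L))
    hi <- .stratifiedHoldout(y, validationFraction)
    sub <- pairs[hi]
    Pc <- cbind(predictProb(sdae, sub), predictProb(cnn, sub))
    comb <- trainCombiner(Pc, y[hi], cfg)
  } else {
    Pc <- cbind(predictProb(sdae, pairs), predictProb(cnn, pairs))
    comb <- trainCombiner(Pc, y, cfg)
  }
  new("EnsembleModel", sdae = sdae, cnn = cnn, combiner = comb, cfg = cfg)
}

#' @rdname predictProb
#' @export
setMethod("predictProb", "EnsembleModel", function(object, pairs, ...) {
  P <- cbind(predictProb(object@sdae, pairs), predictProb(object@cnn, pairs))
  out <- .softmaxRows(.addBias(P %*% object@combiner$W, object@combiner$b))
  colnames(out) <- c("nonInteract", "interact")
  out
})

#' Save or load a fitted model
#'
#' Serializes a model (branch or ensemble) together with the package
#' version to a single file.
#'
#' @param model a fitted model object.
#' @param path file path.
#' @export
modelSave <- function(model, path) {
  saveRDS(list(model = model,
               package = "plipred",
               version = as.character(utils::packageVersion("plipred"))),
          path)
  invisible(path)
}

#' @rdname modelSave
#' @export
modelLoad <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$package, "plipred"))
    stop("not a plipred model archive: ", path)
  obj$model
}
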