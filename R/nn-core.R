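# Minimal neural-network engine: dense and 1-D convolutional layers with
# manual backpropagation, Adam and SGD updates. Everything is expressed as
# BLAS-backed matrix products; 3-D activations use an im2col index gather.
# Parameters live in flat named lists so the optimizers are generic.

.sigmoid <- function(z) 1 / (1 + exp(-z))

.act <- function(z, act) {
  switch(act,
         sigmoid = .sigmoid(z),
         relu = { z[z < 0] <- 0; z },
         linear = z,
         stop("unknown activation: ", act))
}

# derivative of the activation expressed through its output a
.actGradFromOutput <- function(a, act) {
  switch(act,
         sigmoid = a * (1 - a),
         relu = (a > 0) * 1,
         linear = 1,
         stop("unknown activation: ", act))
}

.softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean categorical cross-entropy; Y is a one-hot matrix
.ceLoss <- function(P, Y) {
  -mean(rowSums(Y * log(pmax(P, 1e-12))))
}

.oneHot <- function(y) {
  cbind(1 - y, y)
}

.glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

.addBias <- function(Z, b) {
  Z + rep(b, each = nrow(Z))
}

# ---- dense layers ----------------------------------------------------------

# forward through a stack of dense layers, params named <prefix>W<i>/<prefix>b<i>
.denseStackForward <- function(p, prefix, X, nLayers, act) {
  As <- vector("list", nLayers + 1L)
  As[[1L]] <- X
  for (i in seq_len(nLayers)) {
    Z <- .addBias(As[[i]] %*% p[[paste0(prefix, "W", i)]],
                  p[[paste0(prefix, "b", i)]])
    As[[i + 1L]] <- .act(Z, act)
  }
  As
}

# backward through the same stack; dTop is the gradient w.r.t. the stack
# output activation. Returns grads plus gradient w.r.t. the stack input.
.denseStackBackward <- function(p, prefix, As, nLayers, act, dTop, grads) {
  dA <- dTop
  for (i in rev(seq_len(nLayers))) {
    dZ <- dA * .actGradFromOutput(As[[i + 1L]], act)
    grads[[paste0(prefix, "W", i)]] <- crossprod(As[[i]], dZ)
    grads[[paste0(prefix, "b", i)]] <- colSums(dZ)
    dA <- tcrossprod(dZ, p[[paste0(prefix, "W", i)]])
  }
  list(grads = grads, dX = dA)
}

# classifier head: relu hidden layers with inverted dropout, final softmax
.headForward <- function(p, H, nHidden, dropout, training) {
  As <- vector("list", nHidden + 1L)
  masks <- vector("list", nHidden)
  As[[1L]] <- H
  for (i in seq_len(nHidden)) {
    Z <- .addBias(As[[i]] %*% p[[paste0("hW", i)]], p[[paste0("hb", i)]])
    A <- .act(Z, "relu")
    if (training && dropout > 0) {
      m <- matrix(stats::runif(length(A)) >= dropout, nrow(A), ncol(A))
      A <- A * m / (1 - dropout)
      masks[[i]] <- m
    }
    As[[i + 1L]] <- A
  }
  logits <- .addBias(As[[nHidden + 1L]] %*% p$outW, p$outb)
  list(P = .softmaxRows(logits), As = As, masks = masks)
}

.headBackward <- function(p, hf, nHidden, dropout, dLogits, grads) {
  grads$outW <- crossprod(hf$As[[nHidden + 1L]], dLogits)
  grads$outb <- colSums(dLogits)
  dA <- tcrossprod(dLogits, p$outW)
  for (i in rev(seq_len(nHidden))) {
    if (!is.null(hf$masks[[i]]))
      dA <- dA * hf$masks[[i]] / (1 - dropout)
    dZ <- dA * (hf$As[[i + 1L]] > 0)
    grads[[paste0("hW", i)]] <- crossprod(hf$As[[i]], dZ)
    grads[[paste0("hb", i)]] <- colSums(dZ)
    dA <- tcrossprod(dZ, p[[paste0("hW", i)]])
  }
  list(grads = grads, dH = dA)
}

# ---- 1-D convolution / pooling --------------------------------------------

# X: (N, L, C) array; W: (K*C) x F; relu activation. Unfold, fold, bias
# and pooling run in compiled code (src/conv.cpp); the contractions are
# BLAS matrix products.
.convForward <- function(X, W, b, K) {
  d <- dim(X)
  N <- d[1L]; L <- d[2L]; C <- d[3L]
  Lout <- L - K + 1L
  if (Lout < 1L) stop("input too short for convolution kernel")
  Xcol <- cppIm2col(X, N, L, C, K)
  A <- Xcol %*% W
  mask <- cppBiasRelu(A, b)
  dim(A) <- c(N, Lout, ncol(W))
  list(A = A, Xcol = Xcol, mask = mask,
       N = N, L = L, C = C, K = K, Lout = Lout)
}

# needDX = FALSE skips the (unused) input gradient of the first layer
.convBackward <- function(cf, W, dA, needDX = TRUE) {
  dZm <- dA * cf$mask
  dim(dZm) <- c(cf$N * cf$Lout, ncol(W))
  dW <- crossprod(cf$Xcol, dZm)
  db <- colSums(dZm)
  if (!needDX) return(list(dX = NULL, dW = dW, db = db))
  dXcol <- tcrossprod(dZm, W)
  dX <- cppCol2im(dXcol, cf$N, cf$L, cf$C, cf$K)
  dim(dX) <- c(cf$N, cf$L, cf$C)
  list(dX = dX, dW = dW, db = db)
}

# width-2 max pooling (stride 2, remainder dropped); ties keep the earlier
# position
.poolForward <- function(A) {
  d <- dim(A)
  Lp <- d[2L] %/% 2L
  if (Lp < 1L) stop("input too short for pooling")
  r <- cppPoolFwd(A, d[1L], d[2L], d[3L])
  out <- r$A
  dim(out) <- c(d[1L], Lp, d[3L])
  list(A = out, sel = r$sel, Lin = d[2L])
}

.poolBackward <- function(pf, dOut) {
  d <- dim(dOut)
  dX <- cppPoolBwd(dOut, pf$sel, d[1L], pf$Lin, d[3L])
  dim(dX) <- c(d[1L], pf$Lin, d[3L])
  dX
}

# ---- optimizers ------------------------------------------------------------

.adamInit <- function(p) {
  zero <- lapply(p, function(x) x * 0)
  list(m = zero, v = zero, t = 0L)
}

.adamStep <- function(p, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (nm in names(p)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(p = p, st = st)
}

.sgdStep <- function(p, g, lr) {
  for (nm in names(p))
    p[[nm]] <- p[[nm]] - lr * g[[nm]]
  p
}

# ---- generic supervised training loop --------------------------------------

# Stratified index of a validation holdout
.stratifiedHoldout <- function(y, fraction) {
  idx <- integer(0)
  for (cl in unique(y)) {
    i <- which(y == cl)
    nv <- max(1L, round(length(i) * fraction))
    idx <- c(idx, sample(i, nv))
  }
  sort(idx)
}

# engine: list(forward(p, Xr, Xp, training) -> list(P, cache),
#              backward(p, cache, dLogits) -> grads)
# Runs the Adam phase then the SGD phase with early stopping on validation
# cross-entropy (best weights restored). Returns params and history.
.trainSupervised <- function(engine, params, Xr, Xp, y, cfg, valFraction) {
  n <- length(y)
  vi <- .stratifiedHoldout(y, valFraction)
  ti <- setdiff(seq_len(n), vi)
  if (length(unique(y[ti])) < 2L || length(unique(y[vi])) < 2L)
    stop("both classes required in training and validation splits")
  Y <- .oneHot(y)
  Xrv <- Xr[vi, , drop = FALSE]; Xpv <- Xp[vi, , drop = FALSE]
  Yv <- Y[vi, , drop = FALSE]

  best <- list(loss = Inf, params = params)
  wait <- 0L
  hist <- list()
  stopEarly <- FALSE
  phases <- list(list(name = "adam", epochs = cfg@adamEpochs, lr = cfg@adamLr),
                 list(name = "sgd", epochs = cfg@sgdEpochs, lr = cfg@sgdLr))
  epoch <- 0L
  for (ph in phases) {
    if (stopEarly || ph$epochs < 1L) next
    st <- if (ph$name == "adam") .adamInit(params) else NULL
    for (e in seq_len(ph$epochs)) {
      epoch <- epoch + 1L
      ord <- sample(ti)
      batchLoss <- 0
      nb <- 0L
      for (start in seq.int(1L, length(ord), by = cfg@batchSize)) {
        bi <- ord[start:min(start + cfg@batchSize - 1L, length(ord))]
        fw <- engine$forward(params, Xr[bi, , drop = FALSE],
                             Xp[bi, , drop = FALSE], training = TRUE)
        Yb <- Y[bi, , drop = FALSE]
        batchLoss <- batchLoss + .ceLoss(fw$P, Yb)
        nb <- nb + 1L
        dLogits <- (fw$P - Yb) / length(bi)
        g <- engine$backward(params, fw, dLogits)
        if (ph$name == "adam") {
          upd <- .adamStep(params, g, st, ph$lr)
          params <- upd$p; st <- upd$st
        } else {
          params <- .sgdStep(params, g, ph$lr)
        }
      }
      valP <- engine$forward(params, Xrv, Xpv, training = FALSE)$P
      vloss <- .ceLoss(valP, Yv)
      if (!is.finite(vloss)) stop("non-finite validation loss during training")
      hist[[epoch]] <- data.frame(epoch = epoch, phase = ph$name,
                                  trainLoss = batchLoss / nb, valLoss = vloss)
      if (vloss < best$loss - 1e-8) {
        best <- list(loss = vloss, params = params)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg@patience) { stopEarly <- TRUE; break }
      }
    }
  }
  list(params = best$params, history = do.call(rbind, hist),
       valLoss = best$loss)
}

# ---- feature scaling -------------------------------------------------------

# Per-column min-max scaler fitted on training data; constant columns map
# to 0. Keeps inputs in [0, 1], which suits the sigmoid autoencoder stacks.
.fitScaler <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rg <- hi - lo
  rg[rg == 0] <- 1
  list(lo = lo, rg = rg)
}

.applyScaler <- function(scaler, X) {
  X <- sweep(X, 2L, scaler$lo, "-")
  sweep(X, 2L, scaler$rg, "/")
}
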