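test_that("corruption modes behave as specified", {
  x <- runif(100)
  set.seed(1)
  expect_identical(corruptInput(x, "masking", 0), x)
  expect_identical(corruptInput(x, "gaussian", 0), x)
  expect_identical(corruptInput(x, "masking", 1), x * 0)
  # masking level 0.5 on a long vector zeroes about half the components
  set.seed(2)
  big <- runif(10000) + 1      # strictly positive, so zeros are detectable
  frac <- mean(corruptInput(big, "masking", 0.5) == 0)
  expect_gt(frac, 0.45); expect_lt(frac, 0.55)
  # fresh corruption per call
  set.seed(3)
  expect_false(identical(corruptInput(big, "masking", 0.5),
                         corruptInput(big, "masking", 0.5)))
  expect_error(corruptInput(x, "masking", 1.5), "\\[0, 1\\]")
  expect_error(corruptInput(x, "gaussian", -1), "non-negative")
})

test_that("autoencoder encode/decode match the closed-form sigmoid maps", {
  # zero weights: sigmoid(0) = 0.5 everywhere
  layer <- list(W = matrix(0, 4, 3), b = numeric(3),
                Wp = matrix(0, 3, 4), bp = numeric(4))
  expect_equal(daeEncode(layer, c(1, 2, 3, 4)), rep(0.5, 3))
  expect_equal(daeDecode(layer, c(1, 1, 1)), rep(0.5, 4))
  # 1x1 identity-like layer
  l1 <- list(W = matrix(1, 1, 1), b = 0, Wp = matrix(1, 1, 1), bp = 0)
  expect_equal(daeEncode(l1, 0), 0.5)
  # general fixed weights against a direct evaluation
  set.seed(4)
  l2 <- daeLayer(5, 3)
  x <- runif(5)
  expect_equal(daeEncode(l2, x),
               as.vector(1 / (1 + exp(-(x %*% l2$W + l2$b)))))
  y <- daeEncode(l2, x)
  expect_equal(daeDecode(l2, y),
               as.vector(1 / (1 + exp(-(y %*% l2$Wp + l2$bp)))))
  # encode-decode round trip preserves shape, not values
  expect_length(daeDecode(l2, daeEncode(l2, x)), 5L)
  expect_error(daeEncode(l2, numeric(4)), "dimension mismatch")
})

test_that("greedy pretraining reduces reconstruction loss layer by layer", {
  set.seed(8)
  X <- matrix(runif(200 * 30), 200, 30)
  cfg <- trainConfig(pretrainEpochs = 8L, batchSize = 32L, seed = 8L)
  fit <- pretrainSdae(X, c(16L, 8L), cfg)
  expect_length(fit$layers, 2L)
  for (losses in fit$losses) {
    expect_length(losses, 8L)
    expect_lt(losses[length(losses)], losses[1])
  }
  # zero pretraining epochs: the stack stays at its seeded initialization
  cfg0 <- trainConfig(pretrainEpochs = 0L, seed = 8L)
  a <- pretrainSdae(X, c(16L, 8L), cfg0)
  b <- pretrainSdae(X, c(16L, 8L), cfg0)
  expect_identical(a$layers, b$layers)
  expect_length(a$losses[[1]], 0L)
  expect_error(pretrainSdae(matrix(1, 0, 3), 2L, cfg), "nrow")
})

test_that("early stopping halts right after the patience runs out", {
  cfgSim <- simConfig(nRna = 30L, nProtein = 6L, nPositive = 40L,
                      rnaLengthRange = c(40L, 80L),
                      proteinLengthRange = c(40L, 80L), seed = 2L)
  dsBig <- simulateDataset(cfgSim, withStructures = FALSE)
  enc <- encodeDataset(dsBig, FALSE)
  # zero learning rates freeze the network, so validation loss is constant
  cfg <- tinyTrainConfig(seed = 2L, adamEpochs = 10L, sgdEpochs = 0L,
                         patience = 1L)
  cfg@adamLr <- 0
  m <- trainBranch("sdae", enc, cfg)
  expect_lte(nrow(m@history), 2L)
})

test_that("branch training recovers a planted signal and permuted labels do not", {
  cfgSim <- smallPlantedConfig(seed = 31L)
  ds <- simulateDataset(cfgSim, withStructures = FALSE)
  enc <- encodeDataset(ds, FALSE)
  y <- pairLabels(enc)
  set.seed(31)
  test <- sort(unlist(lapply(split(seq_along(y), y), sample, size = 40)))
  train <- setdiff(seq_along(y), test)
  cfg <- tinyTrainConfig(seed = 31L)
  for (type in c("sdae", "cnn")) {
    m <- trainBranch(type, enc[train], cfg)
    acc <- mean((predictProb(m, enc[test])[, "interact"] >= 0.5) == y[test])
    expect_gt(acc, 0.75)
  }
  # label permutation destroys the signal
  encPerm <- enc
  set.seed(32)
  encPerm@label <- sample(y)
  mP <- trainBranch("sdae", encPerm[train], cfg)
  accP <- mean((predictProb(mP, encPerm[test])[, "interact"] >= 0.5) ==
               pairLabels(encPerm)[test])
  expect_gt(accP, 0.3); expect_lt(accP, 0.7)
})

test_that("training is reproducible and rejects degenerate labels", {
  cfgSim <- simConfig(nRna = 30L, nProtein = 6L, nPositive = 40L,
                      rnaLengthRange = c(40L, 80L),
                      proteinLengthRange = c(40L, 80L), seed = 5L)
  ds <- simulateDataset(cfgSim, withStructures = FALSE)
  enc <- encodeDataset(ds, FALSE)
  cfg <- tinyTrainConfig(seed = 9L, adamEpochs = 4L, sgdEpochs = 1L)
  m1 <- trainBranch("sdae", enc, cfg)
  m2 <- trainBranch("sdae", enc, cfg)
  expect_identical(predictProb(m1, enc), predictProb(m2, enc))
  expect_identical(m1@history, m2@history)
  # single-class labels are refused
  encBad <- enc
  encBad@label <- rep(1L, nPairs(enc))
  expect_error(trainBranch("sdae", encBad, cfg), "single class")
  expect_error(trainEnsemble(enc[0], cfg), "no pairs")
})

test_that("predictions are softmax-normalized, deterministic and dim-checked", {
  cfgSim <- simConfig(nRna = 30L, nProtein = 6L, nPositive = 40L,
                      rnaLengthRange = c(40L, 80L),
                      proteinLengthRange = c(40L, 80L), seed = 6L)
  ds <- simulateDataset(cfgSim, withStructures = TRUE)
  encS <- encodeDataset(ds, TRUE)
  cfg <- tinyTrainConfig(seed = 6L, adamEpochs = 4L, sgdEpochs = 1L)
  m <- trainEnsemble(encS, cfg)
  P <- predictProb(m, encS)
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(unname(rowSums(P)), rep(1, nPairs(encS)), tolerance = 1e-6)
  expect_identical(P, predictProb(m, encS))
  # a structure-mode model must refuse sequence-only vectors
  encSeq <- encodeDataset(ds, FALSE)
  expect_error(predictProb(m, encSeq), "do not match")
  expect_error(predictProb(m@cnn, encSeq), "do not match")
})

test_that("the combiner follows two perfect identical branches", {
  set.seed(12)
  y <- rep(c(0, 1), each = 30)
  perfect <- cbind(1 - y, y)
  # soften so the combiner sees realistic probabilities
  soft <- perfect * 0.96 + 0.02
  P4 <- cbind(soft, soft)
  comb <- trainCombiner(P4, y, trainConfig(seed = 12L))
  ns <- asNamespace("plipred")
  pr <- ns$.softmaxRows(ns$.addBias(P4 %*% comb$W, comb$b))
  expect_identical(as.integer(pr[, 2] >= 0.5), as.integer(y))
})

test_that("the ensemble does not fall far behind its best branch", {
  cfgSim <- smallPlantedConfig(seed = 41L)
  ds <- simulateDataset(cfgSim, withStructures = FALSE)
  enc <- encodeDataset(ds, FALSE)
  y <- pairLabels(enc)
  set.seed(41)
  test <- sort(unlist(lapply(split(seq_along(y), y), sample, size = 40)))
  train <- setdiff(seq_along(y), test)
  m <- trainEnsemble(enc[train], tinyTrainConfig(seed = 41L))
  accOf <- function(mod) mean((predictProb(mod, enc[test])[, 2] >= 0.5) == y[test])
  accs <- c(sdae = accOf(m@sdae), cnn = accOf(m@cnn), ens = accOf(m))
  expect_gte(accs["ens"], max(accs["sdae"], accs["cnn"]) - 0.05)
})

test_that("models survive a save/load round trip", {
  cfgSim <- simConfig(nRna = 30L, nProtein = 6L, nPositive = 40L,
                      rnaLengthRange = c(40L, 80L),
                      proteinLengthRange = c(40L, 80L), seed = 13L)
  ds <- simulateDataset(cfgSim, withStructures = FALSE)
  enc <- encodeDataset(ds, FALSE)
  m <- trainBranch("sdae", enc, tinyTrainConfig(seed = 13L, adamEpochs = 3L,
                                                sgdEpochs = 0L))
  f <- tempfile(fileext = ".rds")
  modelSave(m, f)
  back <- modelLoad(f)
  expect_identical(predictProb(back, enc), predictProb(m, enc))
  expect_error(modelLoad(writeFastaFile(c(a = "ACGT"))))
})
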