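test_that("confusion counts follow the >= threshold rule", {
  expect_identical(confusionCounts(c(1, 0), c(0.9, 0.1)),
                   c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  expect_identical(confusionCounts(c(1, 0), c(0.1, 0.9)),
                   c(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  # a probability exactly at the threshold classifies positive
  expect_identical(confusionCounts(c(1), c(0.5))[["TP"]], 1L)
  expect_error(confusionCounts(numeric(0), numeric(0)), "empty")
})

test_that("metrics reproduce hand-computed values", {
  m <- classMetrics(c(TP = 3, TN = 2, FP = 1, FN = 1))
  expect_equal(m$acc, 5 / 7)
  expect_equal(m$pre, 0.75)
  expect_equal(m$sn, 0.75)
  expect_equal(m$sp, 2 / 3)
  expect_equal(m$mcc, 5 / 12)

  perfect <- classMetrics(c(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(acc = 1, pre = 1, sn = 1, sp = 1, mcc = 1))

  # an always-wrong classifier on balanced counts: accuracy 0, MCC -1
  deg <- classMetrics(c(TP = 0, TN = 0, FP = 5, FN = 5))
  expect_equal(deg$acc, 0)
  expect_equal(deg$mcc, -1)
  # zero margins make a metric undefined: NA sentinel, never silently 0
  noPos <- classMetrics(c(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(noPos$pre))
  expect_true(is.na(noPos$sn))
  expect_true(is.na(noPos$mcc))
})

test_that("metrics agree with an independent re-implementation on 1000 matrices", {
  set.seed(99)
  for (i in 1:1000) {
    cc <- stats::setNames(sample(0:40, 4, replace = TRUE),
                          c("TP", "TN", "FP", "FN"))
    if (sum(cc) == 0) cc["TP"] <- 1L
    m <- classMetrics(cc)
    tp <- cc[["TP"]]; tn <- cc[["TN"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]
    expect_identical(m$acc, (tp + tn) / (tp + tn + fp + fn))
    if (tp + fp > 0) expect_identical(m$pre, tp / (tp + fp)) else expect_true(is.na(m$pre))
    if (tp + fn > 0) expect_identical(m$sn, tp / (tp + fn)) else expect_true(is.na(m$sn))
    if (tn + fp > 0) expect_identical(m$sp, tn / (tn + fp)) else expect_true(is.na(m$sp))
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den > 0) {
      expect_equal(m$mcc, (tp * tn - fp * fn) / sqrt(den), tolerance = 1e-12)
      # MCC symmetry: swapping classes flips nothing but the sign structure
      sw <- classMetrics(c(TP = tn, TN = tp, FP = fn, FN = fp))
      expect_equal(abs(sw$mcc), abs(m$mcc), tolerance = 1e-12)
    }
  }
})

test_that("AUC matches the exhaustive pairwise oracle on all small inputs", {
  expect_equal(aucScore(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(aucScore(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(aucScore(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0)
  expect_error(aucScore(c(1, 1), c(0.5, 0.6)), "both classes")

  set.seed(5)
  grid <- seq(0.1, 0.9, by = 0.2)  # coarse grid forces ties
  for (n in 2:8) {
    labs <- expand.grid(rep(list(c(0, 1)), n))
    for (r in seq_len(nrow(labs))) {
      y <- as.numeric(labs[r, ])
      if (length(unique(y)) < 2) next
      p <- sample(grid, n, replace = TRUE)
      expect_equal(aucScore(y, p), pairwiseAuc(y, p), tolerance = 1e-12)
    }
  }
})

test_that("ROC points step from (0,0) to (1,1) and integrate to the AUC", {
  set.seed(14)
  y <- c(0, 1, rbinom(60, 1, 0.5))
  p <- round(runif(62), 1)
  r <- rocPoints(y, p)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[nrow(r)], r$tpr[nrow(r)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  # trapezoid area under the curve equals the rank-based AUC
  area <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
  expect_equal(area, aucScore(y, p), tolerance = 1e-12)
})

test_that("AUC agrees with pROC on a larger random case", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- rbinom(300, 1, 0.5)
  y[1:2] <- c(0, 1)
  p <- round(runif(300), 2)
  expect_equal(aucScore(y, p),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("stratified folds partition pairs and keep both classes", {
  sf <- getFromNamespace(".stratifiedFolds", "plipred")
  y <- rep(c(0, 1), each = 10)
  f <- sf(y, 5L, seed = 1L)
  expect_identical(sort(unique(f)), 1:5)
  expect_identical(as.integer(table(f)), rep(4L, 5))       # partition
  for (k in 1:5) expect_identical(sort(unique(y[f == k])), c(0, 1))
  # 2 folds on 4 balanced pairs -> two 2-pair folds
  f2 <- sf(c(0, 1, 0, 1), 2L, seed = 3L)
  expect_identical(as.integer(table(f2)), c(2L, 2L))
  expect_error(sf(c(0, 1, 0, 1), 5L, seed = 1L), "more folds")
  expect_error(sf(c(0, rep(1, 9)), 2L, seed = 1L), "too few pairs of class 0")
})

test_that("cross-validation recovers a planted signal on a small dataset", {
  cfg <- smallPlantedConfig(seed = 17L)
  ds <- simulateDataset(cfg, withStructures = FALSE)
  cv <- crossValidate(ds, tinyTrainConfig(seed = 17L), folds = 5L,
                      withStructure = FALSE, seed = 17L)
  expect_identical(nrow(cv$perFold), 15L)   # 5 folds x 3 models
  expect_identical(nrow(cv$mean), 3L)
  ensAcc <- cv$mean$acc[cv$mean$model == "ensemble"]
  expect_gt(ensAcc, 0.7)
  # every pair is tested exactly once
  expect_identical(nrow(cv$predictions), 400L)
  expect_false(anyDuplicated(paste(cv$predictions$rna_id,
                                   cv$predictions$protein_id)) > 0)
})

test_that("structure-only signal shows up in the ablation comparison", {
  structFeatures <- data.frame(
    molecule = c("rna", "rna", "protein", "protein"),
    block = "struct",
    kmer = c("pp", "uup", "HH", "EC"),
    coef = c(1, -1, 1, -1))
  cfg <- simConfig(nRna = 40L, nProtein = 8L, nPositive = 80L,
                   rnaLengthRange = c(50L, 150L),
                   proteinLengthRange = c(50L, 150L),
                   signalStrength = 12, signalFeatures = structFeatures,
                   seed = 23L)
  ds <- simulateDataset(cfg, withStructures = TRUE)
  ab <- ablationStructure(ds, tinyTrainConfig(seed = 23L), folds = 3L,
                          seed = 23L)
  expect_identical(ab$comparison$input, c("sequence", "sequence+structure"))
  # the signal lives in the structure blocks, so the structure row must win
  expect_gte(ab$comparison$acc[2], ab$comparison$acc[1])
  expect_gt(ab$comparison$acc[2], 0.65)
  expect_error(ablationStructure(tinyDataset(withStructures = FALSE)),
               "structure stores")
})
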