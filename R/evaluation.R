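# Binary-classification evaluation: confusion counts, the standard metric
# set (Acc, Pre, Sn, Sp, MCC), rank-based ROC AUC, stratified k-fold cross
# validation, and the sequence-vs-structure ablation experiment.

#' Confusion counts at a probability threshold
#'
#' A pair is called interacting when its class-1 probability is greater
#' than or equal to the threshold.
#'
#' @param labels 0/1 vector of reference labels.
#' @param probabilities class-1 probabilities, same length.
#' @param threshold decision threshold in (0, 1); ties classify positive.
#' @return named integer vector with elements TP, TN, FP, FN.
#' @export
confusionCounts <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(probabilities))
    stop("labels and probabilities differ in length")
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  pred <- as.integer(probabilities >= threshold)
  c(TP = sum(pred == 1L & labels == 1),
    TN = sum(pred == 0L & labels == 0),
    FP = sum(pred == 1L & labels == 0),
    FN = sum(pred == 0L & labels == 1))
}

#' Threshold metrics from confusion counts
#'
#' Computes accuracy (TP+TN)/total, precision TP/(TP+FP), sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP) and the Matthews correlation
#' coefficient (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is reported as NA — an explicit
#' "undefined" sentinel, never silently 0.
#'
#' @param counts named vector with TP, TN, FP, FN (see
#'   [confusionCounts()]).
#' @return one-row data.frame with columns acc, pre, sn, sp, mcc
#'   (fractions in `[0, 1]`, mcc in `[-1, 1]`).
#' @export
classMetrics <- function(counts) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
  tp <- as.numeric(counts["TP"]); tn <- as.numeric(counts["TN"])
  fp <- as.numeric(counts["FP"]); fn <- as.numeric(counts["FN"])
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
  tot <- tp + tn + fp + fn
  if (tot == 0) stop("all counts are zero")
  .ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  data.frame(acc = (tp + tn) / tot,
             pre = .ratio(tp, tp + fp),
             sn = .ratio(tp, tp + fn),
             sp = .ratio(tn, tn + fp),
             mcc = if (denom == 0) NA_real_
                   else (tp * tn - fp * fn) / sqrt(denom))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties handled by midranks, equal to
#' the probability that a random positive scores above a random negative
#' (ties counting one half).
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param probabilities class-1 scores.
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(labels, probabilities) {
  if (length(labels) != length(probabilities))
    stop("labels and probabilities differ in length")
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L)
    stop("AUC requires both classes to be present")
  r <- rank(probabilities)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' Computes the ROC operating points (one per distinct score, plus the
#' endpoints) for export or plotting; suitable for writing as TSV.
#'
#' @param labels 0/1 vector; both classes present.
#' @param probabilities class-1 scores.
#' @return data.frame with columns threshold, fpr, tpr, ordered from the
#'   (0, 0) to the (1, 1) corner.
#' @export
rocPoints <- function(labels, probabilities) {
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L) stop("both classes must be present")
  th <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  out <- lapply(th, function(t) {
    pred <- probabilities >= t
    data.frame(threshold = t,
               fpr = sum(pred & labels == 0) / nneg,
               tpr = sum(pred & labels == 1) / npos)
  })
  do.call(rbind, out)
}

#' Full metric report for one evaluation
#'
#' @param labels,probabilities,threshold see [confusionCounts()].
#' @return one-row data.frame acc/pre/sn/sp/mcc/auc, with the confusion
#'   counts attached as `attr(, "counts")`.
#' @export
metricReport <- function(labels, probabilities, threshold = 0.5) {
  counts <- confusionCounts(labels, probabilities, threshold)
  out <- classMetrics(counts)
  out$auc <- aucScore(labels, probabilities)
  attr(out, "counts") <- counts
  out
}

# Stratified fold assignment: within each class, a balanced random
# permutation of fold ids. Every sample lands in exactly one fold.
.stratifiedFolds <- function(y, k, seed) {
  if (k < 2L) stop("need at least 2 folds")
  if (k > length(y)) stop("more folds than pairs")
  set.seed(seed)
  f <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    if (length(i) < k)
      stop("too few pairs of class ", cl, " for ", k, "-fold stratification")
    f[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  f
}

#' Stratified k-fold cross-validation of the ensemble
#'
#' Pair-level stratified folds; a fresh ensemble (both branches plus
#' combiner) is trained per fold on the remaining pairs and evaluated on
#' the held-out fold. Metrics are reported per fold for the ensemble and
#' for each branch, plus the across-fold mean and standard deviation.
#' Seeded and reproducible.
#'
#' @param ds a labeled [PairedDataset-class].
#' @param cfg a [TrainConfig-class].
#' @param folds number of folds (>= 2).
#' @param withStructure encode with structure blocks?
#' @param seed RNG seed for the fold split; fold f trains with
#'   `cfg@seed + f`.
#' @param models which predictors to report.
#' @return list with `perFold` (data.frame: fold, model, metrics), `mean`
#'   and `sd` (per model), and `predictions` (per-pair held-out
#'   probabilities with fold ids).
#' @export
crossValidate <- function(ds, cfg = trainConfig(), folds = 5L,
                          withStructure = FALSE, seed = 1L,
                          models = c("ensemble", "sdae", "cnn")) {
  stopifnot(is(ds, "PairedDataset"))
  enc <- encodeDataset(ds, withStructure)
  y <- pairLabels(enc)
  if (anyNA(y)) stop("cross-validation requires labeled pairs")
  f <- .stratifiedFolds(y, folds, seed)
  rows <- list()
  preds <- list()
  for (fold in seq_len(folds)) {
    test <- which(f == fold)
    train <- which(f != fold)
    cfgF <- cfg
    cfgF@seed <- .subSeed(cfg@seed, 1000L + fold)
    model <- trainEnsemble(enc[train], cfgF)
    fits <- list(ensemble = model, sdae = model@sdae, cnn = model@cnn)
    for (m in models) {
      p1 <- predictProb(fits[[m]], enc[test])[, "interact"]
      mr <- metricReport(y[test], p1)
      rows[[length(rows) + 1L]] <- cbind(data.frame(fold = fold, model = m), mr)
      if (m == "ensemble")
        preds[[fold]] <- data.frame(rna_id = enc@rnaId[test],
                                    protein_id = enc@proteinId[test],
                                    label = y[test], p_interact = p1,
                                    fold = fold)
    }
  }
  perFold <- do.call(rbind, rows)
  metricCols <- c("acc", "pre", "sn", "sp", "mcc", "auc")
  agg <- function(fun) {
    out <- do.call(rbind, lapply(split(perFold, perFold$model), function(d)
      cbind(data.frame(model = d$model[1]),
            as.data.frame(lapply(d[metricCols], fun, na.rm = TRUE)))))
    out[match(models, out$model), , drop = FALSE]
  }
  list(perFold = perFold, mean = agg(mean), sd = agg(stats::sd),
       predictions = do.call(rbind, preds))
}

#' Sequence-only vs sequence+structure ablation
#'
#' Runs [crossValidate()] twice under identical fold assignments and
#' seeds, differing only in whether the structure blocks are included,
#' and reports the two mean metric rows side by side.
#'
#' @param ds a labeled [PairedDataset-class] with both structure stores.
#' @param cfg,folds,seed as in [crossValidate()].
#' @return list with `comparison` (two-row data.frame: input data x mean
#'   ensemble metrics) and the two full [crossValidate()] results.
#' @export
ablationStructure <- function(ds, cfg = trainConfig(), folds = 5L, seed = 1L) {
  if (!hasStructures(ds))
    stop("ablation requires RNA and protein structure stores")
  seqOnly <- crossValidate(ds, cfg, folds, withStructure = FALSE, seed = seed)
  withStr <- crossValidate(ds, cfg, folds, withStructure = TRUE, seed = seed)
  cmp <- rbind(cbind(data.frame(input = "sequence"),
                     seqOnly$mean[seqOnly$mean$model == "ensemble",
                                  -1, drop = FALSE]),
               cbind(data.frame(input = "sequence+structure"),
                     withStr$mean[withStr$mean$model == "ensemble",
                                  -1, drop = FALSE]))
  rownames(cmp) <- NULL
  list(comparison = cmp, sequenceOnly = seqOnly, withStructure = withStr)
}
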