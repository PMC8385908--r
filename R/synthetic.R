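# Synthetic paired datasets with the structural shape of the plant
# lncRNA-protein benchmarks (a small protein store, a larger RNA store,
# many-to-many pairings, balanced positives/negatives) and a tunable
# planted interaction signal, so that encoding, training and evaluation
# can be exercised end to end without any download.

#' SimConfig: synthetic-dataset parameters
#'
#' @slot nRna,nProtein store sizes (few proteins, many RNAs, mirroring the
#'   benchmark shape).
#' @slot nPositive number of interacting pairs; an equal number of
#'   non-interacting pairs is drawn, so `2*nPositive` must not exceed
#'   `nRna*nProtein`.
#' @slot rnaLengthRange,proteinLengthRange inclusive sequence-length
#'   ranges (uniformly sampled).
#' @slot signalStrength logistic coefficient scale of the planted rule;
#'   0 means pure noise (exchangeable labels).
#' @slot signalFeatures data.frame (molecule, block, kmer, coef) naming
#'   the encoder feature columns the planted rule reads; see
#'   [defaultSignalFeatures()].
#' @slot markov if TRUE, residues follow a sticky first-order Markov chain
#'   instead of being i.i.d. uniform.
#' @slot seed RNG seed.
#' @export
setClass("SimConfig",
  representation(nRna = "integer", nProtein = "integer",
                 nPositive = "integer",
                 rnaLengthRange = "integer", proteinLengthRange = "integer",
                 signalStrength = "numeric", signalFeatures = "data.frame",
                 markov = "logical", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nRna < 1L || object@nProtein < 1L)
      msg <- c(msg, "store sizes must be positive")
    if (object@nPositive < 1L)
      msg <- c(msg, "nPositive must be positive")
    if (2 * object@nPositive > object@nRna * object@nProtein)
      msg <- c(msg, "2*nPositive exceeds the number of possible pairings")
    for (s in c("rnaLengthRange", "proteinLengthRange")) {
      r <- slot(object, s)
      if (length(r) != 2L || r[1] < 1L || r[1] > r[2])
        msg <- c(msg, paste(s, "must be a positive ascending interval"))
    }
    if (object@signalStrength < 0)
      msg <- c(msg, "signalStrength must be >= 0")
    if (!all(c("molecule", "block", "kmer", "coef") %in%
             names(object@signalFeatures)))
      msg <- c(msg, "signalFeatures needs columns molecule, block, kmer, coef")
    if (length(msg)) msg else TRUE
  })

#' Default planted-signal features
#'
#' A fixed set of sequence k-mer columns, half on the RNA side, half on
#' the protein side (protein k-mers are written in the 7-group alphabet),
#' with alternating-sign unit coefficients.
#'
#' @return data.frame with columns molecule, block, kmer, coef.
#' @export
defaultSignalFeatures <- function() {
  data.frame(
    molecule = c("rna", "rna", "rna", "rna",
                 "protein", "protein", "protein", "protein"),
    block = "seq",
    kmer = c("GCA", "TTC", "GCGA", "AAC", "125", "463", "72", "516"),
    coef = c(1, -1, 1, -1, 1, -1, 1, -1))
}

#' @param nRna,nProtein,nPositive,rnaLengthRange,proteinLengthRange see
#'   slots.
#' @param signalStrength,signalFeatures,markov,seed see slots.
#' @rdname SimConfig-class
#' @export
simConfig <- function(nRna = 200L, nProtein = 20L, nPositive = 400L,
                      rnaLengthRange = c(50L, 500L),
                      proteinLengthRange = c(50L, 500L),
                      signalStrength = 8,
                      signalFeatures = defaultSignalFeatures(),
                      markov = FALSE, seed = 1L) {
  new("SimConfig", nRna = as.integer(nRna), nProtein = as.integer(nProtein),
      nPositive = as.integer(nPositive),
      rnaLengthRange = as.integer(rnaLengthRange),
      proteinLengthRange = as.integer(proteinLengthRange),
      signalStrength = signalStrength, signalFeatures = signalFeatures,
      markov = as.logical(markov), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d RNAs x %d proteins, %d+%d pairs, signal %.1f, seed %d\n",
              object@nRna, object@nProtein, object@nPositive,
              object@nPositive, object@signalStrength, object@seed))
})

.randomResidues <- function(n, lengthRange, alphabet, markov) {
  rng <- seq.int(lengthRange[1], lengthRange[2])
  lens <- rng[sample.int(length(rng), n, replace = TRUE)]
  vapply(lens, function(L) {
    if (!markov) {
      paste(sample(alphabet, L, replace = TRUE), collapse = "")
    } else {
      # sticky chain: repeat the previous residue w.p. 0.4, else uniform
      x <- character(L)
      x[1] <- sample(alphabet, 1L)
      if (L > 1) for (i in 2:L)
        x[i] <- if (stats::runif(1) < 0.4) x[i - 1L] else sample(alphabet, 1L)
      paste(x, collapse = "")
    }
  }, character(1))
}

#' Generate the sequence stores of a synthetic dataset
#'
#' Draws `nRna` RNA and `nProtein` protein sequences with i.i.d. uniform
#' residues (or a sticky first-order chain with `markov = TRUE`) at
#' uniformly sampled lengths. Deterministic given the config seed. The
#' returned dataset has empty pair and structure stores; see
#' [genStructures()] and [plantLabels()].
#'
#' @param cfg a [SimConfig-class].
#' @return a [PairedDataset-class] skeleton.
#' @export
genSequences <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(.subSeed(cfg@seed, 41L))
  rna <- .randomResidues(cfg@nRna, cfg@rnaLengthRange, .RNA_BASES, cfg@markov)
  names(rna) <- sprintf("RNA_%04d", seq_len(cfg@nRna))
  protein <- .randomResidues(cfg@nProtein, cfg@proteinLengthRange,
                             .PROTEIN_AA, cfg@markov)
  names(protein) <- sprintf("PROT_%03d", seq_len(cfg@nProtein))
  pairedDataset(rna, protein)
}

# One well-formed dot-bracket string: a left-to-right walk that opens,
# closes (only when something is open) or stays unpaired, with closes
# forced when the remaining positions are needed to balance.
.randDotBracket <- function(L) {
  out <- character(L)
  open <- 0L
  for (i in seq_len(L)) {
    remaining <- L - i + 1L
    if (open >= remaining) {
      ch <- ")"
    } else {
      r <- stats::runif(1)
      canOpen <- remaining - 1L > open
      ch <- if (canOpen && r < 0.3) "("
            else if (open > 0L && r < 0.55) ")"
            else "."
    }
    if (ch == "(") open <- open + 1L
    if (ch == ")") open <- open - 1L
    out[i] <- ch
  }
  paste(out, collapse = "")
}

# H/E/C runs with geometric lengths (mean 5)
.randHec <- function(L) {
  out <- character(0)
  while (length(out) < L) {
    state <- sample(.PROTEIN_STRUCT_CHARS, 1L)
    out <- c(out, rep(state, stats::rgeom(1L, 0.2) + 1L))
  }
  paste(out[seq_len(L)], collapse = "")
}

#' Attach synthetic secondary structures
#'
#' RNA structures are well-formed dot-bracket strings (every `)` matches
#' an earlier `(`) from a stochastic walk; protein structures are random
#' H/E/C runs with geometric run lengths. Both match their sequence
#' lengths exactly. This emulates the *format* of thermodynamic folding
#' and three-state structure predictors, not their physics.
#'
#' @param ds a [PairedDataset-class].
#' @param seed RNG seed.
#' @return the dataset with both structure stores filled.
#' @export
genStructures <- function(ds, seed = 1L) {
  stopifnot(is(ds, "PairedDataset"))
  set.seed(.subSeed(seed, 42L))
  rs <- vapply(rnaSeqs(ds), function(s) .randDotBracket(nchar(s)), character(1))
  ps <- vapply(proteinSeqs(ds), function(s) .randHec(nchar(s)), character(1))
  pairedDataset(rnaSeqs(ds), proteinSeqs(ds), interactionPairs(ds),
                rnaStruct = rs, proteinStruct = ps)
}

# Standardized planted-feature contributions of every store entry.
# Returns list(u = per-RNA contribution, v = per-protein contribution);
# the pair score is u[r] + v[p], scaled by 1/sqrt(#features).
.plantedContributions <- function(ds, cfg) {
  sf <- cfg@signalFeatures
  needStruct <- any(sf$block == "struct")
  if (needStruct && !hasStructures(ds))
    stop("signal features reference structure blocks but the dataset has no structures")
  .contrib <- function(molecule, seqs, structs) {
    rows <- sf[sf$molecule == molecule, , drop = FALSE]
    out <- numeric(length(seqs))
    names(out) <- names(seqs)
    if (nrow(rows) == 0L) return(out)
    M <- .encodeStore(names(seqs), seqs, structs, molecule, needStruct)
    cols <- paste0(rows$block, "_", rows$kmer)
    bad <- setdiff(cols, colnames(M))
    if (length(bad))
      stop("unknown signal feature column(s): ", paste(bad, collapse = ", "))
    for (j in seq_along(cols)) {
      x <- M[, cols[j]]
      s <- stats::sd(x)
      if (s > 0) out <- out + rows$coef[j] * (x - mean(x)) / s
    }
    out
  }
  list(u = .contrib("rna", rnaSeqs(ds), rnaStructures(ds)),
       v = .contrib("protein", proteinSeqs(ds), proteinStructures(ds)))
}

#' Planted interaction scores and probabilities
#'
#' Recomputes the planted rule for every possible (RNA, protein) pairing:
#' the score is the coefficient-weighted sum of the standardized planted
#' k-mer features of the two molecules; the interaction probability is
#' `plogis(signalStrength * (score - s0))` where the offset `s0` is the
#' `1 - nPositive/(nRna*nProtein)` quantile of the scores, so that
#' high-probability pairings are about as abundant as positives. At
#' `signalStrength = 0` every probability is 0.5.
#'
#' @param ds a [PairedDataset-class] holding the stores the rule reads.
#' @param cfg the [SimConfig-class] that defines the rule.
#' @return data.frame over all pairings: rna_id, protein_id, score, prob.
#' @export
plantedScores <- function(ds, cfg) {
  uv <- .plantedContributions(ds, cfg)
  grid <- expand.grid(rna_id = names(uv$u), protein_id = names(uv$v),
                      stringsAsFactors = FALSE)
  score <- uv$u[grid$rna_id] + uv$v[grid$protein_id]
  s0 <- stats::quantile(score, 1 - cfg@nPositive / length(score), names = FALSE)
  data.frame(grid, score = unname(score),
             prob = stats::plogis(cfg@signalStrength * (score - s0)))
}

#' Plant balanced interaction labels
#'
#' Draws `nPositive` positive pairs without replacement, weighted by the
#' planted interaction probability, and an equal number of negative pairs
#' uniformly from the remaining (non-positive) pairings — mirroring the
#' random-pairing negative construction of the benchmark datasets. With
#' `signalStrength = 0` the labels are exchangeable.
#'
#' @param ds a [PairedDataset-class] with sequence (and, if the rule needs
#'   them, structure) stores.
#' @param cfg a [SimConfig-class].
#' @return the dataset with a shuffled balanced pair table.
#' @export
plantLabels <- function(ds, cfg) {
  stopifnot(is(ds, "PairedDataset"), is(cfg, "SimConfig"))
  all <- plantedScores(ds, cfg)
  n <- nrow(all)
  if (2 * cfg@nPositive > n)
    stop("nPositive too large for the available pairings")
  set.seed(.subSeed(cfg@seed, 43L))
  pos <- sample(n, cfg@nPositive, prob = all$prob)
  neg <- sample(setdiff(seq_len(n), pos), cfg@nPositive)
  pairs <- rbind(data.frame(rna_id = all$rna_id[pos],
                            protein_id = all$protein_id[pos], label = 1L),
                 data.frame(rna_id = all$rna_id[neg],
                            protein_id = all$protein_id[neg], label = 0L))
  pairs <- pairs[sample(nrow(pairs)), , drop = FALSE]
  rownames(pairs) <- NULL
  pairedDataset(rnaSeqs(ds), proteinSeqs(ds), pairs,
                rnaStruct = rnaStructures(ds),
                proteinStruct = proteinStructures(ds))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [genSequences()], then [genStructures()] (optional)
#' and [plantLabels()].
#'
#' @param cfg a [SimConfig-class].
#' @param withStructures attach synthetic structure stores?
#' @return a labeled [PairedDataset-class].
#' @export
simulateDataset <- function(cfg = simConfig(), withStructures = TRUE) {
  ds <- genSequences(cfg)
  if (withStructures) ds <- genStructures(ds, cfg@seed)
  plantLabels(ds, cfg)
}

#' Accuracy of the planted-rule oracle
#'
#' Recomputes the true planted probabilities for a labeled dataset and
#' classifies each pair by `prob >= 0.5`. This is the (near-)Bayes
#' reference: a trained model cannot systematically beat it, and at
#' `signalStrength = 0` it scores 0.5 on balanced labels.
#'
#' @param ds a labeled [PairedDataset-class] generated under `cfg`.
#' @param cfg the generating [SimConfig-class].
#' @return accuracy in `[0, 1]`.
#' @export
oracleAccuracy <- function(ds, cfg) {
  all <- plantedScores(ds, cfg)
  key <- paste(all$rna_id, all$protein_id, sep = "\r")
  p <- interactionPairs(ds)
  if (anyNA(p$label)) stop("oracleAccuracy requires labeled pairs")
  prob <- all$prob[match(paste(p$rna_id, p$protein_id, sep = "\r"), key)]
  mean(as.integer(prob >= 0.5) == p$label)
}
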