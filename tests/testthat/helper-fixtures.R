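# Shared fixture builders; everything is generated in code at test time.

# a tiny hand-written dataset with known composition
tinyDataset <- function(withStructures = TRUE) {
  rna <- c(r1 = "ACGTACGTACGTACGTACGT",
           r2 = "GGGGCCCCAAAATTTTACGT",
           r3 = "ATATATATATGCGCGCGCGC")
  protein <- c(p1 = "MKVLAWGRETCYHNQDSIFP",
               p2 = "CCCCCCCCCCWWWWWWWWWW")
  pairs <- data.frame(rna_id = c("r1", "r2", "r3", "r1"),
                      protein_id = c("p1", "p1", "p2", "p2"),
                      label = c(1L, 0L, 1L, 0L))
  if (!withStructures)
    return(pairedDataset(rna, protein, pairs))
  rs <- c(r1 = "..((((......))))....",
          r2 = "(((...)))...((...)).",
          r3 = "....................")
  ps <- c(p1 = "HHHHEEEECCCCHHHHEECC",
          p2 = "CCCCCCCCCCEEEEEEEEEE")
  pairedDataset(rna, protein, pairs, rnaStruct = rs, proteinStruct = ps)
}

# small planted-signal dataset (400 balanced pairs) for fast model tests
smallPlantedConfig <- function(seed = 7L, signalStrength = 10) {
  simConfig(nRna = 100L, nProtein = 10L, nPositive = 200L,
            rnaLengthRange = c(50L, 200L), proteinLengthRange = c(50L, 200L),
            signalStrength = signalStrength, seed = seed)
}

# lightweight architecture so model tests stay fast; the higher learning
# rate suits the narrow layers
tinyTrainConfig <- function(seed = 5L, ...) {
  kw <- list(adamEpochs = 30L, sgdEpochs = 5L, adamLr = 3e-3, sgdLr = 3e-4,
             pretrainEpochs = 3L, sdaeWidths = c(64L, 32L, 16L),
             headWidths = c(32L, 16L), cnnFilters = c(8L, 6L, 4L),
             batchSize = 32L, patience = 8L, seed = seed)
  over <- list(...)
  kw[names(over)] <- over
  do.call(trainConfig, kw)
}

# write a FASTA-framed file from a named character vector
writeFastaFile <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# independent sliding-window k-mer counter (enumerate-and-count oracle)
naiveKmerFrequencies <- function(residues, symbols, kMin, kMax) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  L <- length(chars)
  unlist(lapply(kMin:kMax, function(k) {
    kmers <- symbols
    if (k > 1) for (i in 2:k)
      kmers <- as.vector(vapply(kmers, function(p) paste0(p, symbols),
                                character(length(symbols))))
    if (L < k) return(numeric(length(kmers)))
    windows <- vapply(seq_len(L - k + 1L),
                      function(i) paste(chars[i:(i + k - 1L)], collapse = ""),
                      character(1))
    as.numeric(table(factor(windows, levels = kmers))) / (L - k + 1L)
  }), use.names = FALSE)
}

# brute-force AUC over all positive/negative pairs (Mann-Whitney oracle)
pairwiseAuc <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
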