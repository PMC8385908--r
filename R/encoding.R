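# Fixed-length k-mer featurization.
#
# RNA sequences: k = 1..4 over {A,C,G,T}  -> 4+16+64+256 = 340 features.
# Protein sequences: reduced to 7 physicochemical groups, k = 1..3
#   -> 7+49+343 = 399 features.
# RNA structure (dot-bracket collapsed to unpaired/paired): k = 1..4 over
#   2 symbols -> 2+4+8+16 = 30 features, appended after the sequence
#   blocks (total 370).
# Protein structure (H/E/C): k = 1..3 over 3 symbols -> 3+9+27 = 39
#   features, appended (total 438).
# Every k-block is normalized by its window count L - k + 1, so it is the
# empirical k-mer distribution of that sequence.

.encoderParts <- function(molecule) {
  if (molecule == "rna")
    list(seq = list(red = rnaReduction(), spec = kmerSpec(4L, 1L, 4L)),
         struct = list(red = rnaStructureReduction(), spec = kmerSpec(2L, 1L, 4L)))
  else
    list(seq = list(red = proteinReduction(), spec = kmerSpec(7L, 1L, 3L)),
         struct = list(red = proteinStructureReduction(), spec = kmerSpec(3L, 1L, 3L)))
}

#' Feature-vector block layout
#'
#' Describes the block structure of the encoded vectors: one row per
#' (block, k) segment in vector order, with the block length and the
#' 1-based column offset. Column names (`attr(, "colnames")`) combine the
#' block with the k-mer string, e.g. `seq_GCA` or `struct_up`.
#'
#' @param molecule `"rna"` or `"protein"`.
#' @param withStructure include the structure blocks?
#' @return data.frame with columns block, k, length, offset; total vector
#'   length as `attr(, "totalLength")`, column names as
#'   `attr(, "colnames")`.
#' @examples
#' sum(featureLayout("rna", TRUE)$length)       # 370
#' sum(featureLayout("protein", FALSE)$length)  # 399
#' @export
featureLayout <- function(molecule = c("rna", "protein"), withStructure = FALSE) {
  molecule <- match.arg(molecule)
  parts <- .encoderParts(molecule)
  use <- if (withStructure) c("seq", "struct") else "seq"
  rows <- list()
  nms <- character(0)
  off <- 1L
  for (b in use) {
    spec <- parts[[b]]$spec
    symbols <- parts[[b]]$red@symbols
    for (k in spec@kMin:spec@kMax) {
      len <- as.integer(spec@alphabetSize^k)
      rows[[length(rows) + 1L]] <-
        data.frame(block = b, k = k, length = len, offset = off)
      nms <- c(nms, paste0(b, "_", .kmerStrings(symbols, k)))
      off <- off + len
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "totalLength") <- off - 1L
  attr(out, "colnames") <- nms
  out
}

.encodeOne <- function(residues, structure, molecule, withStructure) {
  parts <- .encoderParts(molecule)
  v <- kmerFrequencies(reduceSequence(residues, parts$seq$red), parts$seq$spec)
  if (withStructure) {
    if (is.null(structure))
      stop("structure string required when withStructure = TRUE")
    if (nchar(structure) != nchar(residues))
      stop(sprintf("structure length (%d) differs from sequence length (%d)",
                   nchar(structure), nchar(residues)))
    v <- c(v, kmerFrequencies(reduceSequence(structure, parts$struct$red),
                              parts$struct$spec))
  }
  names(v) <- attr(featureLayout(molecule, withStructure), "colnames")
  v
}

#' Encode one RNA or protein into its k-mer feature vector
#'
#' `encodeRNA()` produces a 340-dimensional vector from the sequence
#' alone, or 370 dimensions with the dot-bracket structure blocks
#' appended. `encodeProtein()` produces 399 or, with the H/E/C structure
#' blocks, 438 dimensions.
#'
#' @param residues residue string (RNA is expected canonicalized to
#'   A/C/G/T, as produced by [readFasta()]).
#' @param structure optional structure string of the same length.
#' @param withStructure append the structure blocks? Defaults to whether a
#'   structure was given.
#' @return named numeric feature vector.
#' @examples
#' length(encodeRNA("ACGTACGT"))                # 340
#' length(encodeRNA("ACGTACGT", "..((..))"))    # 370
#' @export
encodeRNA <- function(residues, structure = NULL,
                      withStructure = !is.null(structure)) {
  .encodeOne(residues, structure, "rna", withStructure)
}

#' @rdname encodeRNA
#' @export
encodeProtein <- function(residues, structure = NULL,
                          withStructure = !is.null(structure)) {
  .encodeOne(residues, structure, "protein", withStructure)
}

# Encode every id of one store into a feature matrix (rows = ids)
.encodeStore <- function(ids, seqs, structs, molecule, withStructure) {
  layout <- featureLayout(molecule, withStructure)
  out <- matrix(NA_real_, length(ids), attr(layout, "totalLength"),
                dimnames = list(ids, attr(layout, "colnames")))
  for (id in ids) {
    out[id, ] <- tryCatch(
      .encodeOne(seqs[[id]], if (withStructure) structs[[id]] else NULL,
                 molecule, withStructure),
      error = function(e) stop(sprintf("encoding '%s': %s", id,
                                       conditionMessage(e)), call. = FALSE))
  }
  out
}

#' Encode every interaction pair of a dataset
#'
#' Encodes each distinct RNA and protein referenced by the pair table once
#' and assembles per-pair feature matrices in pair order. Deterministic:
#' identical inputs give bit-identical matrices.
#'
#' @param ds a [PairedDataset-class].
#' @param withStructure append structure blocks (requires both structure
#'   stores).
#' @return an [EncodedPairs-class].
#' @export
encodeDataset <- function(ds, withStructure = FALSE) {
  stopifnot(is(ds, "PairedDataset"))
  pairs <- interactionPairs(ds)
  if (nrow(pairs) == 0L) stop("dataset has no pairs to encode")
  if (withStructure && !hasStructures(ds))
    stop("withStructure = TRUE but the dataset has no structure stores")
  rids <- unique(pairs$rna_id)
  pids <- unique(pairs$protein_id)
  Mr <- .encodeStore(rids, rnaSeqs(ds), rnaStructures(ds), "rna", withStructure)
  Mp <- .encodeStore(pids, proteinSeqs(ds), proteinStructures(ds), "protein",
                     withStructure)
  new("EncodedPairs",
      rna = Mr[pairs$rna_id, , drop = FALSE],
      protein = Mp[pairs$protein_id, , drop = FALSE],
      rnaId = pairs$rna_id, proteinId = pairs$protein_id,
      label = as.integer(pairs$label), withStructure = withStructure)
}
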