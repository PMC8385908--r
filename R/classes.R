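#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' PairedDataset: sequence/structure stores plus interaction pairs
#'
#' Central data container: named character stores for RNA and protein
#' sequences, optional parallel structure stores keyed by the same ids
#' (dot-bracket for RNA, H/E/C for protein), and a pair table with columns
#' `rna_id`, `protein_id` and `label` (0 = non-interacting,
#' 1 = interacting, NA = unlabeled / prediction mode).
#'
#' @slot rna,protein named character vectors of residue strings.
#' @slot rnaStruct,proteinStruct optional named character vectors; when
#'   present, each structure string has the same length as its sequence.
#' @slot pairs data.frame with columns rna_id, protein_id, label.
#' @export
setClass("PairedDataset",
  representation(rna = "character", protein = "character",
                 rnaStruct = "characterOrNULL",
                 proteinStruct = "characterOrNULL",
                 pairs = "data.frame"),
  validity = function(object) {
    msg <- character()
    .checkStore <- function(store, what) {
      if (length(store) && (is.null(names(store)) || any(!nzchar(names(store)))))
        msg <<- c(msg, paste(what, "store must be named"))
      if (anyDuplicated(names(store)))
        msg <<- c(msg, paste("duplicate ids in", what, "store"))
      if (length(store) && any(grepl("\\s", names(store))))
        msg <<- c(msg, paste(what, "ids must not contain whitespace"))
      if (length(store) && any(!nzchar(store)))
        msg <<- c(msg, paste("empty residue string in", what, "store"))
    }
    .checkStore(object@rna, "rna")
    .checkStore(object@protein, "protein")
    .checkStruct <- function(struct, seqs, what) {
      if (is.null(struct)) return()
      miss <- setdiff(names(struct), names(seqs))
      if (length(miss))
        msg <<- c(msg, paste0(what, " structure ids missing from sequence store: ",
                              paste(utils::head(miss, 3), collapse = ", ")))
      common <- intersect(names(struct), names(seqs))
      bad <- common[nchar(struct[common]) != nchar(seqs[common])]
      if (length(bad))
        msg <<- c(msg, paste0(what, " structure length differs from sequence for: ",
                              paste(utils::head(bad, 3), collapse = ", ")))
    }
    .checkStruct(object@rnaStruct, object@rna, "rna")
    .checkStruct(object@proteinStruct, object@protein, "protein")
    p <- object@pairs
    if (nrow(p)) {
      if (!all(c("rna_id", "protein_id", "label") %in% names(p)))
        msg <- c(msg, "pairs must have columns rna_id, protein_id, label")
      else {
        if (anyDuplicated(paste(p$rna_id, p$protein_id, sep = "\r")))
          msg <- c(msg, "duplicate (rna_id, protein_id) pairs")
        if (!all(p$rna_id %in% names(object@rna)))
          msg <- c(msg, "pair rna_id not found in rna store")
        if (!all(p$protein_id %in% names(object@protein)))
          msg <- c(msg, "pair protein_id not found in protein store")
        lab <- p$label
        if (!all(is.na(lab) | lab %in% c(0L, 1L)))
          msg <- c(msg, "labels must be 0, 1 or NA")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a PairedDataset
#'
#' @param rna,protein named character vectors (id -> residue string).
#' @param pairs data.frame with columns rna_id, protein_id and optionally
#'   label; a missing label column becomes NA (prediction mode).
#' @param rnaStruct,proteinStruct optional named character structure stores.
#' @return a validated [PairedDataset-class].
#' @export
pairedDataset <- function(rna, protein,
                          pairs = data.frame(rna_id = character(),
                                             protein_id = character(),
                                             label = integer()),
                          rnaStruct = NULL, proteinStruct = NULL) {
  pairs <- as.data.frame(pairs)
  if (!"label" %in% names(pairs)) pairs$label <- NA_integer_
  pairs$label <- as.integer(pairs$label)
  pairs$rna_id <- as.character(pairs$rna_id)
  pairs$protein_id <- as.character(pairs$protein_id)
  new("PairedDataset", rna = rna, protein = protein,
      rnaStruct = rnaStruct, proteinStruct = proteinStruct,
      pairs = pairs[, c("rna_id", "protein_id", "label")])
}

#' Accessors for PairedDataset
#'
#' @param object a [PairedDataset-class].
#' @return the requested store or table.
#' @export
rnaSeqs <- function(object) object@rna

#' @rdname rnaSeqs
#' @export
proteinSeqs <- function(object) object@protein

#' @rdname rnaSeqs
#' @export
rnaStructures <- function(object) object@rnaStruct

#' @rdname rnaSeqs
#' @export
proteinStructures <- function(object) object@proteinStruct

#' @rdname rnaSeqs
#' @export
interactionPairs <- function(object) object@pairs

#' @rdname rnaSeqs
#' @export
hasStructures <- function(object) {
  !is.null(object@rnaStruct) && !is.null(object@proteinStruct)
}

setMethod("show", "PairedDataset", function(object) {
  cat("PairedDataset\n")
  cat(sprintf("  RNA store:     %d sequences (length %s)\n",
              length(object@rna),
              if (length(object@rna))
                paste(range(nchar(object@rna)), collapse = "-") else "-"))
  cat(sprintf("  protein store: %d sequences (length %s)\n",
              length(object@protein),
              if (length(object@protein))
                paste(range(nchar(object@protein)), collapse = "-") else "-"))
  cat(sprintf("  structures:    %s\n",
              if (hasStructures(object)) "RNA + protein" else "none"))
  lab <- object@pairs$label
  cat(sprintf("  pairs:         %d (%d positive, %d negative, %d unlabeled)\n",
              nrow(object@pairs), sum(lab == 1L, na.rm = TRUE),
              sum(lab == 0L, na.rm = TRUE), sum(is.na(lab))))
})

#' EncodedPairs: k-mer feature matrices for interaction pairs
#'
#' One row per interaction pair. The RNA matrix has 340 columns
#' (sequence-only mode) or 370 (with structure blocks appended); the
#' protein matrix 399 or 438.
#'
#' @slot rna,protein numeric feature matrices, one row per pair.
#' @slot rnaId,proteinId pair identifiers, parallel to the rows.
#' @slot label integer 0/1 labels (NA when unlabeled).
#' @slot withStructure whether structure blocks are included.
#' @export
setClass("EncodedPairs",
  representation(rna = "matrix", protein = "matrix",
                 rnaId = "character", proteinId = "character",
                 label = "integer", withStructure = "logical"),
  validity = function(object) {
    n <- nrow(object@rna)
    if (nrow(object@protein) != n || length(object@label) != n ||
        length(object@rnaId) != n || length(object@proteinId) != n)
      return("row/label/id counts disagree")
    dims <- if (object@withStructure) c(370L, 438L) else c(340L, 399L)
    if (ncol(object@rna) != dims[1])
      return(sprintf("RNA matrix must have %d columns in this mode", dims[1]))
    if (ncol(object@protein) != dims[2])
      return(sprintf("protein matrix must have %d columns in this mode", dims[2]))
    TRUE
  })

#' @param object an EncodedPairs.
#' @rdname EncodedPairs-class
#' @export
nPairs <- function(object) nrow(object@rna)

#' @param which `"rna"` or `"protein"`.
#' @rdname EncodedPairs-class
#' @export
featureMatrix <- function(object, which = c("rna", "protein")) {
  which <- match.arg(which)
  slot(object, which)
}

#' @rdname EncodedPairs-class
#' @export
pairLabels <- function(object) object@label

setMethod("show", "EncodedPairs", function(object) {
  cat(sprintf("EncodedPairs: %d pairs, RNA %d-dim, protein %d-dim (%s)\n",
              nPairs(object), ncol(object@rna), ncol(object@protein),
              if (object@withStructure) "sequence + structure"
              else "sequence only"))
})

#' @param x an EncodedPairs.
#' @param i row (pair) index.
#' @param j,drop,... ignored.
#' @rdname EncodedPairs-class
#' @export
setMethod("[", "EncodedPairs", function(x, i, j, ..., drop = FALSE) {
  new("EncodedPairs",
      rna = x@rna[i, , drop = FALSE], protein = x@protein[i, , drop = FALSE],
      rnaId = x@rnaId[i], proteinId = x@proteinId[i],
      label = x@label[i], withStructure = x@withStructure)
})
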