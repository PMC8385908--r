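# Residue alphabets used throughout the package. RNA is canonicalized to
# DNA letters (U -> T) on input, so the k-mer alphabet is A < C < G < T.
.RNA_BASES <- c("A", "C", "G", "T")
.PROTEIN_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.RNA_STRUCT_CHARS <- c(".", "(", ")")
.PROTEIN_STRUCT_CHARS <- c("H", "E", "C")

# Physicochemical 7-group partition of the 20 amino acids
# (conjoint-triad-style):
#   1 {V,G,A}  2 {F,P,L,I}  3 {S,Y,M,T}  4 {H,N,W,Q}  5 {R,K}  6 {E,D}  7 {C}
.PROTEIN_GROUPS <- list(
  c("V", "G", "A"),
  c("F", "P", "L", "I"),
  c("S", "Y", "M", "T"),
  c("H", "N", "W", "Q"),
  c("R", "K"),
  c("E", "D"),
  c("C")
)

#' AlphabetReduction class
#'
#' Maps a source residue alphabet onto a (usually smaller) contiguous set of
#' group indices, e.g. the seven physicochemical amino-acid groups used for
#' protein k-mer features, or the collapse of dot-bracket RNA structure
#' characters onto unpaired/paired. Group indices start at 0.
#'
#' @slot name identifier of the reduction.
#' @slot map named integer vector; names are source residues, values are
#'   0-based group indices.
#' @slot nGroups number of groups (size of the reduced alphabet).
#' @slot symbols one display symbol per group, in group order; used to name
#'   k-mer feature columns.
#' @export
setClass("AlphabetReduction",
  representation(name = "character", map = "integer",
                 nGroups = "integer", symbols = "character"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@map)) || anyNA(object@map))
      msg <- c(msg, "map must be a named integer vector without NA")
    u <- sort(unique(object@map))
    if (!identical(u, seq_len(object@nGroups) - 1L))
      msg <- c(msg, "group indices must be contiguous from 0")
    if (length(object@symbols) != object@nGroups)
      msg <- c(msg, "need one symbol per group")
    if (length(msg)) msg else TRUE
  })

.makeReduction <- function(name, residues, groups, symbols) {
  map <- integer(0)
  for (g in seq_along(groups))
    map[groups[[g]]] <- g - 1L
  map <- map[residues]
  names(map) <- residues
  new("AlphabetReduction", name = name, map = map,
      nGroups = length(groups), symbols = symbols)
}

#' Built-in alphabet reductions
#'
#' `rnaReduction()` is the identity map over A/C/G/T; `proteinReduction()`
#' maps the 20 amino acids onto the seven physicochemical groups;
#' `rnaStructureReduction()` collapses dot-bracket characters onto
#' unpaired ("u") vs paired ("p"); `proteinStructureReduction()` is the
#' identity over the three-state H/E/C alphabet.
#'
#' @return An [AlphabetReduction-class] object.
#' @examples
#' reduceSequence("VGAC", proteinReduction())  # 0 0 0 6
#' @export
rnaReduction <- function() {
  .makeReduction("rna", .RNA_BASES,
                 as.list(.RNA_BASES), .RNA_BASES)
}

#' @rdname rnaReduction
#' @export
proteinReduction <- function() {
  .makeReduction("protein", .PROTEIN_AA, .PROTEIN_GROUPS,
                 as.character(seq_len(7)))
}

#' @rdname rnaReduction
#' @export
rnaStructureReduction <- function() {
  .makeReduction("rna_structure", .RNA_STRUCT_CHARS,
                 list(".", c("(", ")")), c("u", "p"))
}

#' @rdname rnaReduction
#' @export
proteinStructureReduction <- function() {
  .makeReduction("protein_structure", .PROTEIN_STRUCT_CHARS,
                 as.list(.PROTEIN_STRUCT_CHARS), .PROTEIN_STRUCT_CHARS)
}

#' Reduce a residue string to group indices
#'
#' Replaces each residue by the 0-based index of its group under the given
#' reduction. The result has the same length as the input.
#'
#' @param residues single character string.
#' @param reduction an [AlphabetReduction-class].
#' @return integer vector of group indices (0-based).
#' @export
reduceSequence <- function(residues, reduction) {
  stopifnot(is(reduction, "AlphabetReduction"))
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("'residues' must be a single character string")
  if (!nzchar(residues)) stop("empty residue string")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- match(chars, names(reduction@map))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("residue '%s' at position %d is not in the '%s' alphabet",
                 chars[bad], bad, reduction@name))
  }
  unname(reduction@map[idx])
}
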