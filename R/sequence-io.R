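# Reading and validating FASTA sequences, structure strings (FASTA
# framing), pair-label tables (headerless TSV, CSV by extension), and
# feature-matrix text files. Parsing goes through Biostrings and
# data.table; validation (alphabets, ids, duplicates) is done here.

.readFastaRaw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("malformed FASTA in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  seqs <- as.character(set)
  # id = first whitespace-delimited token of the header
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("FASTA entry with empty id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  names(seqs) <- ids
  seqs
}

.validateAlphabet <- function(seqs, allowed, what, dropInvalid = FALSE) {
  pat <- paste0("[^", paste(gsub("([.()])", "\\\\\\1", allowed), collapse = ""),
                "]")
  bad <- grepl(pat, seqs)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    if (!dropInvalid)
      stop(sprintf("empty sequence for record '%s'", names(seqs)[empty][1]))
    bad <- bad | empty
  }
  if (any(bad) && !dropInvalid) {
    id <- names(seqs)[bad][1]
    pos <- regexpr(pat, seqs[bad][1])
    stop(sprintf("record '%s': character '%s' at position %d is not a valid %s residue",
                 id, substr(seqs[bad][1], pos, pos), pos, what))
  }
  if (any(bad)) {
    warning(sprintf("dropped %d record(s) with residues outside the %s alphabet",
                    sum(bad), what))
    seqs <- seqs[!bad]
  }
  seqs
}

#' Read sequences from FASTA
#'
#' Reads a FASTA file into a named character vector (id -> residues). RNA
#' sequences are canonicalized on input: lowercase is raised and U is
#' mapped to T, so the downstream k-mer alphabet is always A/C/G/T.
#' Residues outside the declared alphabet (ambiguity codes such as N or X
#' included) are an error unless `dropAmbiguous = TRUE`, which discards
#' the offending records with a warning.
#'
#' @param path FASTA file.
#' @param alphabet `"rna"` or `"protein"`.
#' @param dropAmbiguous drop invalid records instead of failing.
#' @return named character vector of validated residue strings.
#' @export
readFasta <- function(path, alphabet = c("rna", "protein"),
                      dropAmbiguous = FALSE) {
  alphabet <- match.arg(alphabet)
  seqs <- .readFastaRaw(path)
  if (length(seqs) == 0L) return(stats::setNames(character(0), character(0)))
  seqs <- stats::setNames(toupper(seqs), names(seqs))
  if (alphabet == "rna") {
    seqs <- stats::setNames(chartr("U", "T", seqs), names(seqs))
    .validateAlphabet(seqs, .RNA_BASES, "RNA", dropAmbiguous)
  } else {
    .validateAlphabet(seqs, .PROTEIN_AA, "protein", dropAmbiguous)
  }
}

#' Read secondary-structure strings
#'
#' Structure strings reuse FASTA framing: one record per molecule, keyed
#' by the same ids as the sequence file. RNA structures are dot-bracket
#' strings over `.`, `(`, `)` (other bracket dialects are rejected);
#' parentheses are not required to balance. Protein structures are
#' three-state strings over H (helix), E (sheet), C (coil).
#'
#' @param path file with FASTA-framed structure strings.
#' @param kind `"rna"` or `"protein"`.
#' @return named character vector of structure strings.
#' @export
readStructures <- function(path, kind = c("rna", "protein")) {
  kind <- match.arg(kind)
  seqs <- .readFastaRaw(path)
  if (length(seqs) == 0L) return(stats::setNames(character(0), character(0)))
  if (kind == "rna")
    .validateAlphabet(seqs, .RNA_STRUCT_CHARS, "RNA structure")
  else
    .validateAlphabet(toupper(seqs), .PROTEIN_STRUCT_CHARS, "protein structure")
}

#' Read an interaction-pair table
#'
#' Headerless two- or three-column table: rna_id, protein_id and an
#' optional 0/1 label. Tab-separated by default; comma-separated when the
#' file ends in `.csv`. Pairs without a label (prediction mode) get NA.
#'
#' @param path pair file.
#' @return data.frame with columns rna_id, protein_id, label.
#' @export
readPairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::fread(path, header = FALSE, sep = sep,
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 2L || ncol(dt) > 3L)
    stop("pair file must have 2 or 3 columns (rna_id, protein_id[, label])")
  out <- data.frame(rna_id = dt[[1]], protein_id = dt[[2]],
                    label = NA_integer_)
  if (ncol(dt) == 3L) {
    lab <- dt[[3]]
    ok <- lab %in% c("0", "1")
    if (any(!ok))
      stop("unknown label token '", lab[!ok][1], "' (labels must be 0 or 1)")
    out$label <- as.integer(lab)
  }
  key <- paste(out$rna_id, out$protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- out[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate pair (%s, %s)", d$rna_id, d$protein_id))
  }
  out
}

#' Assemble a PairedDataset from files
#'
#' @param rnaPath,proteinPath FASTA sequence files.
#' @param pairsPath pair table, see [readPairs()].
#' @param rnaStructPath,proteinStructPath optional structure files, see
#'   [readStructures()].
#' @param dropAmbiguous passed to [readFasta()]; pairs referencing dropped
#'   records are removed.
#' @return a validated [PairedDataset-class].
#' @export
readPairedDataset <- function(rnaPath, proteinPath, pairsPath,
                              rnaStructPath = NULL, proteinStructPath = NULL,
                              dropAmbiguous = FALSE) {
  rna <- readFasta(rnaPath, "rna", dropAmbiguous)
  protein <- readFasta(proteinPath, "protein", dropAmbiguous)
  pairs <- readPairs(pairsPath)
  if (dropAmbiguous) {
    keep <- pairs$rna_id %in% names(rna) & pairs$protein_id %in% names(protein)
    if (!all(keep)) {
      warning(sprintf("dropped %d pair(s) referencing removed records",
                      sum(!keep)))
      pairs <- pairs[keep, , drop = FALSE]
    }
  }
  rs <- if (!is.null(rnaStructPath)) readStructures(rnaStructPath, "rna")
  ps <- if (!is.null(proteinStructPath))
    readStructures(proteinStructPath, "protein")
  pairedDataset(rna, protein, pairs, rnaStruct = rs, proteinStruct = ps)
}

#' Write / read a feature matrix as delimited text
#'
#' Tab-separated with a header row; the first column `id` carries the
#' row identifiers, the remaining columns the feature layout (see
#' [featureLayout()]). Round-trips losslessly at serialization precision.
#'
#' @param x numeric matrix with row and column names, or a list of
#'   equal-length named feature vectors.
#' @param path output file.
#' @export
writeFeatureMatrix <- function(x, path) {
  if (is.list(x) && !is.data.frame(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) > 1L)
      stop("inconsistent feature-vector lengths: ",
           paste(unique(lens), collapse = ", "))
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("v", seq_along(x))
    x <- do.call(rbind, x)
    rownames(x) <- ids
  }
  stopifnot(is.matrix(x))
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(x)))
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  dt <- data.table::data.table(id = ids)
  if (nrow(x) == 0L) {
    # header-only file
    writeLines(paste(c("id", cn), collapse = "\t"), path)
    return(invisible(path))
  }
  dt <- cbind(dt, data.table::as.data.table(x))
  data.table::setnames(dt, c("id", cn))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @return `readFeatureMatrix()`: the numeric matrix, ids as rownames.
#' @export
readFeatureMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Write a PairedDataset to standard files
#'
#' Emits `rna.fasta`, `protein.fasta`, `pairs.tsv` and, when structures
#' are present, `rna_structure.fasta` / `protein_structure.fasta` into a
#' directory, in the formats consumed by [readPairedDataset()].
#'
#' @param ds a [PairedDataset-class].
#' @param dir output directory (created if missing).
#' @return named character vector of the files written.
#' @export
writeDatasetFiles <- function(ds, dir) {
  stopifnot(is(ds, "PairedDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeFasta <- function(seqs, path) {
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
    path
  }
  files <- c(rna = .writeFasta(rnaSeqs(ds), file.path(dir, "rna.fasta")),
             protein = .writeFasta(proteinSeqs(ds),
                                   file.path(dir, "protein.fasta")))
  if (!is.null(rnaStructures(ds)))
    files["rnaStruct"] <- .writeFasta(rnaStructures(ds),
                                      file.path(dir, "rna_structure.fasta"))
  if (!is.null(proteinStructures(ds)))
    files["proteinStruct"] <-
      .writeFasta(proteinStructures(ds),
                  file.path(dir, "protein_structure.fasta"))
  p <- interactionPairs(ds)
  pp <- file.path(dir, "pairs.tsv")
  if (all(is.na(p$label))) p <- p[, c("rna_id", "protein_id")]
  data.table::fwrite(p, pp, sep = "\t", col.names = FALSE)
  files["pairs"] <- pp
  files
}
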