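#' KmerSpec class
#'
#' Describes a multi-scale k-mer feature block: an alphabet size and an
#' inclusive range of k values. The resulting feature vector concatenates,
#' for k = kMin..kMax, one block of `alphabetSize^k` normalized k-mer
#' frequencies in lexicographic k-mer order.
#'
#' @slot alphabetSize size of the (possibly reduced) residue alphabet.
#' @slot kMin,kMax inclusive k range, 1 <= kMin <= kMax.
#' @export
setClass("KmerSpec",
  representation(alphabetSize = "integer", kMin = "integer", kMax = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@alphabetSize < 2L)
      msg <- c(msg, "alphabetSize must be >= 2")
    if (object@kMin < 1L || object@kMin > object@kMax)
      msg <- c(msg, "need 1 <= kMin <= kMax")
    if (length(msg)) msg else TRUE
  })

#' @param alphabetSize,kMin,kMax see slots.
#' @rdname KmerSpec-class
#' @export
kmerSpec <- function(alphabetSize, kMin = 1L, kMax) {
  new("KmerSpec", alphabetSize = as.integer(alphabetSize),
      kMin = as.integer(kMin), kMax = as.integer(kMax))
}

#' @param spec a [KmerSpec-class].
#' @return `kmerSpecLength()`: total feature-vector length,
#'   `sum(alphabetSize^(kMin:kMax))`.
#' @rdname KmerSpec-class
#' @export
kmerSpecLength <- function(spec) {
  as.integer(sum(spec@alphabetSize^(spec@kMin:spec@kMax)))
}

# All k-mer strings over `symbols` for one k, ordered so that the last
# position varies fastest -- i.e. ascending lexicographic order, matching
# the positional index used by kmerFrequencies().
.kmerStrings <- function(symbols, k) {
  out <- symbols
  if (k > 1) for (i in 2:k)
    out <- as.vector(vapply(out, function(p) paste0(p, symbols),
                            character(length(symbols))))
  out
}

#' K-mer feature column names
#'
#' @param spec a [KmerSpec-class].
#' @param symbols display symbols of the (reduced) alphabet, in alphabet
#'   order.
#' @return character vector of length `kmerSpecLength(spec)`.
#' @export
kmerNames <- function(spec, symbols) {
  stopifnot(length(symbols) == spec@alphabetSize)
  unlist(lapply(spec@kMin:spec@kMax, function(k) .kmerStrings(symbols, k)),
         use.names = FALSE)
}

#' Normalized k-mer frequency vector
#'
#' Counts every k-mer (sliding window, step 1) for each k in the spec's
#' range and normalizes each k-block by its number of windows, L - k + 1,
#' so that every block with L >= k is an empirical probability distribution
#' summing to 1. Blocks with L < k are all-zero. Blocks are concatenated in
#' increasing k; within a block, k-mers are in lexicographic order.
#'
#' @param groups integer vector of 0-based group indices, e.g. from
#'   [reduceSequence()].
#' @param spec a [KmerSpec-class] whose `alphabetSize` matches the coding.
#' @return numeric vector of length `kmerSpecLength(spec)`.
#' @examples
#' v <- kmerFrequencies(reduceSequence("ACGT", rnaReduction()), kmerSpec(4, 1, 2))
#' sum(v[1:4])  # the 1-mer block sums to 1
#' @export
kmerFrequencies <- function(groups, spec) {
  stopifnot(is(spec, "KmerSpec"))
  L <- length(groups)
  if (L == 0L) stop("cannot compute k-mer frequencies of an empty sequence")
  if (any(groups < 0L | groups >= spec@alphabetSize))
    stop("group index outside the declared alphabet size")
  A <- spec@alphabetSize
  blocks <- lapply(spec@kMin:spec@kMax, function(k) {
    if (L < k) return(numeric(A^k))
    nw <- L - k + 1L
    idx <- groups[seq_len(nw)]
    if (k > 1) for (j in 2:k)
      idx <- idx * A + groups[seq.int(j, j + nw - 1L)]
    tabulate(idx + 1L, nbins = A^k) / nw
  })
  unlist(blocks, use.names = FALSE)
}
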