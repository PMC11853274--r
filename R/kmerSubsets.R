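## k-mer vocabulary enumeration and XY1/XY0 subset partitioning.
##
## The 4^k k-mers are ordered lexicographically (A < C < G < T) and indexed
## by rank 0..4^k-1; rank digits base 4 are the bases, most significant
## first. All membership computations work on this integer representation,
## so string scanning can serve as an independent oracle in tests.

## base-4 digit matrix of all ranks 0..4^k-1; column j = j-th base (0..3)
kmerDigits <- function(k) {
  n <- 4L^k
  d <- matrix(0L, nrow = n, ncol = k)
  r <- 0:(n - 1L)
  for (j in k:1) {
    d[, j] <- r %% 4L
    r <- r %/% 4L
  }
  d
}

#' Enumerate the k-mer vocabulary
#'
#' All DNA words of length \code{k} over A, C, G, T in lexicographic order
#' (rank 0 is the all-A word, rank \code{4^k - 1} the all-T word).
#'
#' @param k integer word length, between 1 and 12.
#' @return character vector of length \code{4^k}.
#' @examples
#' enumerateKmers(1)
#' length(enumerateKmers(6))  # 4096
#' @export
enumerateKmers <- function(k) {
  k <- checkK(k)
  d <- kmerDigits(k)
  out <- DNA_BASES[d[, 1] + 1L]
  if (k > 1L) for (j in 2:k) out <- paste0(out, DNA_BASES[d[, j] + 1L])
  out
}

checkK <- function(k, min = 1L) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k) ||
      k < min || k > 12)
    stop("invalid parameter: k must be an integer in [", min, ", 12]",
         call. = FALSE)
  as.integer(k)
}

#' Test dinucleotide containment
#'
#' Does a k-mer contain the dinucleotide XY as a contiguous substring?
#' Containment is orientation-specific (X immediately followed by Y on the
#' given strand) and overlapping occurrences count.
#'
#' @param kmer character vector of DNA words (A/C/G/T only).
#' @param pattern two-character dinucleotide, e.g. \code{"AG"}.
#' @return logical vector, one element per input word.
#' @examples
#' containsPattern("AAGTCC", "AG")  # TRUE
#' containsPattern("ACGTCA", "AG")  # FALSE
#' @export
containsPattern <- function(kmer, pattern) {
  checkPattern(pattern)
  stopIfNotBases(kmer, "k-mer")
  x <- substr(pattern, 1L, 1L)
  y <- substr(pattern, 2L, 2L)
  lens <- nchar(kmer)
  out <- logical(length(kmer))
  for (j in seq_len(max(c(lens, 1L)) - 1L)) {
    live <- lens > j
    out[live] <- out[live] |
      (substr(kmer[live], j, j) == x & substr(kmer[live], j + 1L, j + 1L) == y)
  }
  out
}

## membership of every rank 0..4^k-1 in the XY1 subset, via digit arithmetic
patternMembershipByRank <- function(k, pattern) {
  checkPattern(pattern)
  d <- kmerDigits(k)
  xi <- match(substr(pattern, 1, 1), DNA_BASES) - 1L
  yi <- match(substr(pattern, 2, 2), DNA_BASES) - 1L
  member <- logical(4L^k)
  for (j in seq_len(k - 1L))
    member <- member | (d[, j] == xi & d[, j + 1L] == yi)
  member
}

#' Partition the vocabulary by dinucleotide containment
#'
#' Splits the rank space 0..4^k-1 into the XY1 subset (k-mers containing the
#' dinucleotide) and its complement XY0. For k = 6 the sizes are 1185/2911
#' when X != Y and 991/3105 when X = Y.
#'
#' @param k word length, at least 2.
#' @param pattern two-character dinucleotide.
#' @return list with integer rank vectors \code{xy1} and \code{xy0}
#'   (0-based, lexicographic rank).
#' @examples
#' lengths(partitionByPattern(6, "AG"))  # 1185, 2911
#' lengths(partitionByPattern(6, "AA"))  # 991, 3105
#' @export
partitionByPattern <- function(k, pattern) {
  k <- checkK(k, min = 2L)
  member <- patternMembershipByRank(k, pattern)
  r <- 0:(4L^k - 1L)
  list(xy1 = r[member], xy0 = r[!member])
}

#' Closed-form count of pattern-avoiding k-mers
#'
#' Number of k-mers over a 4-letter alphabet that avoid a fixed dinucleotide,
#' by linear recurrence: a_n = 4 a_(n-1) - a_(n-2) when the two bases differ,
#' a_n = 3 a_(n-1) + 3 a_(n-2) when the pattern is a homodinucleotide
#' (self-overlapping), with a_0 = 1 and a_1 = 4. Serves as an independent
#' oracle for the enumerated XY0 subset sizes (2911 and 3105 at k = 6).
#'
#' @param k word length (>= 0).
#' @param selfOverlapping logical; TRUE for X = Y patterns.
#' @return integer count of avoiding words.
#' @examples
#' avoidanceCount(6, FALSE)  # 2911
#' avoidanceCount(6, TRUE)   # 3105
#' @export
avoidanceCount <- function(k, selfOverlapping) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k) || k < 0)
    stop("invalid parameter: k must be a non-negative integer", call. = FALSE)
  stopifnot(is.logical(selfOverlapping), length(selfOverlapping) == 1L)
  if (k == 0) return(1L)
  if (k == 1) return(4L)
  a <- c(1, 4)
  for (n in 2:k) {
    nxt <- if (selfOverlapping) 3 * a[2] + 3 * a[1] else 4 * a[2] - a[1]
    a <- c(a[2], nxt)
  }
  as.integer(a[2])
}

#' Build the full 16-pattern subset partition
#'
#' Computes XY1 membership of every k-mer for all 16 dinucleotides.
#'
#' @param k word length (default 6).
#' @return a [KmerPartition-class] object.
#' @examples
#' part <- kmerPartition(6)
#' subsetSizes(part)
#' @export
kmerPartition <- function(k = 6L) {
  k <- checkK(k, min = 2L)
  pats <- allDinucleotides()
  m <- vapply(pats, function(p) patternMembershipByRank(k, p),
              logical(4L^k))
  colnames(m) <- pats
  new("KmerPartition", k = k, kmers = enumerateKmers(k), membership = m)
}

#' @describeIn kmerPartition word length of a partition.
#' @param x a \code{KmerPartition}.
#' @export
setMethod("kmerSize", "KmerPartition", function(x) x@k)

#' @describeIn kmerPartition the ordered k-mer vocabulary.
#' @export
setMethod("kmerNames", "KmerPartition", function(x) x@kmers)

#' @describeIn kmerPartition 0-based ranks of one subset;
#'   \code{class} is \code{"XY1"} or \code{"XY0"}.
#' @param pattern dinucleotide label.
#' @param class subset class, \code{"XY1"} (default) or \code{"XY0"}.
#' @export
setMethod("subsetMembers", "KmerPartition",
  function(x, pattern, class = c("XY1", "XY0")) {
    class <- match.arg(class)
    checkPattern(pattern)
    if (!pattern %in% colnames(x@membership))
      stop("unknown pattern: ", pattern, call. = FALSE)
    inset <- x@membership[, pattern]
    if (class == "XY0") inset <- !inset
    which(inset) - 1L
  })

#' @describeIn kmerPartition matrix of XY1 and XY0 sizes per dinucleotide.
#' @export
setMethod("subsetSizes", "KmerPartition", function(x) {
  n1 <- colSums(x@membership)
  cbind(XY1 = n1, XY0 = nrow(x@membership) - n1)
})

setMethod("show", "KmerPartition", function(object) {
  cat("KmerPartition: k =", object@k, "(", length(object@kmers),
      "k-mers ), 16 dinucleotide subsets\n")
  sz <- subsetSizes(object)
  homo <- paste0(DNA_BASES, DNA_BASES)
  cat("  XY1 sizes:",
      unique(sz[setdiff(rownames(sz), homo), "XY1"])[1], "(X != Y) /",
      unique(sz[homo, "XY1"])[1], "(X = Y)\n")
})

#' Export a subset partition as TSV
#'
#' Writes one row per k-mer with its rank and 16 columns of 0/1 XY1
#' membership flags named \code{AA1}..\code{TT1}.
#'
#' @param partition a [KmerPartition-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePartition <- function(partition, path) {
  stopifnot(is(partition, "KmerPartition"))
  m <- partition@membership * 1L
  colnames(m) <- paste0(colnames(m), "1")
  df <- data.frame(kmer = partition@kmers,
                   rank = seq_along(partition@kmers) - 1L, m,
                   check.names = FALSE)
  writeTSV(df, path)
}
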