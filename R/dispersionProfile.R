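## Positional 6-mer counting and the dispersion statistic.
##
## At every start site the 4096 6-mer counts across N aligned windows form a
## frequency distribution; the dispersion of a subset is the ratio of the
## subset's population standard deviation to that of the full vocabulary.
## Counts and frequencies give the same ratio, so sigma is computed on
## counts.

## integer base codes (0..3) for a window set, N x 100
windowBaseCodes <- function(windows) {
  m <- as.matrix(windows@sequences)
  codes <- match(m, DNA_BASES) - 1L
  if (anyNA(codes))
    stop("invalid sequence: non-ACGT base in windows", call. = FALSE)
  matrix(codes, nrow = nrow(m), ncol = ncol(m))
}

#' Count k-mers by start site across aligned windows
#'
#' Slides a k-base window with 1-base step over every 100-base acceptor
#' window and tabulates, for each of the 95 start sites (k = 6; labels
#' -50..-1, +1..+45, a k-mer indexed by its first base), how many of the N
#' sequences carry each k-mer there. Every site's counts sum to N.
#'
#' @param windows an [AcceptorWindowSet-class].
#' @param k word length (default 6).
#' @return a [PositionalKmerMatrix-class].
#' @examples
#' w <- newAcceptorWindowSet(
#'   Biostrings::DNAStringSet(strrep("A", 100)),
#'   S4Vectors::DataFrame(event_id = "e1", mode = "common"))
#' pkm <- countKmersBySite(w)
#' all(kmerCounts(pkm)[, 1] == 1)  # AAAAAA everywhere
#' @export
countKmersBySite <- function(windows, k = 6L) {
  stopifnot(is(windows, "AcceptorWindowSet"))
  k <- checkK(k, min = 1L)
  n <- nWindows(windows)
  if (n < 1L) stop("need at least one window", call. = FALSE)
  codes <- windowBaseCodes(windows)
  nSites <- ncol(codes) - k + 1L
  counts <- matrix(0L, nrow = nSites, ncol = 4L^k)
  for (s in seq_len(nSites)) {
    r <- codes[, s]
    for (j in seq_len(k - 1L)) r <- r * 4L + codes[, s + j]
    counts[s, ] <- tabulate(r + 1L, nbins = 4L^k)
  }
  labels <- offsetToLabel(seq_len(nSites) - 1L)
  dimnames(counts) <- list(labels, NULL)
  new("PositionalKmerMatrix", counts = counts,
      siteLabels = labels, nSequences = n, k = k)
}

#' @describeIn countKmersBySite the site x k-mer count matrix.
#' @param x a \code{PositionalKmerMatrix}.
#' @export
setMethod("kmerCounts", "PositionalKmerMatrix", function(x) x@counts)

#' @describeIn countKmersBySite number of windows counted.
#' @export
setMethod("nSequences", "PositionalKmerMatrix", function(x) x@nSequences)

#' @describeIn countKmersBySite zero-skipping start-site labels.
#' @export
setMethod("siteLabels", "PositionalKmerMatrix", function(x) x@siteLabels)

#' @describeIn countKmersBySite word length.
#' @export
setMethod("kmerSize", "PositionalKmerMatrix", function(x) x@k)

setMethod("show", "PositionalKmerMatrix", function(object) {
  cat("PositionalKmerMatrix:", nrow(object@counts), "sites x",
      ncol(object@counts), "k-mers, N =", object@nSequences, "\n")
})

#' Standard deviation of a k-mer subset's count distribution
#'
#' Population (divide-by-n) standard deviation of the counts of the member
#' k-mers about the member mean. Computed on counts; dividing by N to get
#' frequencies rescales both numerator and denominator of the dispersion
#' ratio identically, so the ratio is unchanged.
#'
#' @param counts numeric vector of per-k-mer counts at one site.
#' @param members integer vector of 0-based member ranks (defaults to the
#'   full vocabulary).
#' @return the population standard deviation.
#' @examples
#' subsetSigma(c(1, 2, 3, 4))            # sqrt(1.25)
#' subsetSigma(c(1, 2, 3, 4), c(0, 3))   # 1.5
#' @export
subsetSigma <- function(counts, members = seq_along(counts) - 1L) {
  if (length(members) < 1L)
    stop("invalid parameter: empty member set", call. = FALSE)
  if (any(members < 0L | members >= length(counts)))
    stop("invalid parameter: member rank out of range", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  popSd(counts[members + 1L])
}

#' Dispersion of a k-mer subset
#'
#' The ratio rho = sigma_members / sigma_total of the subset's population
#' standard deviation to that of the full count vector. rho < 1 flags
#' conservative (narrower than background) usage of the subset, rho > 1
#' more random usage; the full vocabulary has rho = 1 by construction.
#'
#' @inheritParams subsetSigma
#' @return the dispersion value.
#' @examples
#' dispersion(c(1, 2, 3, 4), c(0, 3))  # 1.5 / sqrt(1.25)
#' @export
dispersion <- function(counts, members) {
  sTot <- subsetSigma(counts)
  if (sTot == 0)
    stop("degenerate distribution: total standard deviation is zero",
         call. = FALSE)
  subsetSigma(counts, members) / sTot
}

#' Dispersion profile across all sites, patterns and subset classes
#'
#' Computes rho for every start site, each of the 16 dinucleotide patterns
#' and both subset classes (XY1 and XY0), as a tidy table.
#'
#' @param pkm a [PositionalKmerMatrix-class].
#' @param partition a [KmerPartition-class] with matching k.
#' @return a [DispersionProfile-class]; its table has columns site, pattern,
#'   subset_class, rho, sigma_subset, sigma_total.
#' @export
dispersionProfile <- function(pkm, partition = kmerPartition(kmerSize(pkm))) {
  stopifnot(is(pkm, "PositionalKmerMatrix"), is(partition, "KmerPartition"))
  if (kmerSize(partition) != kmerSize(pkm))
    stop("partition and matrix disagree on k", call. = FALSE)
  C <- pkm@counts          # sites x 4096
  M <- partition@membership * 1  # 4096 x 16
  nV <- ncol(C)
  n1 <- colSums(M)
  n0 <- nV - n1

  rowM <- rowMeans(C)
  rowM2 <- rowMeans(C^2)
  sTot <- sqrt(pmax(rowM2 - rowM^2, 0))
  if (any(sTot == 0))
    stop("degenerate distribution: zero total standard deviation at site(s) ",
         paste(pkm@siteLabels[sTot == 0], collapse = ", "), call. = FALSE)

  S1 <- C %*% M            # sites x 16 member sums
  S2 <- C^2 %*% M
  mu1 <- sweep(S1, 2L, n1, "/")
  sig1 <- sqrt(pmax(sweep(S2, 2L, n1, "/") - mu1^2, 0))
  mu0 <- sweep(nV * rowM - S1, 2L, n0, "/")
  sig0 <- sqrt(pmax(sweep(nV * rowM2 - S2, 2L, n0, "/") - mu0^2, 0))

  pats <- colnames(partition@membership)
  long <- function(sig, cls)
    data.frame(site = rep(pkm@siteLabels, times = length(pats)),
               pattern = rep(pats, each = nrow(C)),
               subset_class = cls,
               rho = as.vector(sig) / rep(sTot, times = length(pats)),
               sigma_subset = as.vector(sig),
               sigma_total = rep(sTot, times = length(pats)))
  tab <- rbind(long(sig1, "XY1"), long(sig0, "XY0"))
  rownames(tab) <- NULL
  new("DispersionProfile", table = tab, nSequences = pkm@nSequences)
}

#' @describeIn dispersionProfile the tidy per-site dispersion table.
#' @param x a \code{DispersionProfile}.
#' @export
setMethod("profileTable", "DispersionProfile", function(x) x@table)

#' @describeIn dispersionProfile number of windows profiled.
#' @export
setMethod("nSequences", "DispersionProfile", function(x) x@nSequences)

#' @describeIn dispersionProfile sorted unique site labels in the profile.
#' @export
setMethod("siteLabels", "DispersionProfile",
          function(x) sort(unique(x@table$site)))

setMethod("show", "DispersionProfile", function(object) {
  cat("DispersionProfile:", length(unique(object@table$site)), "sites x",
      length(unique(object@table$pattern)), "patterns x 2 classes, N =",
      object@nSequences, "\n")
})

#' Write a dispersion profile as tidy TSV
#'
#' Columns site, pattern, subset_class, rho, sigma_subset, sigma_total,
#' n_sequences.
#'
#' @param profile a [DispersionProfile-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProfileTable <- function(profile, path) {
  stopifnot(is(profile, "DispersionProfile"))
  writeTSV(cbind(profile@table, n_sequences = profile@nSequences), path)
}
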