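#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' KmerPartition: XY1/XY0 membership of every k-mer
#'
#' Partition of the full k-mer vocabulary (lexicographic order, A < C < G < T)
#' into, for each of the 16 dinucleotides XY, the XY1 subset (k-mers
#' containing XY as a contiguous substring) and its complement XY0.
#'
#' @slot k integer word length.
#' @slot kmers character vector of length \code{4^k}, lexicographic.
#' @slot membership logical matrix, \code{4^k} rows (k-mers) by 16 columns
#'   (dinucleotides \code{AA}..\code{TT}); \code{TRUE} means the k-mer
#'   belongs to the XY1 subset of that column's dinucleotide.
#'
#' @seealso [kmerPartition()], [subsetMembers()], [subsetSizes()]
#' @export
setClass("KmerPartition",
  representation(k = "integer", kmers = "character", membership = "matrix"))

setValidity("KmerPartition", function(object) {
  n <- length(object@kmers)
  if (n != 4L^object@k) return("length(kmers) must be 4^k")
  if (!is.logical(object@membership)) return("membership must be logical")
  if (nrow(object@membership) != n || ncol(object@membership) != 16L)
    return("membership must be 4^k x 16")
  TRUE
})

#' SpliceGraph: bipartite donor-acceptor pairing structure
#'
#' Deduplicated donor and acceptor splice sites and the edges (introns)
#' joining them, built from canonical GT-AG splice events. Sites are keyed by
#' (chrom, strand, position), where position is the genomic coordinate of the
#' terminal intronic base (G of GT for donors, G of AG for acceptors),
#' 1-based.
#'
#' @slot donors data.frame with columns chrom, strand, pos, degree.
#' @slot acceptors data.frame with columns chrom, strand, pos, degree.
#' @slot edges data.frame with columns donor (row index into donors),
#'   acceptor (row index into acceptors), n_transcripts, transcript_ids.
#'
#' @seealso [buildSpliceGraph()], [classifyAcceptors()]
#' @export
setClass("SpliceGraph",
  representation(donors = "data.frame", acceptors = "data.frame",
                 edges = "data.frame"))

setValidity("SpliceGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e$donor < 1L | e$donor > nrow(object@donors)))
      return("edge refers to unknown donor")
    if (any(e$acceptor < 1L | e$acceptor > nrow(object@acceptors)))
      return("edge refers to unknown acceptor")
  }
  TRUE
})

#' AcceptorWindowSet: aligned 100-base acceptor windows
#'
#' A set of 100-base sequences in transcription orientation, aligned on the
#' splice junction, with the zero-skipping site convention: base labels
#' -50..-1 then +1..+50 (no 0), the junction falling between labels -1 and
#' +1. For canonical sites the bases at labels -2/-1 are A and G.
#'
#' @slot sequences a [Biostrings::DNAStringSet] of equal width 100.
#' @slot info a [S4Vectors::DataFrame] with one row per window; columns
#'   include event_id, mode, submode and ag_ok (logical AG check at -2/-1).
#'
#' @seealso [extractWindows()], [generateWindows()], [countKmersBySite()]
#' @export
setClass("AcceptorWindowSet",
  representation(sequences = "DNAStringSet", info = "DataFrame"))

setValidity("AcceptorWindowSet", function(object) {
  w <- Biostrings::width(object@sequences)
  if (length(w) && any(w != 100L)) return("all windows must be 100 bases")
  if (nrow(object@info) != length(object@sequences))
    return("info must have one row per sequence")
  TRUE
})

#' PositionalKmerMatrix: per-site 6-mer occurrence counts
#'
#' Counts of each k-mer starting at each site across a set of aligned
#' 100-base windows. With k = 6 a window yields 95 start sites, labelled
#' -50..-1, +1..+45 (zero-skipping; a k-mer is indexed by its first base).
#'
#' @slot counts integer matrix, sites (rows, 95 for k = 6) by k-mers
#'   (columns, lexicographic).
#' @slot siteLabels integer vector of zero-skipping start-site labels.
#' @slot nSequences number of windows counted.
#' @slot k word length.
#'
#' @seealso [countKmersBySite()], [dispersionProfile()]
#' @export
setClass("PositionalKmerMatrix",
  representation(counts = "matrix", siteLabels = "integer",
                 nSequences = "integer", k = "integer"))

setValidity("PositionalKmerMatrix", function(object) {
  if (nrow(object@counts) != length(object@siteLabels))
    return("one row of counts per site label")
  if (ncol(object@counts) != 4L^object@k)
    return("counts must have 4^k columns")
  rs <- rowSums(object@counts)
  if (length(rs) && any(rs != object@nSequences))
    return("counts at every site must sum to nSequences")
  TRUE
})

#' DispersionProfile: per-site dispersion of every XY subset
#'
#' For every start site, dinucleotide pattern XY and subset class (XY1/XY0),
#' the dispersion rho = sigma_subset / sigma_total, where sigma is the
#' population standard deviation of the per-k-mer counts at that site
#' (equivalently of frequencies; the scale cancels in the ratio).
#' rho < 1 flags conservative (narrow) usage of the subset, rho > 1 random
#' usage.
#'
#' @slot table data.frame with columns site, pattern, subset_class, rho,
#'   sigma_subset, sigma_total.
#' @slot nSequences number of windows profiled.
#'
#' @seealso [dispersionProfile()], [compareModes()]
#' @export
setClass("DispersionProfile",
  representation(table = "data.frame", nSequences = "integer"))

setValidity("DispersionProfile", function(object) {
  need <- c("site", "pattern", "subset_class", "rho",
            "sigma_subset", "sigma_total")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  TRUE
})
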