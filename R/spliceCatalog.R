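## Splice-event catalogue: introns from a GTF, the bipartite donor-acceptor
## graph, and acceptor mode / sub-mode classification.
##
## Coordinates are 1-based genomic. A donor position is the first intronic
## base in transcription orientation (the G of GT), an acceptor position the
## last intronic base (the G of AG). "Upstream" always means 5' in
## transcription direction.

#' Derive splice events from a GTF annotation
#'
#' Reads exon features grouped by transcript and infers one splice event
#' (intron) between each pair of consecutive exons of a transcript.
#'
#' @param gtf path to a GTF file, or a [GenomicRanges::GRanges] of exon
#'   features carrying \code{transcript_id} (and optionally \code{gene_id})
#'   metadata columns.
#' @return data.frame with columns chrom, strand, donor_pos, acceptor_pos,
#'   transcript_id, gene_id, event_id.
#' @seealso [buildSpliceGraph()]
#' @export
spliceEventsFromGTF <- function(gtf) {
  if (is.character(gtf)) gtf <- rtracklayer::import(gtf, format = "gtf")
  stopifnot(is(gtf, "GRanges"))
  if (!is.null(gtf$type)) gtf <- gtf[gtf$type == "exon"]
  if (is.null(gtf$transcript_id))
    stop("annotation lacks transcript_id on exon features", call. = FALSE)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gtf)),
                   start = GenomicRanges::start(gtf),
                   end = GenomicRanges::end(gtf),
                   strand = as.character(GenomicRanges::strand(gtf)),
                   transcript_id = gtf$transcript_id,
                   gene_id = if (is.null(gtf$gene_id)) NA_character_
                             else gtf$gene_id)
  ev <- do.call(rbind, lapply(split(df, df$transcript_id), function(tx) {
    tx <- tx[order(tx$start), ]
    if (nrow(tx) < 2L) return(NULL)
    if (length(unique(tx$strand)) != 1L || length(unique(tx$chrom)) != 1L)
      stop("invalid event: transcript ", tx$transcript_id[1L],
           " spans strands or contigs", call. = FALSE)
    istart <- tx$end[-nrow(tx)] + 1L
    iend <- tx$start[-1L] - 1L
    if (any(iend < istart))
      stop("invalid event: zero-length or negative intron in transcript ",
           tx$transcript_id[1L], call. = FALSE)
    minus <- tx$strand[1L] == "-"
    data.frame(chrom = tx$chrom[1L], strand = tx$strand[1L],
               donor_pos = if (minus) iend else istart,
               acceptor_pos = if (minus) istart else iend,
               transcript_id = tx$transcript_id[1L],
               gene_id = tx$gene_id[1L])
  }))
  rownames(ev) <- NULL
  ev$event_id <- sprintf("%s:%s:%d-%d", ev$chrom, ev$strand,
                         ev$donor_pos, ev$acceptor_pos)
  ev
}

#' Build the bipartite donor-acceptor splice graph
#'
#' Deduplicates donor and acceptor sites by (chrom, strand, position) and
#' splice events by site pair, recording per-edge transcript support and
#' per-node degrees.
#'
#' @param events data.frame with columns chrom, strand, donor_pos,
#'   acceptor_pos and optionally transcript_id.
#' @return a [SpliceGraph-class].
#' @examples
#' ev <- data.frame(chrom = "c", strand = "+",
#'                  donor_pos = c(101, 101), acceptor_pos = c(300, 400))
#' g <- buildSpliceGraph(ev)
#' donorSites(g)$degree  # 2
#' @export
buildSpliceGraph <- function(events) {
  stopifnot(is.data.frame(events), nrow(events) > 0L)
  need <- c("chrom", "strand", "donor_pos", "acceptor_pos")
  if (!all(need %in% names(events)))
    stop("events must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if ("donor_strand" %in% names(events) &&
      "acceptor_strand" %in% names(events) &&
      any(events$donor_strand != events$acceptor_strand))
    stop("invalid event: donor and acceptor on different strands",
         call. = FALSE)
  if (!all(events$strand %in% c("+", "-")))
    stop("invalid event: strand must be + or -", call. = FALSE)
  ilen <- abs(events$acceptor_pos - events$donor_pos) + 1L
  okdir <- ifelse(events$strand == "+",
                  events$acceptor_pos > events$donor_pos,
                  events$acceptor_pos < events$donor_pos)
  if (any(!okdir | ilen < 1L))
    stop("invalid event: acceptor not downstream of donor", call. = FALSE)
  if (is.null(events$transcript_id))
    events$transcript_id <- sprintf("event%06d", seq_len(nrow(events)))

  dkey <- paste(events$chrom, events$strand, events$donor_pos)
  akey <- paste(events$chrom, events$strand, events$acceptor_pos)
  didx <- match(dkey, unique(dkey))
  aidx <- match(akey, unique(akey))
  firstd <- !duplicated(didx)
  firsta <- !duplicated(aidx)
  donors <- data.frame(chrom = events$chrom[firstd],
                       strand = events$strand[firstd],
                       pos = events$donor_pos[firstd])
  acceptors <- data.frame(chrom = events$chrom[firsta],
                          strand = events$strand[firsta],
                          pos = events$acceptor_pos[firsta])
  ekey <- paste(didx, aidx)
  grp <- split(seq_len(nrow(events)), factor(ekey, levels = unique(ekey)))
  edges <- data.frame(
    donor = didx[vapply(grp, `[`, integer(1L), 1L)],
    acceptor = aidx[vapply(grp, `[`, integer(1L), 1L)],
    n_transcripts = vapply(grp, function(i)
      length(unique(events$transcript_id[i])), integer(1L)),
    transcript_ids = vapply(grp, function(i)
      paste(sort(unique(events$transcript_id[i])), collapse = ","),
      character(1L)))
  rownames(edges) <- NULL
  donors$degree <- as.integer(table(factor(edges$donor,
                                           levels = seq_len(nrow(donors)))))
  acceptors$degree <- as.integer(table(factor(edges$acceptor,
                                        levels = seq_len(nrow(acceptors)))))
  new("SpliceGraph", donors = donors, acceptors = acceptors, edges = edges)
}

#' @describeIn buildSpliceGraph donor site table (chrom, strand, pos, degree).
#' @param x a \code{SpliceGraph}.
#' @export
setMethod("donorSites", "SpliceGraph", function(x) x@donors)

#' @describeIn buildSpliceGraph acceptor site table.
#' @export
setMethod("acceptorSites", "SpliceGraph", function(x) x@acceptors)

#' @describeIn buildSpliceGraph deduplicated edge table.
#' @export
setMethod("graphEdges", "SpliceGraph", function(x) x@edges)

setMethod("show", "SpliceGraph", function(object) {
  cat("SpliceGraph:", nrow(object@donors), "donors,",
      nrow(object@acceptors), "acceptors,", nrow(object@edges), "edges\n")
})

## signed position increasing in transcription direction
tpos <- function(pos, strand) pos * ifelse(strand == "-", -1, 1)

#' Classify acceptor splicing modes and sub-modes
#'
#' Assigns each acceptor site a mode from the donor-acceptor pairing
#' structure: \describe{
#'   \item{common}{one-to-one: the acceptor and its single donor each pair
#'     once.}
#'   \item{constitutive}{one acceptor paired with several donors, each donor
#'     pairing only once.}
#'   \item{alternative}{one of several acceptors sharing a single donor that
#'     pairs with each of them once.}
#'   \item{ambiguous}{many-to-many pairings; excluded downstream.}
#' }
#' Alternative acceptors are further assigned a sub-mode relative to the
#' reference junction of their donor group (the acceptor supported by the
#' most transcripts): \code{normal} at the reference intron-exon junction,
#' \code{intronic} strictly inside the reference intron, \code{exonic}
#' strictly inside the reference downstream exon. Groups whose reference is
#' ambiguous (tied support) or acceptors falling outside the reference
#' transcripts' downstream exon are \code{unclassifiable} and excluded.
#'
#' @param graph a [SpliceGraph-class].
#' @param exons optional exon model used for sub-modes: a data.frame with
#'   columns chrom, start, end, strand, transcript_id (or a GRanges with a
#'   \code{transcript_id} column). Without it sub-modes of alternative
#'   acceptors are \code{NA}.
#' @return data.frame with one row per acceptor: chrom, strand, acceptor_pos,
#'   mode, submode, n_donors, donor_positions.
#' @export
classifyAcceptors <- function(graph, exons = NULL) {
  stopifnot(is(graph, "SpliceGraph"))
  acc <- graph@acceptors
  don <- graph@donors
  edg <- graph@edges
  if (!is.null(exons) && is(exons, "GRanges")) {
    if (!is.null(exons$type)) exons <- exons[exons$type == "exon"]
    exons <- data.frame(chrom = as.character(GenomicRanges::seqnames(exons)),
                        start = GenomicRanges::start(exons),
                        end = GenomicRanges::end(exons),
                        strand = as.character(GenomicRanges::strand(exons)),
                        transcript_id = exons$transcript_id)
  }

  mode <- character(nrow(acc))
  submode <- rep("not_applicable", nrow(acc))
  ndon <- integer(nrow(acc))
  dpos <- character(nrow(acc))
  for (i in seq_len(nrow(acc))) {
    ed <- edg[edg$acceptor == i, , drop = FALSE]
    ddeg <- don$degree[ed$donor]
    ndon[i] <- nrow(ed)
    dpos[i] <- paste(sort(don$pos[ed$donor]), collapse = ",")
    mode[i] <-
      if (acc$degree[i] == 1L && all(ddeg == 1L)) "common"
      else if (acc$degree[i] > 1L && all(ddeg == 1L)) "constitutive"
      else if (acc$degree[i] == 1L && any(ddeg > 1L)) "alternative"
      else "ambiguous"
  }

  ## sub-modes per alternative group (acceptors sharing a donor)
  altDonors <- unique(edg$donor[edg$acceptor %in% which(mode == "alternative")])
  for (d in altDonors) {
    ed <- edg[edg$donor == d, , drop = FALSE]
    members <- ed$acceptor
    if (!all(mode[members] == "alternative")) {
      ## mixed group (some member ambiguous): leave pure members unclassified
      submode[members[mode[members] == "alternative"]] <- "unclassifiable"
      next
    }
    if (is.null(exons)) { submode[members] <- NA_character_; next }
    top <- which(ed$n_transcripts == max(ed$n_transcripts))
    if (length(top) != 1L) { submode[members] <- "unclassifiable"; next }
    refEdge <- ed[top, ]
    refAcc <- refEdge$acceptor
    strand <- acc$strand[refAcc]
    chrom <- acc$chrom[refAcc]
    refT <- tpos(acc$pos[refAcc], strand)
    donT <- tpos(don$pos[d], strand)
    ## downstream exon(s) of the reference transcripts: exon whose
    ## transcription start abuts the reference acceptor
    refTx <- strsplit(refEdge$transcript_ids, ",")[[1L]]
    ex <- exons[exons$transcript_id %in% refTx & exons$chrom == chrom &
                exons$strand == strand, , drop = FALSE]
    exStartT <- tpos(if (strand == "-") ex$end else ex$start, strand)
    exEndT <- tpos(if (strand == "-") ex$start else ex$end, strand)
    dn <- ex[exStartT == refT + 1L, , drop = FALSE]
    dnEndT <- exEndT[exStartT == refT + 1L]
    for (a in members) {
      aT <- tpos(acc$pos[a], strand)
      submode[a] <-
        if (aT == refT) "normal"
        else if (aT > donT && aT < refT) "intronic"
        else if (aT > refT && nrow(dn) && any(aT <= dnEndT)) "exonic"
        else "unclassifiable"
    }
  }

  data.frame(chrom = acc$chrom, strand = acc$strand,
             acceptor_pos = acc$pos, mode = mode, submode = submode,
             n_donors = ndon, donor_positions = dpos)
}

#' Write the acceptor classification table
#'
#' @param tbl output of [classifyAcceptors()].
#' @param path TSV output path.
#' @return the path, invisibly.
#' @export
writeAcceptorTable <- function(tbl, path) writeTSV(tbl, path)

#' Export acceptor sites as BED6
#'
#' One single-base feature per acceptor, name \code{mode.submode}. Output is
#' 0-based half-open as per the BED convention.
#'
#' @inheritParams writeAcceptorTable
#' @return the path, invisibly.
#' @export
exportAcceptorBED <- function(tbl, path) {
  gr <- GenomicRanges::GRanges(
    tbl$chrom,
    IRanges::IRanges(tbl$acceptor_pos, tbl$acceptor_pos),
    strand = tbl$strand)
  gr$name <- paste(tbl$mode, tbl$submode, sep = ".")
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
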