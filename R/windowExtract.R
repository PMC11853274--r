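## Aligned 100-base acceptor windows and the 100-bp exclusion filters.
##
## Windows run in transcription orientation with the zero-skipping site
## convention: base labels -50..-1 upstream (intron side), +1..+50
## downstream (exon side), no label 0; the splice junction lies between
## labels -1 and +1, so canonical windows carry A at -2 and G at -1.

WINDOW_FLANK <- 50L

#' Zero-skipping site labels
#'
#' \code{baseSiteLabels()} returns the 100 base labels of a window
#' (-50..-1, +1..+50); \code{kmerStartLabels()} the 95 labels at which a
#' 6-mer can start (-50..-1, +1..+45), a 6-mer being indexed by its first
#' base.
#'
#' @return integer vector of labels.
#' @export
baseSiteLabels <- function() c(-50:-1, 1:50)

#' @rdname baseSiteLabels
#' @export
kmerStartLabels <- function() c(-50:-1, 1:45)

#' Convert between site labels and sequence offsets
#'
#' Maps the zero-skipping label (-50..-1, +1..+50) to the 0-based sequence
#' offset 0..99 and back: label -50 is offset 0, label -1 offset 49, label
#' +1 offset 50, label +50 offset 99.
#'
#' @param label integer site label(s), no 0.
#' @param offset integer offset(s) in 0..99.
#' @return integer vector.
#' @examples
#' labelToOffset(c(-50, -1, 1, 50))  # 0 49 50 99
#' offsetToLabel(labelToOffset(-7))  # -7
#' @export
labelToOffset <- function(label) {
  if (any(label == 0L | label < -WINDOW_FLANK | label > WINDOW_FLANK))
    stop("invalid coordinate: site labels run -50..-1, +1..+50 (no 0)",
         call. = FALSE)
  as.integer(ifelse(label < 0L, label + WINDOW_FLANK,
                    label + WINDOW_FLANK - 1L))
}

#' @rdname labelToOffset
#' @export
offsetToLabel <- function(offset) {
  if (any(offset < 0L | offset > 2L * WINDOW_FLANK - 1L))
    stop("invalid coordinate: offsets run 0..99", call. = FALSE)
  as.integer(ifelse(offset < WINDOW_FLANK, offset - WINDOW_FLANK,
                    offset - WINDOW_FLANK + 1L))
}

#' Apply the 100-bp exclusion filters to labeled splice events
#'
#' Removes events whose intron is shorter than 100 bases (strictly), and,
#' within each group of alternative acceptors sharing a donor (and
#' symmetrically each group of donors sharing a constitutive acceptor), any
#' pair of sites separated by fewer than 100 bases; both members of a close
#' pair are removed.
#'
#' @param events data.frame with columns chrom, strand, donor_pos,
#'   acceptor_pos, mode, and optionally event_id.
#' @return list with elements \code{retained} (data.frame) and
#'   \code{rejected} (data.frame with a \code{reason} column).
#' @examples
#' ev <- data.frame(chrom = "c", strand = "+", donor_pos = 101,
#'                  acceptor_pos = 199, mode = "common")
#' filterEvents(ev)$rejected$reason  # intron shorter than 100
#' @export
filterEvents <- function(events) {
  stopifnot(is.data.frame(events))
  if (is.null(events$event_id))
    events$event_id <- sprintf("%s:%s:%d-%d", events$chrom, events$strand,
                               events$donor_pos, events$acceptor_pos)
  reason <- rep(NA_character_, nrow(events))

  ilen <- abs(events$acceptor_pos - events$donor_pos) + 1L
  reason[ilen < 100L] <- "intron_lt_100bp"

  closePairs <- function(sites, positions) {
    ## indices (into events) of members of any pair < 100 bp apart
    hit <- integer(0)
    if (length(sites) > 1L) {
      for (i in seq_along(sites)[-length(sites)])
        for (j in (i + 1L):length(sites))
          if (abs(positions[i] - positions[j]) < 100L)
            hit <- c(hit, sites[i], sites[j])
    }
    unique(hit)
  }
  alt <- which(events$mode == "alternative")
  for (g in split(alt, paste(events$chrom[alt], events$strand[alt],
                             events$donor_pos[alt]))) {
    hit <- closePairs(g, events$acceptor_pos[g])
    reason[hit[is.na(reason[hit])]] <- "alt_acceptors_lt_100bp"
  }
  con <- which(events$mode == "constitutive")
  for (g in split(con, paste(events$chrom[con], events$strand[con],
                             events$acceptor_pos[con]))) {
    hit <- closePairs(g, events$donor_pos[g])
    reason[hit[is.na(reason[hit])]] <- "alt_donors_lt_100bp"
  }

  keep <- is.na(reason)
  rejected <- events[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(rejected) <- NULL
  retained <- events[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, rejected = rejected)
}

#' Construct an AcceptorWindowSet
#'
#' Low-level constructor pairing 100-base sequences with per-window
#' metadata.
#'
#' @param sequences a [Biostrings::DNAStringSet] of width-100 sequences.
#' @param info a data.frame or DataFrame, one row per sequence.
#' @return an [AcceptorWindowSet-class].
#' @export
newAcceptorWindowSet <- function(sequences, info) {
  new("AcceptorWindowSet", sequences = sequences,
      info = S4Vectors::DataFrame(info))
}

#' Extract aligned 100-base acceptor windows from a genome
#'
#' For each event, takes 50 bases on either side of the splice junction
#' (the junction follows the acceptor position in transcription direction)
#' and reverse-complements minus-strand windows so every window reads in
#' transcription orientation. The AG check at labels -2/-1 is recorded per
#' window in the \code{ag_ok} column, not enforced.
#'
#' @param genome a named [Biostrings::DNAStringSet] of contigs, or a path to
#'   a FASTA file.
#' @param events data.frame with columns chrom, strand, acceptor_pos and
#'   optionally mode, submode, event_id (one window per row).
#' @param onN what to do with windows containing non-ACGT bases:
#'   \code{"reject"} (default, dropped with a message) or \code{"keep"}.
#' @return an [AcceptorWindowSet-class].
#' @export
extractWindows <- function(genome, events, onN = c("reject", "keep")) {
  onN <- match.arg(onN)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(is(genome, "DNAStringSet"), is.data.frame(events))
  names(genome) <- sub("\\s.*", "", names(genome))
  for (col in c("mode", "submode", "event_id"))
    if (is.null(events[[col]])) events[[col]] <- NA_character_

  seqs <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    chrom <- events$chrom[i]
    if (!chrom %in% names(genome))
      stop("contig not in genome: ", chrom, call. = FALSE)
    a <- events$acceptor_pos[i]
    minus <- events$strand[i] == "-"
    gstart <- if (minus) a - WINDOW_FLANK else a - WINDOW_FLANK + 1L
    gend <- gstart + 2L * WINDOW_FLANK - 1L
    if (gstart < 1L || gend > length(genome[[chrom]]))
      stop("boundary error: window [", gstart, ",", gend,
           "] overruns contig ", chrom, call. = FALSE)
    s <- Biostrings::subseq(genome[[chrom]], gstart, gend)
    if (minus) s <- Biostrings::reverseComplement(s)
    seqs[i] <- toupper(as.character(s))
  }
  hasN <- grepl("[^ACGT]", seqs)
  if (onN == "reject" && any(hasN)) {
    message("dropping ", sum(hasN), " window(s) with ambiguous bases")
    events <- events[!hasN, , drop = FALSE]
    seqs <- seqs[!hasN]
  }
  agOff <- labelToOffset(c(-2L, -1L)) + 1L
  info <- S4Vectors::DataFrame(
    event_id = events$event_id, chrom = events$chrom,
    strand = events$strand, acceptor_pos = events$acceptor_pos,
    mode = events$mode, submode = events$submode,
    ag_ok = substr(seqs, agOff[1L], agOff[2L]) == "AG")
  newAcceptorWindowSet(Biostrings::DNAStringSet(seqs), info)
}

#' @describeIn extractWindows the window sequences.
#' @param x an \code{AcceptorWindowSet}.
#' @export
setMethod("windowSequences", "AcceptorWindowSet", function(x) x@sequences)

#' @describeIn extractWindows per-window metadata.
#' @export
setMethod("windowInfo", "AcceptorWindowSet", function(x) x@info)

#' @describeIn extractWindows number of windows.
#' @export
setMethod("nWindows", "AcceptorWindowSet", function(x) length(x@sequences))

setMethod("show", "AcceptorWindowSet", function(object) {
  cat("AcceptorWindowSet:", length(object@sequences),
      "windows of 100 bases\n")
  if (length(object@sequences)) {
    tab <- table(object@info$mode, useNA = "ifany")
    cat("  modes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' Write windows as FASTA and TSV
#'
#' FASTA headers are \code{event_id|mode|submode}.
#'
#' @param windows an [AcceptorWindowSet-class].
#' @param fastaPath,tsvPath output paths (either may be NULL to skip).
#' @return invisible NULL.
#' @export
writeWindows <- function(windows, fastaPath = NULL, tsvPath = NULL) {
  stopifnot(is(windows, "AcceptorWindowSet"))
  info <- as.data.frame(windows@info)
  if (!is.null(fastaPath)) {
    seqs <- windows@sequences
    names(seqs) <- paste(info$event_id, info$mode, info$submode, sep = "|")
    Biostrings::writeXStringSet(seqs, fastaPath)
  }
  if (!is.null(tsvPath))
    writeTSV(cbind(info, sequence = as.character(windows@sequences)),
             tsvPath)
  invisible(NULL)
}

#' Read windows from FASTA (optionally with a mode-label table)
#'
#' Inverse of [writeWindows()]: headers of the form
#' \code{event_id|mode|submode} are parsed back; alternatively a TSV with
#' columns event_id, mode, submode overrides labels by event_id.
#'
#' @param fastaPath windows FASTA path.
#' @param labelPath optional TSV of labels.
#' @return an [AcceptorWindowSet-class].
#' @export
readWindows <- function(fastaPath, labelPath = NULL) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  info <- data.frame(
    event_id = vapply(parts, `[`, character(1L), 1L),
    mode = vapply(parts, function(p) if (length(p) > 1L) p[2L]
                  else NA_character_, character(1L)),
    submode = vapply(parts, function(p) if (length(p) > 2L) p[3L]
                     else NA_character_, character(1L)))
  if (!is.null(labelPath)) {
    lab <- utils::read.delim(labelPath)
    m <- match(info$event_id, lab$event_id)
    info$mode[!is.na(m)] <- lab$mode[m[!is.na(m)]]
    if (!is.null(lab$submode))
      info$submode[!is.na(m)] <- lab$submode[m[!is.na(m)]]
  }
  seqChar <- toupper(as.character(seqs))
  agOff <- labelToOffset(c(-2L, -1L)) + 1L
  info$chrom <- NA_character_; info$strand <- NA_character_
  info$acceptor_pos <- NA_integer_
  info$ag_ok <- substr(seqChar, agOff[1L], agOff[2L]) == "AG"
  names(seqs) <- info$event_id
  newAcceptorWindowSet(Biostrings::DNAStringSet(seqChar), info)
}
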