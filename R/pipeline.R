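## End-to-end orchestration: catalogue -> filter -> extract -> count ->
## dispersion -> region tests, for annotation-derived or synthetic inputs,
## with a JSON run manifest tying record counts and outputs together.

writeManifest <- function(outDir, seed, inputs, counts, outputs) {
  manifest <- list(inputs = inputs, seed = seed, counts = counts,
                   outputs = outputs,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

## profiles + region comparisons for a named list of window sets
profileAndCompare <- function(windowSets, partition, regions, alpha,
                              outDir, prefix) {
  profiles <- list()
  outputs <- character(0)
  for (m in names(windowSets)) {
    pkm <- countKmersBySite(windowSets[[m]])
    profiles[[m]] <- dispersionProfile(pkm, partition)
    p <- file.path(outDir, sprintf("%sprofile_%s.tsv", prefix, m))
    writeProfileTable(profiles[[m]], p)
    outputs <- c(outputs, p)
  }
  tests <- NULL
  if (length(profiles) >= 2L) {
    tests <- compareModesByRegion(profiles, regions, alpha = alpha)
    p <- file.path(outDir, paste0(prefix, "region_tests.tsv"))
    writeTSV(tests, p)
    outputs <- c(outputs, p)
  } else {
    warning("fewer than two modes with windows; region tests skipped",
            call. = FALSE)
  }
  list(profiles = profiles, tests = tests, outputs = outputs)
}

#' Run the annotation-driven pipeline
#'
#' From a genome FASTA and a GTF: derives splice events, classifies
#' acceptor modes and sub-modes, applies the 100-bp exclusion filters,
#' extracts aligned 100-base windows per retained acceptor, profiles
#' dispersion per mode and tests region-wise differences between modes.
#' All tables, the rejection log and a JSON manifest are written to
#' \code{outDir}.
#'
#' @param genomeFile path to a (multi-)FASTA genome.
#' @param gtfFile path to a GTF with exon features.
#' @param outDir output directory (created if missing).
#' @param regions region table, default [defaultRegions()].
#' @param alpha significance threshold on adjusted p-values.
#' @param bySubmode also profile and test the alternative sub-modes
#'   (default TRUE when at least two sub-modes have windows).
#' @return invisibly, a list with elements acceptors, retained, rejected,
#'   windows, profiles, tests, submodeTests, manifest.
#' @export
runAnnotationMode <- function(genomeFile, gtfFile, outDir,
                              regions = defaultRegions(), alpha = 0.05,
                              bySubmode = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  genome <- Biostrings::readDNAStringSet(genomeFile)
  names(genome) <- sub("\\s.*", "", names(genome))
  events <- spliceEventsFromGTF(gtfFile)
  missing <- setdiff(unique(events$chrom), names(genome))
  if (length(missing))
    stop("contig(s) in annotation but not genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  graph <- buildSpliceGraph(events)
  acceptors <- classifyAcceptors(graph, exons = events2exons(gtfFile))

  ## one row per edge, carrying the acceptor's mode
  edges <- graphEdges(graph)
  acc <- acceptorSites(graph)
  don <- donorSites(graph)
  eventTab <- data.frame(
    chrom = acc$chrom[edges$acceptor], strand = acc$strand[edges$acceptor],
    donor_pos = don$pos[edges$donor],
    acceptor_pos = acc$pos[edges$acceptor],
    mode = acceptors$mode[edges$acceptor],
    submode = acceptors$submode[edges$acceptor])
  eventTab$event_id <- sprintf("%s:%s:%d-%d", eventTab$chrom,
                               eventTab$strand, eventTab$donor_pos,
                               eventTab$acceptor_pos)
  flt <- filterEvents(eventTab)

  ## one window per acceptor all of whose events were retained
  keyAll <- paste(eventTab$chrom, eventTab$strand, eventTab$acceptor_pos)
  keyKept <- paste(flt$retained$chrom, flt$retained$strand,
                   flt$retained$acceptor_pos)
  keyRej <- paste(flt$rejected$chrom, flt$rejected$strand,
                  flt$rejected$acceptor_pos)
  winTab <- flt$retained[!duplicated(keyKept) &
                           !(keyKept %in% keyRej), , drop = FALSE]
  winTab <- winTab[winTab$mode %in%
                     c("common", "constitutive", "alternative") &
                   !winTab$submode %in% "unclassifiable", , drop = FALSE]
  windows <- extractWindows(genome, winTab)

  accPath <- file.path(outDir, "acceptor_modes.tsv")
  writeAcceptorTable(acceptors, accPath)
  bedPath <- file.path(outDir, "acceptor_sites.bed")
  exportAcceptorBED(acceptors, bedPath)
  rejPath <- file.path(outDir, "rejected_events.tsv")
  writeTSV(flt$rejected, rejPath)
  fastaPath <- file.path(outDir, "windows.fa")
  winTsvPath <- file.path(outDir, "windows.tsv")
  writeWindows(windows, fastaPath, winTsvPath)

  info <- windowInfo(windows)
  byMode <- lapply(split(seq_len(nWindows(windows)), info$mode),
                   function(i) windows[i])
  byMode <- byMode[vapply(byMode, nWindows, integer(1L)) > 0L]
  partition <- kmerPartition(6L)
  pc <- profileAndCompare(byMode, partition, regions, alpha, outDir, "mode_")

  submodeTests <- NULL
  if (bySubmode) {
    alt <- info$mode == "alternative" &
      info$submode %in% c("normal", "exonic", "intronic")
    bySub <- lapply(split(which(alt), info$submode[alt]),
                    function(i) windows[i])
    bySub <- bySub[vapply(bySub, nWindows, integer(1L)) > 0L]
    if (length(bySub) >= 2L) {
      ps <- profileAndCompare(bySub, partition, regions, alpha, outDir,
                              "submode_")
      submodeTests <- ps$tests
      pc$outputs <- c(pc$outputs, ps$outputs)
    }
  }

  manifest <- writeManifest(
    outDir, seed = NA,
    inputs = list(genome = genomeFile, gtf = gtfFile),
    counts = list(events = nrow(eventTab), retained = nrow(flt$retained),
                  rejected = nrow(flt$rejected),
                  acceptors = nrow(acceptors), windows = nWindows(windows)),
    outputs = c(accPath, bedPath, rejPath, fastaPath, winTsvPath,
                pc$outputs))
  invisible(list(acceptors = acceptors, retained = flt$retained,
                 rejected = flt$rejected, windows = windows,
                 profiles = pc$profiles, tests = pc$tests,
                 submodeTests = submodeTests, manifest = manifest))
}

## exon model for sub-mode classification, from a GTF path or GRanges
events2exons <- function(gtf) {
  if (is.character(gtf)) gtf <- rtracklayer::import(gtf, format = "gtf")
  if (!is.null(gtf$type)) gtf <- gtf[gtf$type == "exon"]
  data.frame(chrom = as.character(GenomicRanges::seqnames(gtf)),
             start = GenomicRanges::start(gtf),
             end = GenomicRanges::end(gtf),
             strand = as.character(GenomicRanges::strand(gtf)),
             transcript_id = gtf$transcript_id)
}

#' Run the synthetic-data pipeline
#'
#' Generates one window set per mode from the configuration (injections
#' applied to their target modes), profiles dispersion and tests
#' region-wise differences; writes windows, profiles, test tables and a
#' manifest to \code{outDir}.
#'
#' @param config a [generatorConfig()].
#' @param outDir output directory (created if missing).
#' @param modes mode labels to simulate.
#' @param regions region table, default [defaultRegions()].
#' @param alpha significance threshold on adjusted p-values.
#' @return invisibly, a list with elements windows (named list), profiles,
#'   tests, manifest.
#' @export
runSyntheticMode <- function(config, outDir,
                             modes = c("common", "constitutive",
                                       "alternative"),
                             regions = defaultRegions(), alpha = 0.05) {
  stopifnot(inherits(config, "GeneratorConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  windowSets <- lapply(stats::setNames(modes, modes),
                       function(m) generateWindows(config, m))
  outputs <- character(0)
  for (m in modes) {
    p <- file.path(outDir, sprintf("windows_%s.fa", m))
    writeWindows(windowSets[[m]], p, NULL)
    outputs <- c(outputs, p)
  }
  partition <- kmerPartition(6L)
  pc <- profileAndCompare(windowSets, partition, regions, alpha, outDir, "")
  manifest <- writeManifest(
    outDir, seed = config$seed,
    inputs = list(generator = "synthetic", n_per_mode = config$nPerMode,
                  modes = modes,
                  injections = if (is.null(config$injections)) 0L
                               else nrow(config$injections)),
    counts = c(list(windows_total = config$nPerMode * length(modes)),
               stats::setNames(lapply(windowSets, nWindows), modes)),
    outputs = c(outputs, pc$outputs))
  invisible(list(windows = windowSets, profiles = pc$profiles,
                 tests = pc$tests, manifest = manifest))
}

#' Subset an AcceptorWindowSet
#'
#' @param x an [AcceptorWindowSet-class].
#' @param i index vector.
#' @param j,...,drop ignored.
#' @return an [AcceptorWindowSet-class] with the selected windows.
#' @export
setMethod("[", "AcceptorWindowSet", function(x, i, j, ..., drop = FALSE) {
  newAcceptorWindowSet(x@sequences[i], x@info[i, , drop = FALSE])
})
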