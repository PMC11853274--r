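## Synthetic acceptor-like windows and a planted toy annotation.
##
## The window generator emulates the gross structure of real acceptor
## regions: a pyrimidine-rich upstream tract, a core with the fixed AG at
## labels -2/-1 and a polypyrimidine run-in, and a separate downstream
## (exonic) base composition. Optional per-mode injections enrich a
## dinucleotide over a site interval to plant detectable dispersion
## differences between modes.

defaultCoreWeights <- function() {
  labels <- c(-7:-1, 1:6)
  w <- matrix(0, nrow = 4L, ncol = length(labels),
              dimnames = list(DNA_BASES, labels))
  w[, as.character(-7:-3)] <- c(0.08, 0.41, 0.08, 0.43)  # polypyrimidine
  w["A", "-2"] <- 1                                       # fixed A
  w["G", "-1"] <- 1                                       # fixed G
  w[, "1"] <- c(0.25, 0.14, 0.47, 0.14)                   # G-rich exon start
  w[, as.character(2:6)] <- c(0.26, 0.23, 0.26, 0.25)
  w
}

#' Generator configuration for synthetic acceptor windows
#'
#' @param nPerMode windows generated per mode (default 2000).
#' @param seed base seed; all randomness is derived from it.
#' @param upstreamPyrimidine probability that an upstream base (labels
#'   -50..-8) is C or T (default 0.7, split evenly; purines split evenly).
#' @param coreWeights 4 x 13 matrix of per-base probabilities for labels
#'   -7..+6 (rows A, C, G, T; columns must sum to 1, with A fixed at -2 and
#'   G at -1). Default: polypyrimidine run-in at -7..-3, G-rich +1.
#' @param downstreamComposition length-4 base probabilities for labels
#'   +7..+50 (default uniform).
#' @param injections data.frame with columns pattern, from, to (site
#'   labels), multiplier, mode; each row multiplies the expected occurrence
#'   count of the dinucleotide inside the label interval by
#'   \code{multiplier} for windows of the target mode.
#' @return a validated \code{GeneratorConfig} (classed list).
#' @export
generatorConfig <- function(nPerMode = 2000L, seed = 1L,
                            upstreamPyrimidine = 0.7,
                            coreWeights = defaultCoreWeights(),
                            downstreamComposition = rep(0.25, 4L),
                            injections = NULL) {
  stopifnot(nPerMode >= 1L, upstreamPyrimidine >= 0, upstreamPyrimidine <= 1)
  coreWeights <- as.matrix(coreWeights)
  if (!all(dim(coreWeights) == c(4L, 13L)))
    stop("coreWeights must be 4 bases x 13 labels (-7..+6)", call. = FALSE)
  if (max(abs(colSums(coreWeights) - 1)) > 1e-8)
    stop("coreWeights columns must sum to 1", call. = FALSE)
  rownames(coreWeights) <- DNA_BASES
  colnames(coreWeights) <- c(-7:-1, 1:6)
  if (coreWeights["A", "-2"] != 1 || coreWeights["G", "-1"] != 1)
    stop("coreWeights must fix A at label -2 and G at label -1",
         call. = FALSE)
  stopifnot(length(downstreamComposition) == 4L,
            abs(sum(downstreamComposition) - 1) < 1e-8)
  if (!is.null(injections)) {
    need <- c("pattern", "from", "to", "multiplier", "mode")
    stopifnot(is.data.frame(injections), all(need %in% names(injections)))
    for (p in injections$pattern) checkPattern(p)
    if (any(injections$multiplier <= 0))
      stop("injection multiplier must be > 0", call. = FALSE)
  }
  structure(list(nPerMode = as.integer(nPerMode), seed = as.integer(seed),
                 upstreamPyrimidine = upstreamPyrimidine,
                 coreWeights = coreWeights,
                 downstreamComposition = downstreamComposition,
                 injections = injections),
            class = "GeneratorConfig")
}

## per-position base probability matrix, 4 x 100
positionProbMatrix <- function(config) {
  P <- matrix(0, nrow = 4L, ncol = 100L, dimnames = list(DNA_BASES, NULL))
  pyr <- config$upstreamPyrimidine
  P[, 1:43] <- c((1 - pyr) / 2, pyr / 2, (1 - pyr) / 2, pyr / 2)
  P[, 44:56] <- config$coreWeights
  P[, 57:100] <- config$downstreamComposition
  P
}

## sample an n x length(cols) block of base codes (0..3) column-wise
sampleBlock <- function(n, P, cols) {
  out <- matrix(0L, nrow = n, ncol = length(cols))
  for (i in seq_along(cols))
    out[, i] <- sample.int(4L, n, replace = TRUE, prob = P[, cols[i]]) - 1L
  out
}

## occurrences of dinucleotide (xi, yi codes) fully inside each row of B
countPatternRows <- function(B, xi, yi) {
  L <- ncol(B)
  if (L < 2L) return(integer(nrow(B)))
  rowSums(B[, 1:(L - 1L), drop = FALSE] == xi &
          B[, 2:L, drop = FALSE] == yi)
}

## Enrich a dinucleotide over interval columns by rejection resampling:
## per-window target counts are drawn from an exponentially tilted null
## count distribution whose mean is multiplier x the null mean, then the
## interval is redrawn until the observed count matches the target.
applyInjection <- function(B, P, inj) {
  xi <- match(substr(inj$pattern, 1, 1), DNA_BASES) - 1L
  yi <- match(substr(inj$pattern, 2, 2), DNA_BASES) - 1L
  cols <- (labelToOffset(inj$from) + 1L):(labelToOffset(inj$to) + 1L)
  L <- length(cols)
  mu0 <- sum(P[xi + 1L, cols[-L]] * P[yi + 1L, cols[-1L]])
  mu1 <- inj$multiplier * mu0
  if (mu1 > floor((L + 1L) / 2))
    stop("invalid parameter: infeasible injection (expected count ",
         round(mu1, 2), " exceeds interval capacity)", call. = FALSE)

  ## empirical null pmf of the interval pattern count
  sim <- countPatternRows(sampleBlock(4000L, P, cols), xi, yi)
  tab <- table(sim)
  support <- as.integer(names(tab))
  phat <- as.numeric(tab) / sum(tab)
  keep <- phat >= 2 / 4000          # bound the resampling cost
  support <- support[keep]; phat <- phat[keep]
  tiltMean <- function(th) sum(support * th^support * phat) /
    sum(th^support * phat)
  target <-
    if (max(support) <= mu1) rep(max(support), nrow(B))
    else {
      th <- stats::uniroot(function(t) tiltMean(t) - mu1,
                           lower = 1e-6, upper = 1e6, tol = 1e-9)$root
      w <- th^support * phat
      sample(support, nrow(B), replace = TRUE, prob = w / sum(w))
    }

  pending <- which(countPatternRows(B[, cols, drop = FALSE], xi, yi) !=
                   target)
  iter <- 0L
  while (length(pending) && iter < 5000L) {
    iter <- iter + 1L
    draw <- sampleBlock(length(pending), P, cols)
    got <- countPatternRows(draw, xi, yi)
    hit <- got == target[pending]
    if (any(hit)) B[pending[hit], cols] <- draw[hit, , drop = FALSE]
    pending <- pending[!hit]
  }
  B
}

codesToWindows <- function(B, mode, idPrefix) {
  chars <- matrix(DNA_BASES[B + 1L], nrow = nrow(B))
  seqs <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
  info <- S4Vectors::DataFrame(
    event_id = sprintf("%s_%05d", idPrefix, seq_len(nrow(B))),
    chrom = NA_character_, strand = NA_character_,
    acceptor_pos = NA_integer_, mode = mode, submode = NA_character_,
    ag_ok = TRUE)
  newAcceptorWindowSet(Biostrings::DNAStringSet(seqs), info)
}

#' Generate synthetic acceptor windows for one mode
#'
#' Draws \code{nPerMode} 100-base windows from the positional base model
#' (upstream pyrimidine bias, core weights with fixed AG at -2/-1,
#' downstream composition), then applies any injections configured for the
#' given mode. Deterministic given the configuration seed and mode.
#'
#' @param config a [generatorConfig()].
#' @param mode mode label attached to the windows (also selects
#'   injections targeting this mode).
#' @param seed optional explicit seed overriding the one derived from
#'   \code{config$seed} and \code{mode}.
#' @return an [AcceptorWindowSet-class].
#' @examples
#' w <- generateWindows(generatorConfig(nPerMode = 10), "common")
#' all(windowInfo(w)$ag_ok)
#' @export
generateWindows <- function(config, mode, seed = NULL) {
  stopifnot(inherits(config, "GeneratorConfig"))
  if (is.null(seed))
    seed <- subSeed(config$seed, sum(utf8ToInt(mode)))
  P <- positionProbMatrix(config)
  withr::local_seed(seed)
  B <- sampleBlock(config$nPerMode, P, 1:100)
  inj <- config$injections
  if (!is.null(inj))
    for (i in which(inj$mode == mode))
      B <- applyInjection(B, P, inj[i, ])
  codesToWindows(B, mode, paste0("syn_", mode))
}

#' Generate a null pair of window sets
#'
#' Two independent draws from the identical generator (no injections,
#' distinct sub-seeds) — the input for type-I smoke checks.
#'
#' @param config a [generatorConfig()].
#' @return list of two [AcceptorWindowSet-class]s named \code{a} and
#'   \code{b}.
#' @export
generateNullPair <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  cfg <- config
  cfg$injections <- NULL
  list(a = generateWindows(cfg, "null_a", seed = subSeed(config$seed, 1L)),
       b = generateWindows(cfg, "null_b", seed = subSeed(config$seed, 2L)))
}

## ---- toy annotation -------------------------------------------------------

toyTranscripts <- function() {
  tx <- function(gene, id, chrom, strand, starts, ends)
    data.frame(gene_id = gene, transcript_id = id, chrom = chrom,
               strand = strand, start = starts, end = ends)
  rbind(
    tx("GA", "A1", "chrT", "+", c(201, 901, 1601), c(400, 1100, 1800)),
    tx("GB", "B1", "chrT", "+", c(2201, 3001), c(2400, 3200)),
    tx("GB", "B2", "chrT", "+", c(2201, 3001), c(2500, 3200)),
    tx("GC", "C1", "chrT", "+", c(4001, 5001), c(4200, 5300)),
    tx("GC", "C1b", "chrT", "+", c(3901, 5001), c(4200, 5250)),
    tx("GC", "C2", "chrT", "+", c(4001, 5101), c(4200, 5300)),
    tx("GC", "C3", "chrT", "+", c(4001, 4801), c(4200, 5300)),
    tx("GD", "D1", "chrT", "+", c(6001, 6280), c(6200, 6500)),
    tx("GE", "E1a", "chrT", "+", c(7001, 7501), c(7200, 7700)),
    tx("GE", "E1b", "chrT", "+", c(6901, 7501), c(7200, 7650)),
    tx("GE", "E2", "chrT", "+", c(7001, 7551), c(7200, 7700)),
    tx("GF", "F1", "chrU", "-", c(101, 501), c(200, 700)))
}

toyTruth <- function() {
  row <- function(chrom, strand, pos, mode, submode, retained, reason = NA)
    data.frame(chrom = chrom, strand = strand, acceptor_pos = pos,
               mode = mode, submode = submode, retained = retained,
               reject_reason = reason)
  rbind(
    row("chrT", "+", 900, "common", "not_applicable", TRUE),
    row("chrT", "+", 1600, "common", "not_applicable", TRUE),
    row("chrT", "+", 3000, "constitutive", "not_applicable", TRUE),
    row("chrT", "+", 5000, "alternative", "normal", TRUE),
    row("chrT", "+", 5100, "alternative", "exonic", TRUE),
    row("chrT", "+", 4800, "alternative", "intronic", TRUE),
    row("chrT", "+", 6279, "common", "not_applicable", FALSE,
        "intron_lt_100bp"),
    row("chrT", "+", 7500, "alternative", "normal", FALSE,
        "alt_acceptors_lt_100bp"),
    row("chrT", "+", 7550, "alternative", "exonic", FALSE,
        "alt_acceptors_lt_100bp"),
    row("chrU", "-", 201, "common", "not_applicable", TRUE))
}

#' Generate the planted toy genome and annotation
#'
#' Builds a small two-contig genome (10 kb + 0.8 kb) and a 12-transcript
#' annotation that plants every classification case end to end: common,
#' constitutive and alternative acceptors with normal/exonic/intronic
#' sub-modes (all introns canonical GT..AG), one sub-100-bp intron and one
#' pair of alternative acceptors 50 bp apart sharing a donor (the two
#' exclusion-filter violations), plus a minus-strand gene exercising
#' reverse-complemented window extraction. The truth table lists every
#' acceptor's planted mode, sub-mode and filter fate.
#'
#' @param seed seed for the random background sequence.
#' @return list with elements \code{genome} (named
#'   [Biostrings::DNAStringSet]), \code{exons} (data.frame with gene_id,
#'   transcript_id, chrom, strand, start, end) and \code{truth}
#'   (data.frame).
#' @export
generateToyAnnotation <- function(seed = 1L) {
  withr::local_seed(subSeed(seed, 99L))
  mk <- function(n) sample(DNA_BASES, n, replace = TRUE)
  chrT <- mk(10000L); chrU <- mk(800L)

  ## plant canonical dinucleotides at every intron boundary
  plantPlus <- function(g, istart, iend) {
    g[istart] <- "G"; g[istart + 1L] <- "T"
    g[iend - 1L] <- "A"; g[iend] <- "G"
    g
  }
  introns <- rbind(c(401, 900), c(1101, 1600), c(2401, 3000), c(2501, 3000),
                   c(4201, 5000), c(4201, 5100), c(4201, 4800),
                   c(6201, 6279), c(7201, 7500), c(7201, 7550))
  for (i in seq_len(nrow(introns)))
    chrT <- plantPlus(chrT, introns[i, 1L], introns[i, 2L])
  ## chrU minus-strand intron 201..500: GT/AG on the minus strand
  chrU[500] <- "C"; chrU[499] <- "A"   # donor GT (revcomp)
  chrU[202] <- "T"; chrU[201] <- "C"   # acceptor AG (revcomp)

  genome <- Biostrings::DNAStringSet(c(chrT = paste(chrT, collapse = ""),
                                       chrU = paste(chrU, collapse = "")))
  list(genome = genome, exons = toyTranscripts(), truth = toyTruth())
}

#' Write the toy annotation bundle to disk
#'
#' Writes genome FASTA, exon GTF and truth TSV, the file inputs for
#' [runAnnotationMode()].
#'
#' @param dir output directory (created if missing).
#' @param seed passed to [generateToyAnnotation()].
#' @return named list of paths (genome, gtf, truth).
#' @export
writeToyAnnotation <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- generateToyAnnotation(seed)
  genomePath <- file.path(dir, "toy_genome.fa")
  gtfPath <- file.path(dir, "toy_annotation.gtf")
  truthPath <- file.path(dir, "toy_truth.tsv")
  Biostrings::writeXStringSet(toy$genome, genomePath)
  ex <- toy$exons
  gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end),
                               strand = ex$strand)
  gr$source <- "toy"
  gr$type <- "exon"
  gr$gene_id <- ex$gene_id
  gr$transcript_id <- ex$transcript_id
  rtracklayer::export(gr, gtfPath, format = "gtf")
  writeTSV(toy$truth, truthPath)
  list(genome = genomePath, gtf = gtfPath, truth = truthPath)
}
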