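test_that("generator config validates its probability model", {
  expect_s3_class(generatorConfig(), "GeneratorConfig")
  badCore <- spliceDispersion:::defaultCoreWeights()
  badCore[, 1] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(generatorConfig(coreWeights = badCore), "sum to 1")
  noAG <- spliceDispersion:::defaultCoreWeights()
  noAG[, "-2"] <- c(0.25, 0.25, 0.25, 0.25)
  expect_error(generatorConfig(coreWeights = noAG), "fix A")
  expect_error(generatorConfig(
    injections = data.frame(pattern = "AG", from = 5, to = 30,
                            multiplier = -1, mode = "x")), "multiplier")
})

test_that("windows are deterministic, AG-anchored and pyrimidine-biased", {
  cfg <- generatorConfig(nPerMode = 200, seed = 5)
  w1 <- generateWindows(cfg, "common")
  w2 <- generateWindows(cfg, "common")
  expect_identical(as.character(windowSequences(w1)),
                   as.character(windowSequences(w2)))
  expect_identical(nWindows(w1), 200L)
  seqs <- as.character(windowSequences(w1))
  expect_true(all(nchar(seqs) == 100))
  expect_true(all(substr(seqs, 49, 50) == "AG"))   # labels -2/-1
  # different modes draw independently
  w3 <- generateWindows(cfg, "alternative")
  expect_false(identical(as.character(windowSequences(w3)), seqs))

  # empirical upstream pyrimidine fraction within a 99% binomial interval
  cfgP <- generatorConfig(nPerMode = 5000, seed = 9,
                          upstreamPyrimidine = 0.8)
  up <- substr(as.character(windowSequences(generateWindows(cfgP, "m"))),
               1, 43)
  bases <- unlist(strsplit(up, ""))
  phat <- mean(bases %in% c("C", "T"))
  half <- 2.576 * sqrt(0.8 * 0.2 / length(bases))
  expect_lt(abs(phat - 0.8), half)
})

test_that("null pairs differ only by sampling noise", {
  pair <- generateNullPair(generatorConfig(nPerMode = 500, seed = 17))
  expect_identical(nWindows(pair$a), 500L)
  expect_identical(nWindows(pair$b), 500L)
  expect_false(identical(as.character(windowSequences(pair$a)),
                         as.character(windowSequences(pair$b))))
  part <- kmerPartition(6)
  pa <- profileTable(dispersionProfile(countKmersBySite(pair$a), part))
  pb <- profileTable(dispersionProfile(countKmersBySite(pair$b), part))
  d <- abs(pa$rho[pa$subset_class == "XY1"] -
             pb$rho[pb$subset_class == "XY1"])
  # seeded Monte-Carlo envelope: max |delta rho| over 20 null replicates at
  # this N was 0.36; anything above 0.40 would signal a systematic shift
  expect_lt(max(d), 0.40)
})

test_that("injection shifts pattern counts by the multiplier and checks capacity", {
  inj <- data.frame(pattern = "AG", from = 5, to = 30, multiplier = 3,
                    mode = "inj")
  cfg <- generatorConfig(nPerMode = 1000, seed = 23, injections = inj)
  wNull <- generateWindows(cfg, "other")     # injection not targeted
  wInj <- generateWindows(cfg, "inj")
  countAG <- function(w) {
    s <- substr(as.character(windowSequences(w)),
                labelToOffset(5L) + 1L, labelToOffset(30L) + 1L)
    sum(vapply(gregexpr("AG", s), function(m) sum(m > 0), numeric(1)))
  }
  ratio <- countAG(wInj) / countAG(wNull)
  expect_gt(ratio, 2.4)
  expect_lt(ratio, 3.6)

  badInj <- data.frame(pattern = "AG", from = 5, to = 10, multiplier = 50,
                       mode = "inj")
  cfgBad <- generatorConfig(nPerMode = 10, seed = 1, injections = badInj)
  expect_error(generateWindows(cfgBad, "inj"), "infeasible")
})

test_that("toy annotation plants every mode, sub-mode and filter case", {
  toy <- generateToyAnnotation(seed = 1)
  expect_s4_class(toy$genome, "DNAStringSet")
  expect_identical(names(toy$genome), c("chrT", "chrU"))

  ev <- spliceEventsFromGTF(local({
    ex <- toy$exons
    gr <- GenomicRanges::GRanges(ex$chrom,
                                 IRanges::IRanges(ex$start, ex$end),
                                 strand = ex$strand)
    gr$type <- "exon"; gr$transcript_id <- ex$transcript_id
    gr$gene_id <- ex$gene_id
    gr
  }))
  graph <- buildSpliceGraph(ev)
  cls <- classifyAcceptors(graph, toy$exons)
  m <- merge(toy$truth, cls, by = c("chrom", "strand", "acceptor_pos"))
  expect_identical(nrow(m), nrow(toy$truth))
  expect_identical(m$mode.x, m$mode.y)
  expect_identical(m$submode.x, m$submode.y)

  # the planted GT..AG boundaries are canonical on the genome
  don <- donorSites(graph)
  for (i in seq_len(nrow(don))) {
    g <- toy$genome[[don$chrom[i]]]
    two <- if (don$strand[i] == "+")
      as.character(Biostrings::subseq(g, don$pos[i], don$pos[i] + 1))
    else as.character(Biostrings::reverseComplement(
      Biostrings::subseq(g, don$pos[i] - 1, don$pos[i])))
    expect_identical(two, "GT")
  }
})
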