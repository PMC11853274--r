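mkEvents <- function(donors, acceptors, tx = NULL, strand = "+") {
  data.frame(chrom = "c", strand = strand, donor_pos = donors,
             acceptor_pos = acceptors,
             transcript_id = if (is.null(tx))
               sprintf("t%d", seq_along(donors)) else tx)
}

test_that("splice graph deduplicates nodes and edges", {
  g <- buildSpliceGraph(mkEvents(101, 300))
  expect_identical(donorSites(g)$degree, 1L)
  expect_identical(acceptorSites(g)$degree, 1L)

  g2 <- buildSpliceGraph(mkEvents(c(101, 101), c(300, 400)))
  expect_identical(donorSites(g2)$degree, 2L)
  expect_identical(nrow(graphEdges(g2)), 2L)

  # duplicate event collapses to a single edge with pooled support
  g3 <- buildSpliceGraph(mkEvents(c(101, 101), c(300, 300), c("t1", "t2")))
  expect_identical(nrow(graphEdges(g3)), 1L)
  expect_identical(graphEdges(g3)$n_transcripts, 2L)

  bad <- mkEvents(101, 300)
  bad$donor_strand <- "+"; bad$acceptor_strand <- "-"
  expect_error(buildSpliceGraph(bad), "invalid event")
  expect_error(buildSpliceGraph(mkEvents(300, 101)), "invalid event")
})

test_that("acceptor modes follow the pairing structure", {
  # one-to-one
  g <- buildSpliceGraph(mkEvents(101, 300))
  expect_identical(classifyAcceptors(g)$mode, "common")

  # one acceptor, three donors each pairing once -> constitutive
  g <- buildSpliceGraph(mkEvents(c(101, 151, 201), c(400, 400, 400)))
  cls <- classifyAcceptors(g)
  expect_identical(cls$mode, "constitutive")
  expect_identical(cls$n_donors, 3L)

  # one donor, two acceptors -> both alternative
  g <- buildSpliceGraph(mkEvents(c(101, 101), c(300, 400)))
  expect_identical(classifyAcceptors(g)$mode,
                   c("alternative", "alternative"))

  # many-to-many -> ambiguous where both degrees exceed one
  g <- buildSpliceGraph(mkEvents(c(101, 101, 51), c(300, 400, 400)))
  cls <- classifyAcceptors(g)
  expect_identical(cls$mode[cls$acceptor_pos == 300], "alternative")
  expect_identical(cls$mode[cls$acceptor_pos == 400], "ambiguous")

  # modes partition the acceptor set
  expect_identical(sum(table(cls$mode)), nrow(cls))
})

test_that("alternative sub-modes classify against the majority junction", {
  # donor 101; reference acceptor 300 (2 transcripts, exon 301..500),
  # 260 inside the intron, 350 inside the reference exon
  ev <- mkEvents(c(101, 101, 101, 101), c(300, 300, 260, 350),
                 c("t1", "t2", "t3", "t4"))
  exons <- data.frame(
    chrom = "c", strand = "+",
    start = c(1, 301, 1, 301, 1, 261, 1, 351),
    end = c(100, 500, 100, 450, 100, 500, 100, 500),
    transcript_id = c("t1", "t1", "t2", "t2", "t3", "t3", "t4", "t4"))
  cls <- classifyAcceptors(buildSpliceGraph(ev), exons)
  expect_identical(cls$submode[cls$acceptor_pos == 300], "normal")
  expect_identical(cls$submode[cls$acceptor_pos == 260], "intronic")
  expect_identical(cls$submode[cls$acceptor_pos == 350], "exonic")

  # beyond the reference exon end -> unclassifiable
  ev2 <- rbind(ev, mkEvents(101, 600, "t5"))
  exons2 <- rbind(exons, data.frame(chrom = "c", strand = "+",
                                    start = c(1, 601), end = c(100, 700),
                                    transcript_id = "t5"))
  cls2 <- classifyAcceptors(buildSpliceGraph(ev2), exons2)
  expect_identical(cls2$submode[cls2$acceptor_pos == 600],
                   "unclassifiable")

  # tied support -> whole group unclassifiable
  evTie <- mkEvents(c(101, 101), c(300, 350), c("t1", "t4"))
  clsTie <- classifyAcceptors(buildSpliceGraph(evTie),
                              exons[exons$transcript_id %in%
                                      c("t1", "t4"), ])
  expect_true(all(clsTie$submode == "unclassifiable"))

  # without an exon model sub-modes stay NA
  clsNA <- classifyAcceptors(buildSpliceGraph(ev))
  expect_true(all(is.na(clsNA$submode[clsNA$mode == "alternative"])))
})

test_that("sub-modes respect transcription direction on the minus strand", {
  # minus strand: transcription right to left; donor 700, reference
  # acceptor 400 (exon 200..399), 450 intronic (between donor and ref),
  # 350 exonic (inside the reference downstream exon)
  ev <- mkEvents(c(700, 700, 700, 700), c(400, 400, 450, 350),
                 c("t1", "t2", "t3", "t4"), strand = "-")
  exons <- data.frame(
    chrom = "c", strand = "-",
    start = c(701, 200, 701, 250, 701, 200, 701, 200),
    end = c(800, 399, 800, 399, 800, 449, 800, 349),
    transcript_id = c("t1", "t1", "t2", "t2", "t3", "t3", "t4", "t4"))
  cls <- classifyAcceptors(buildSpliceGraph(ev), exons)
  expect_identical(cls$submode[cls$acceptor_pos == 400], "normal")
  expect_identical(cls$submode[cls$acceptor_pos == 450], "intronic")
  expect_identical(cls$submode[cls$acceptor_pos == 350], "exonic")
})

test_that("introns are inferred from GTF exons per transcript", {
  ex <- GenomicRanges::GRanges(
    "c", IRanges::IRanges(c(1, 201, 1, 201), c(100, 300, 100, 300)),
    strand = c("+", "+", "-", "-"))
  ex$type <- "exon"
  ex$transcript_id <- c("p", "p", "m", "m")
  ex$gene_id <- c("gp", "gp", "gm", "gm")
  ev <- spliceEventsFromGTF(ex)
  plus <- ev[ev$strand == "+", ]
  minus <- ev[ev$strand == "-", ]
  expect_identical(plus$donor_pos, 101L)
  expect_identical(plus$acceptor_pos, 200L)
  expect_identical(minus$donor_pos, 200L)
  expect_identical(minus$acceptor_pos, 101L)
})
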