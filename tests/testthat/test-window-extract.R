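test_that("site labels round-trip through offsets and reject label 0", {
  labels <- baseSiteLabels()
  expect_length(labels, 100)
  expect_identical(labelToOffset(c(-50L, -1L, 1L, 50L)), c(0L, 49L, 50L, 99L))
  expect_identical(offsetToLabel(labelToOffset(labels)), labels)
  expect_identical(labelToOffset(offsetToLabel(0:99)), 0:99)
  expect_error(labelToOffset(0), "invalid coordinate")
  expect_error(labelToOffset(51), "invalid coordinate")
  expect_error(offsetToLabel(100), "invalid coordinate")
  expect_length(kmerStartLabels(), 95)
})

test_that("windows extract in transcription orientation on both strands", {
  # 200-base toy contig with a planted acceptor AG at 99-100 (plus strand):
  # junction between 100 and 101
  withr::local_seed(11)
  base <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  base[99] <- "A"; base[100] <- "G"
  contig <- paste(base, collapse = "")
  genome <- Biostrings::DNAStringSet(c(toy = contig))

  evPlus <- data.frame(chrom = "toy", strand = "+", acceptor_pos = 100,
                       mode = "common", submode = "not_applicable",
                       event_id = "p1")
  wPlus <- extractWindows(genome, evPlus)
  sPlus <- as.character(windowSequences(wPlus))
  expect_identical(nchar(sPlus), 100L)
  expect_identical(substr(sPlus, 49, 50), "AG")   # labels -2/-1
  expect_true(windowInfo(wPlus)$ag_ok)
  expect_identical(sPlus, substr(contig, 51, 150))

  # same junction treated as a minus-strand acceptor at 101: the window is
  # the reverse complement of genomic [51, 150] around the junction
  evMinus <- data.frame(chrom = "toy", strand = "-", acceptor_pos = 101,
                        mode = "common", submode = "not_applicable",
                        event_id = "m1")
  base2 <- base
  base2[101] <- "C"; base2[102] <- "T"   # minus-strand AG at labels -2/-1
  genome2 <- Biostrings::DNAStringSet(c(toy = paste(base2, collapse = "")))
  wMinus <- extractWindows(genome2, evMinus)
  sMinus <- as.character(windowSequences(wMinus))
  expect_identical(substr(sMinus, 49, 50), "AG")
  expect_identical(
    sMinus,
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(substr(paste(base2, collapse = ""),
                                      51, 150))))[1])

  # insufficient context -> boundary error
  evEdge <- data.frame(chrom = "toy", strand = "+", acceptor_pos = 30,
                       mode = "common", submode = NA, event_id = "e1")
  expect_error(extractWindows(genome, evEdge), "boundary")
})

test_that("windows containing ambiguous bases are rejected by default", {
  contig <- paste(rep("ACGT", 50), collapse = "")
  sub <- paste0(substr(contig, 1, 119), "N", substr(contig, 121, 200))
  genome <- Biostrings::DNAStringSet(c(toy = sub))
  ev <- data.frame(chrom = "toy", strand = "+", acceptor_pos = 100,
                   mode = "common", submode = NA, event_id = "n1")
  expect_message(w <- extractWindows(genome, ev), "ambiguous")
  expect_identical(nWindows(w), 0L)
  wKeep <- extractWindows(genome, ev, onN = "keep")
  expect_identical(nWindows(wKeep), 1L)
})

test_that("100-bp exclusion filters follow the strict-inequality boundary", {
  ev <- data.frame(
    chrom = "c", strand = "+",
    donor_pos = c(101, 101, 501, 501, 2001, 2101),
    acceptor_pos = c(199, 200, 900, 950, 2800, 2800),
    mode = c("common", "common", "alternative", "alternative",
             "constitutive", "constitutive"),
    event_id = sprintf("e%d", 1:6))
  flt <- filterEvents(ev)
  # intron span 99 excluded, span 100 retained
  expect_identical(flt$rejected$event_id[flt$rejected$reason ==
                                           "intron_lt_100bp"], "e1")
  expect_true("e2" %in% flt$retained$event_id)
  # alternative acceptors 50 apart sharing donor 501: both removed
  expect_setequal(
    flt$rejected$event_id[flt$rejected$reason == "alt_acceptors_lt_100bp"],
    c("e3", "e4"))
  # donors of one constitutive acceptor exactly 100 apart: retained
  expect_true(all(c("e5", "e6") %in% flt$retained$event_id))
  expect_identical(nrow(flt$retained) + nrow(flt$rejected), nrow(ev))

  # close donors of a constitutive acceptor are removed symmetrically
  ev2 <- data.frame(chrom = "c", strand = "+",
                    donor_pos = c(2001, 2050), acceptor_pos = 2800,
                    mode = "constitutive", event_id = c("d1", "d2"))
  flt2 <- filterEvents(ev2)
  expect_setequal(flt2$rejected$reason, "alt_donors_lt_100bp")
  expect_identical(nrow(flt2$retained), 0L)
})

test_that("windows survive a FASTA round trip with labels", {
  w <- randomWindows(5)
  info <- windowInfo(w)
  info$mode <- c("common", "common", "alternative", "alternative",
                 "constitutive")
  info$submode <- c(NA, NA, "normal", "exonic", NA)
  w <- newAcceptorWindowSet(windowSequences(w), info)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeWindows(w, fa)
  back <- readWindows(fa)
  expect_identical(unname(as.character(windowSequences(back))),
                   unname(as.character(windowSequences(w))))
  expect_identical(windowInfo(back)$mode, info$mode)
  expect_identical(windowInfo(back)$submode,
                   ifelse(is.na(info$submode), "NA", info$submode))
})
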