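# shared fixtures built in code

# AcceptorWindowSet from plain strings (recycled mode labels)
windowsFromStrings <- function(seqs, mode = "test") {
  info <- S4Vectors::DataFrame(
    event_id = sprintf("w%03d", seq_along(seqs)),
    chrom = NA_character_, strand = NA_character_,
    acceptor_pos = NA_integer_,
    mode = rep_len(mode, length(seqs)), submode = NA_character_,
    ag_ok = NA)
  newAcceptorWindowSet(Biostrings::DNAStringSet(seqs), info)
}

# random 100-base windows (uniform bases), seeded
randomWindows <- function(n, seed = 1) {
  withr::local_seed(seed)
  windowsFromStrings(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
          collapse = ""), character(1)))
}

# textbook step-up BH, written independently of stats::p.adjust
referenceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- min(1, prev)
  }
  adj
}

# naive per-sequence substring 6-mer counter (independent oracle)
naiveCountKmers <- function(seqs, k = 6) {
  vocab <- enumerateKmers(k)
  nSites <- nchar(seqs[1]) - k + 1
  counts <- matrix(0L, nrow = nSites, ncol = length(vocab))
  for (s in seqs) {
    for (j in seq_len(nSites)) {
      w <- substr(s, j, j + k - 1)
      r <- match(w, vocab)
      counts[j, r] <- counts[j, r] + 1L
    }
  }
  counts
}
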