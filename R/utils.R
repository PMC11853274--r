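DNA_BASES <- c("A", "C", "G", "T")

#' Population standard deviation
#'
#' Divide-by-n standard deviation, used for both numerator and denominator of
#' the dispersion ratio (consistency is what matters; the n vs n-1 choice
#' cancels in the ratio).
#'
#' @param x numeric vector.
#' @return sqrt(mean((x - mean(x))^2)).
#' @keywords internal
popSd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

## Deterministic sub-seed derivation; keeps results < 2^31 so they are valid
## R integer seeds.
subSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

stopIfNotBases <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop("invalid ", what, ": non-ACGT character in ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

## All 16 dinucleotides in fixed (lexicographic) order AA, AC, ..., TT.
allDinucleotides <- function() {
  as.vector(t(outer(DNA_BASES, DNA_BASES, paste0)))
}

checkPattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) != 2L)
    stop("pattern must be a single two-character string", call. = FALSE)
  stopIfNotBases(pattern, "pattern")
  pattern
}
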