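## Region-wise comparison of dispersion profiles between splicing modes:
## paired t-tests across sites, BH-FDR over the per-region family, star
## annotation, and the three-way significance grouping.

#' Region specification
#'
#' A named inclusive interval of zero-skipping site labels. The defaults
#' follow the statistical analysis: upstream -50..-7 (44 sites), core
#' -6..+1 (7 sites), downstream +2..+45 (44 sites), giving paired-t degrees
#' of freedom 43 / 6 / 43.
#'
#' @param name region name.
#' @param from,to inclusive site-label bounds within -50..+45 (no 0).
#' @return a one-row data.frame with columns name, from, to.
#' @examples
#' regionSpec("upstream", -50, -7)
#' @export
regionSpec <- function(name, from, to) {
  lab <- kmerStartLabels()
  if (!from %in% lab || !to %in% lab || from > to)
    stop("invalid region: bounds must be k-mer start labels in -50..+45",
         call. = FALSE)
  data.frame(name = name, from = as.integer(from), to = as.integer(to))
}

#' @rdname regionSpec
#' @export
defaultRegions <- function() {
  rbind(regionSpec("upstream", -50L, -7L),
        regionSpec("core", -6L, 1L),
        regionSpec("downstream", 2L, 45L))
}

#' @rdname regionSpec
#' @param region a one-row region data.frame.
#' @return \code{regionSites()}: the site labels falling in the region.
#' @export
regionSites <- function(region) {
  lab <- kmerStartLabels()
  lab[lab >= region$from & lab <= region$to]
}

#' Paired t-test across sites
#'
#' Classical paired t on the differences d = x - y with df = length - 1 and
#' a two-sided p-value. Degenerate cases follow fixed conventions: all-zero
#' differences give t = 0, p = 1; zero-variance differences with nonzero
#' mean give t = +/-Inf, p = 0.
#'
#' @param x,y numeric vectors of per-site values in the same site order.
#' @return list with elements t, df, p.
#' @examples
#' pairedT(c(2, 4, 6), c(1, 2, 3))  # t = 2 / (1/sqrt(3)), df = 2
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  d <- x - y
  n <- length(d)
  md <- mean(d)
  sd_ <- stats::sd(d)
  if (sd_ == 0) {
    if (md == 0) return(list(t = 0, df = n - 1L, p = 1))
    return(list(t = sign(md) * Inf, df = n - 1L, p = 0))
  }
  t <- md / (sd_ / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), df = n - 1L))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (monotone, capped at 1, original order
#' restored), with input validation.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("invalid parameter: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Significance stars
#'
#' Maps an adjusted p-value to the conventional categories, boundaries
#' inclusive: \code{****} for p <= 0.0001, \code{***} for p <= 0.001,
#' \code{**} for p <= 0.01, \code{*} for p <= 0.05, else \code{ns}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return character vector of categories.
#' @examples
#' starsFromP(c(0.03, 0.05, 0.2))  # "*" "*" "ns"
#' @export
starsFromP <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("invalid parameter: p-values must lie in [0, 1]", call. = FALSE)
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

## rho values of one profile for (pattern, class) over given sites, in order
rhoVector <- function(profile, pattern, sites, subsetClass) {
  tab <- profile@table
  sel <- tab$pattern == pattern & tab$subset_class == subsetClass &
    tab$site %in% sites
  v <- tab[sel, ]
  v$rho[match(sites, v$site)]
}

#' Compare splicing modes region by region
#'
#' For one region and every dinucleotide pattern, runs a paired t-test on
#' the per-site dispersion values between every unordered pair of modes,
#' adjusts p-values by Benjamini-Hochberg over the whole family (all 16
#' patterns x all mode pairs within the region), annotates stars and
#' assigns each pattern a significance group: \code{A} if all three pairwise
#' comparisons are significant, \code{C} if none is, \code{B} otherwise
#' (some but not all pairs significant; with three modes this is the "one
#' mode distinguished from the others" case).
#'
#' @param profiles named list of [DispersionProfile-class], one per mode
#'   (>= 2 modes, identical site grids).
#' @param region one-row region data.frame from [regionSpec()].
#' @param subsetClass subset class to compare, default \code{"XY1"}.
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @return data.frame with columns pattern, region, mode_a, mode_b, t, df,
#'   p_raw, p_adj, stars, group.
#' @export
compareModes <- function(profiles, region, subsetClass = "XY1",
                         alpha = 0.05) {
  stopifnot(is.list(profiles), length(profiles) >= 2L,
            !is.null(names(profiles)))
  grids <- lapply(profiles, siteLabels)
  for (g in grids[-1L])
    if (!identical(g, grids[[1L]]))
      stop("alignment error: profiles have different site grids",
           call. = FALSE)
  sites <- regionSites(region)
  if (!all(sites %in% grids[[1L]]))
    stop("alignment error: region sites missing from profiles",
         call. = FALSE)

  modes <- names(profiles)
  pairs <- utils::combn(modes, 2L)
  pats <- sort(unique(profiles[[1L]]@table$pattern))
  rows <- list()
  for (pat in pats) {
    vecs <- lapply(profiles, rhoVector, pattern = pat, sites = sites,
                   subsetClass = subsetClass)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      tt <- pairedT(vecs[[a]], vecs[[b]])
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = pat, region = region$name, mode_a = a, mode_b = b,
        t = tt$t, df = tt$df, p_raw = tt$p)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bhAdjust(res$p_raw)
  res$stars <- starsFromP(res$p_adj)
  nsig <- tapply(res$p_adj <= alpha, res$pattern, sum)
  npair <- ncol(pairs)
  grp <- ifelse(nsig == npair, "A", ifelse(nsig == 0L, "C", "B"))
  res$group <- grp[res$pattern]
  rownames(res) <- NULL
  res
}

#' Run mode comparisons for several regions
#'
#' Convenience wrapper applying [compareModes()] to each region (each region
#' is its own FDR family).
#'
#' @inheritParams compareModes
#' @param regions data.frame of regions, default [defaultRegions()].
#' @return row-bound comparison table across regions.
#' @export
compareModesByRegion <- function(profiles, regions = defaultRegions(),
                                 subsetClass = "XY1", alpha = 0.05) {
  do.call(rbind, lapply(seq_len(nrow(regions)), function(i)
    compareModes(profiles, regions[i, , drop = FALSE],
                 subsetClass = subsetClass, alpha = alpha)))
}

#' Summarise significance groups per pattern and region
#'
#' @param results output of [compareModes()] or [compareModesByRegion()].
#' @return data.frame with one row per (region, pattern) and its group.
#' @export
significanceGroups <- function(results) {
  u <- unique(results[, c("region", "pattern", "group")])
  rownames(u) <- NULL
  u[order(u$region, u$pattern), ]
}
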