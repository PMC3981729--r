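#' Intra-chromosomal pairwise r2 with permutation significance
#'
#' For every same-chromosome pair of mapped markers, r2 is the squared
#' Pearson correlation of the two 0/1 call vectors over genotypes
#' non-missing at both markers (under haploid scoring this equals the
#' haplotype-count statistic `D^2/(pA*pa*pB*pb)`). Comparison-wise
#' significance comes from permutations of one marker's complete-case
#' calls: `p = (1 + #{r2_perm >= r2_obs}) / (1 + nPerm)`. Pairs whose
#' complete-case columns are monomorphic, or with fewer than `minN`
#' comparable genotypes, are skipped (counted in the `"skipped"`
#' attribute). Pairs more than 50 cM apart are flagged unlinked
#' (strictly greater: a pair at exactly 50 cM is linked).
#'
#' @param panel a [DartPanel-class].
#' @param map genetic map; defaults to the panel annotation.
#' @param nPerm permutations per pair.
#' @param seed integer seed for the permutation stream.
#' @param minN minimum complete-case genotypes per pair.
#' @param markers optional marker subset.
#' @param genotypes optional genotype subset (e.g. one structure group).
#' @return data.frame, one row per retained pair: `markerA`, `markerB`,
#'   `chrom`, `dist`, `r2`, `p`, `n`, `significant` (p < 0.05),
#'   `unlinked` (dist > 50). Attribute `"skipped"` counts dropped pairs.
#' @export
pairR2 <- function(panel, map = markerMap(panel), nPerm = 1000L,
                   seed = NULL, minN = 4L, markers = NULL,
                   genotypes = NULL) {
  map <- validateMap(map)
  x <- markerCalls(panel)
  if (!is.null(genotypes)) x <- x[genotypes, , drop = FALSE]
  if (!is.null(markers)) map <- map[map$marker %in% markers, , drop = FALSE]
  map <- map[map$marker %in% colnames(x), , drop = FALSE]
  map <- map[order(map$chrom, map$pos, map$marker), , drop = FALSE]
  pairs <- do.call(rbind, lapply(split(seq_len(nrow(map)), map$chrom),
    function(idx) {
      if (length(idx) < 2) return(NULL)
      cbind(rep(idx, times = rev(seq_along(idx)) - 1),
            unlist(lapply(seq_along(idx)[-length(idx)],
                          function(i) idx[(i + 1):length(idx)])))
    }))
  if (is.null(pairs) || !nrow(pairs)) stop("no intra-chromosomal pairs")
  ia <- match(map$marker[pairs[, 1]], colnames(x))
  ib <- match(map$marker[pairs[, 2]], colnames(x))
  if (!is.null(seed)) set.seed(seed)
  res <- .pair_r2_perm(x, ia, ib, as.integer(nPerm))
  out <- data.frame(markerA = map$marker[pairs[, 1]],
                    markerB = map$marker[pairs[, 2]],
                    chrom = map$chrom[pairs[, 1]],
                    dist = abs(map$pos[pairs[, 2]] - map$pos[pairs[, 1]]),
                    r2 = res$r2, p = res$p, n = res$n,
                    stringsAsFactors = FALSE)
  skip <- !is.finite(out$r2) | out$n < minN
  out <- out[!skip, , drop = FALSE]
  rownames(out) <- NULL
  out$significant <- out$p < 0.05
  out$unlinked <- out$dist > 50
  attr(out, "skipped") <- sum(skip)
  out
}

#' Background LD from unlinked pairs
#'
#' The 95th percentile (linear interpolation between order statistics,
#' [stats::quantile()] type 7) of r2 among pairs more than 50 cM apart.
#'
#' @param pairs data.frame from [pairR2()].
#' @param minUnlinked minimum number of unlinked pairs required.
#' @param probs percentile, default 0.95.
#' @return background r2 level.
#' @export
backgroundLd <- function(pairs, minUnlinked = 20L, probs = 0.95) {
  u <- pairs$r2[pairs$unlinked]
  if (length(u) < minUnlinked)
    stop("only ", length(u), " unlinked pairs (> 50 cM); ",
         "simulate a longer map or pool chromosomes")
  unname(stats::quantile(u, probs = probs, type = 7))
}

#' LD decay from a loess fit against the background level
#'
#' Fits a locally weighted quadratic (degree-2, tricube weights)
#' regression of r2 on distance over the significant pairs, evaluates it
#' on a regular grid from 0 to the maximum pair distance, and reports
#' the smallest grid distance at which the fitted curve falls to or
#' below the background level. When the curve stays above background
#' over the whole grid the result records no intercept together with
#' the curve's terminal extent.
#'
#' @param pairs data.frame of significant pairs (rows of [pairR2()]
#'   output with `significant == TRUE`; non-significant rows are
#'   dropped here as a convenience).
#' @param background background r2 from [backgroundLd()].
#' @param span loess span.
#' @param gridStep evaluation grid step in cM.
#' @param minPairs minimum number of significant pairs required.
#' @return list of class `"ldDecay"`: `decayCM` (`NA` when no
#'   intercept), `noIntercept`, `maxExtent` (largest fitted distance),
#'   `background`, `span`, `curve` (data.frame `dist`, `r2`).
#' @export
fitDecay <- function(pairs, background, span = 0.5, gridStep = 0.5,
                     minPairs = 30L) {
  sig <- if ("significant" %in% names(pairs))
    pairs[pairs$significant %in% TRUE, , drop = FALSE] else pairs
  if (nrow(sig) < minPairs)
    stop("only ", nrow(sig), " significant pairs; need >= ", minPairs)
  if (length(unique(sig$dist)) < 2) stop("degenerate fit: all distances equal")
  fit <- stats::loess(r2 ~ dist, data = sig, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(0, max(sig$dist), by = gridStep)
  yhat <- stats::predict(fit, newdata = data.frame(dist = grid))
  below <- which(yhat <= background)
  decay <- if (length(below)) grid[below[1]] else NA_real_
  structure(list(decayCM = decay, noIntercept = !length(below),
                 maxExtent = max(grid), background = background,
                 span = span,
                 curve = data.frame(dist = grid, r2 = yhat)),
            class = "ldDecay")
}

#' @export
print.ldDecay <- function(x, ...) {
  if (x$noIntercept)
    cat(sprintf("LD decay: no intercept (curve above background %.4f up to %.1f cM)\n",
                x$background, x$maxExtent))
  else
    cat(sprintf("LD decay: %.1f cM (background r2 = %.4f)\n",
                x$decayCM, x$background))
  invisible(x)
}

#' Stratified LD summaries and adjacent-pair profile
#'
#' Mean r2 per chromosome, per genome and whole-genome, over all pairs
#' and over significant pairs only, with pair counts; plus the
#' adjacent-pair profile (each marker paired with its map successor,
#' plotted at the proximal locus). Chromosomes with no retained pairs
#' are reported with `NA` means.
#'
#' @param pairs data.frame from [pairR2()].
#' @param map genetic map (for the chromosome roster and adjacency).
#' @return list with data.frames `perChromosome`, `perGenome`,
#'   `wholeGenome` (columns `nPairs`, `nSignificant`, `nUnlinked`,
#'   `meanR2`, `meanR2Significant`) and `adjacentProfile` (`chrom`,
#'   `pos`, `markerA`, `markerB`, `r2`).
#' @export
ldSummaries <- function(pairs, map) {
  map <- validateMap(map)
  strat <- function(sel) {
    r <- pairs$r2[sel]
    s <- pairs$significant[sel]
    data.frame(nPairs = sum(sel), nSignificant = sum(s),
               nUnlinked = sum(pairs$unlinked[sel]),
               meanR2 = if (any(sel)) mean(r) else NA_real_,
               meanR2Significant = if (any(s)) mean(r[s]) else NA_real_)
  }
  chroms <- sort(unique(map$chrom))
  perChrom <- do.call(rbind, lapply(chroms, function(ch)
    cbind(chrom = ch, strat(pairs$chrom == ch))))
  genomes <- sort(unique(substring(chroms, 2, 2)))
  perGenome <- do.call(rbind, lapply(genomes, function(g)
    cbind(genome = g, strat(substring(pairs$chrom, 2, 2) == g))))
  whole <- strat(rep(TRUE, nrow(pairs)))
  map <- map[order(map$chrom, map$pos), , drop = FALSE]
  key <- paste(pairs$markerA, pairs$markerB)
  key2 <- paste(pairs$markerB, pairs$markerA)
  adj <- do.call(rbind, lapply(split(map, map$chrom), function(m) {
    if (nrow(m) < 2) return(NULL)
    a <- m$marker[-nrow(m)]; b <- m$marker[-1]
    hit <- match(paste(a, b), key)
    alt <- match(paste(a, b), key2)
    hit[is.na(hit)] <- alt[is.na(hit)]
    data.frame(chrom = m$chrom[1], pos = m$pos[-nrow(m)],
               markerA = a, markerB = b,
               r2 = ifelse(is.na(hit), NA_real_, pairs$r2[hit]),
               stringsAsFactors = FALSE)
  }))
  rownames(adj) <- NULL
  list(perChromosome = perChrom, perGenome = perGenome,
       wholeGenome = whole, adjacentProfile = adj)
}
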