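#' Genetic-map coverage summary
#'
#' Per-chromosome gap statistics and per-genome marker tallies for a
#' mapped marker set. Gaps are successive position differences within a
#' chromosome (chromosomes with fewer than two markers contribute no
#' gaps); genome membership follows the chromosome suffix letter.
#'
#' @param map data.frame with columns `marker`, `chrom`, `pos`
#'   (see [readMapTable()]).
#' @return list with `genomeCounts`, `genomeFractions` (named by A/B/D,
#'   summing to 1), `gaps` (data.frame `chrom`, `from`, `to`, `gap`,
#'   sorted by decreasing gap), `nGapsOver10`, `nGapsOver50`,
#'   `fracIntervalsUnder10`, and a per-chromosome table `perChromosome`.
#' @export
summarizeCoverage <- function(map) {
  map <- validateMap(map)
  if (!nrow(map)) stop("empty map")
  genome <- substring(map$chrom, 2, 2)
  genomeCounts <- table(factor(genome, levels = c("A", "B", "D")))
  genomeCounts <- stats::setNames(as.integer(genomeCounts),
                                  names(genomeCounts))
  gaps <- do.call(rbind, lapply(split(map, map$chrom), function(m) {
    if (nrow(m) < 2) return(NULL)
    p <- sort(m$pos)
    data.frame(chrom = m$chrom[1], from = p[-length(p)], to = p[-1],
               gap = diff(p), stringsAsFactors = FALSE)
  }))
  if (is.null(gaps))
    gaps <- data.frame(chrom = character(), from = numeric(),
                       to = numeric(), gap = numeric())
  gaps <- gaps[order(-gaps$gap), , drop = FALSE]
  rownames(gaps) <- NULL
  perChrom <- do.call(rbind, lapply(split(map, map$chrom), function(m) {
    g <- if (nrow(m) >= 2) diff(sort(m$pos)) else numeric(0)
    data.frame(chrom = m$chrom[1], nMarkers = nrow(m),
               span = diff(range(m$pos)),
               maxGap = if (length(g)) max(g) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(perChrom) <- NULL
  list(genomeCounts = genomeCounts,
       genomeFractions = genomeCounts / sum(genomeCounts),
       gaps = gaps,
       nGapsOver10 = sum(gaps$gap > 10),
       nGapsOver50 = sum(gaps$gap > 50),
       fracIntervalsUnder10 = if (nrow(gaps)) mean(gaps$gap <= 10) else NA_real_,
       perChromosome = perChrom)
}

#' Per-marker descriptive statistics
#'
#' Band frequency, polymorphism, polymorphism information content and
#' rare/private flags for every marker. The band frequency f is the
#' proportion of band-present calls among non-missing calls; a marker is
#' polymorphic when both states are observed; PIC for a dominant
#' biallelic marker under the homozygosity assumption is `2*f*(1-f)`
#' (equivalently `1 - f^2 - (1-f)^2`). A marker is rare when the band
#' occurs in at most `rareThreshold` genotypes (at least one), private
#' when it occurs in exactly one. Markers with all calls missing are
#' flagged unassessable and excluded from these definitions.
#'
#' @param panel a [DartPanel-class] with at least two genotypes.
#' @param rareThreshold integer, maximum carrier count of a rare band.
#' @return data.frame, one row per marker: `marker`, `nPresent`,
#'   `nCalled`, `freq`, `polymorphic`, `pic`, `rare`, `private`,
#'   `unassessable`.
#' @export
markerStatistics <- function(panel, rareThreshold = 5L) {
  x <- markerCalls(panel)
  if (nrow(x) < 2) stop("need at least two genotypes")
  nCalled <- colSums(!is.na(x))
  nPresent <- colSums(x == 1L, na.rm = TRUE)
  f <- ifelse(nCalled > 0, nPresent / nCalled, NA_real_)
  unass <- nCalled == 0
  poly <- !unass & nPresent > 0 & nPresent < nCalled
  data.frame(marker = colnames(x), nPresent = nPresent, nCalled = nCalled,
             freq = f, polymorphic = poly, pic = 2 * f * (1 - f),
             rare = !unass & nPresent >= 1 & nPresent <= rareThreshold,
             private = !unass & nPresent == 1,
             unassessable = unass, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Group-private marker counts
#'
#' A marker is private to a group when every genotype carrying the band
#' (among non-missing calls) belongs to that group and at least one
#' carrier exists.
#'
#' @param panel a [DartPanel-class].
#' @param labels genotype-to-group labels (named character); defaults to
#'   `genotypeGroups(panel)`.
#' @return list with `counts` (named integer per group) and `markers`
#'   (named list of private marker ids per group).
#' @export
privateMarkersByGroup <- function(panel, labels = genotypeGroups(panel)) {
  x <- markerCalls(panel)
  if (is.null(labels)) stop("no group labels given or stored in the panel")
  miss <- setdiff(rownames(x), names(labels))
  if (length(miss)) stop("unlabeled genotype: ", miss[1])
  labels <- labels[rownames(x)]
  groups <- sort(unique(labels))
  carrier <- x == 1L    # NA where missing
  out <- lapply(groups, function(g) {
    ing <- labels == g
    nIn <- colSums(carrier[ing, , drop = FALSE], na.rm = TRUE)
    nOut <- colSums(carrier[!ing, , drop = FALSE], na.rm = TRUE)
    colnames(x)[nIn >= 1 & nOut == 0]
  })
  names(out) <- groups
  list(counts = vapply(out, length, integer(1)), markers = out)
}
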