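#' Configuration for synthetic dominant-marker panels
#'
#' Describes the panel the generator emulates: a collection of
#' homozygous (haploid-scored) genotypes in one or more subpopulations,
#' genotyped at mapped dominant markers. Defaults reproduce the study
#' conditions the package is calibrated against: 92 genotypes in two
#' groups of 26 and 66, ~1,400 markers on the 21 wheat chromosomes with
#' the usual B > A > D genome asymmetry (96/66/38 markers per B/A/D
#' chromosome), genome-wide differentiation Fst = 0.13, one strongly
#' differentiated block on chromosome 2D (a dwarfing-locus analogue),
#' a 67 cM marker gap on 4D, and 3% missing calls.
#'
#' @param groupSizes integer vector of subpopulation sizes.
#' @param fst differentiation parameter in `[0, 1)` of the
#'   Balding-Nichols model.
#' @param markersPerChromosome named integer vector (names from
#'   [wheatChromosomes]); default as described above.
#' @param chromosomeLengths named numeric vector of map lengths in cM;
#'   default 160 cM per chromosome.
#' @param selectedBlock `"default"` for the built-in 2D block (only when
#'   there are two groups), `NULL` for none, or a list with elements
#'   `chrom`, `start`, `end` (cM) and `freq` (per-group band
#'   frequencies inside the block).
#' @param missingRate probability that a call is missing, in `[0, 1)`.
#' @param gap4D numeric(2) interval kept free of markers on 4D, or
#'   `NULL` for no gap.
#' @param seed integer seed; all randomness in [simulatePanel()] and
#'   [simulateLdBlock()] flows from it.
#' @return A list of class `"simConfig"`.
#' @seealso [simulatePanel()], [simulateLdBlock()]
#' @export
simConfig <- function(groupSizes = c(26L, 66L), fst = 0.13,
                      markersPerChromosome = NULL,
                      chromosomeLengths = NULL,
                      selectedBlock = "default",
                      missingRate = 0.03, gap4D = c(60, 127), seed = 1L) {
  groupSizes <- as.integer(groupSizes)
  if (length(groupSizes) < 1 || any(groupSizes < 1) || sum(groupSizes) < 2)
    stop("groupSizes must be positive with total >= 2")
  if (!is.finite(fst) || fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must be in [0, 1)")
  if (is.null(markersPerChromosome)) {
    genome <- substring(wheatChromosomes, 2, 2)
    markersPerChromosome <- stats::setNames(
      c(A = 66L, B = 96L, D = 38L)[genome], wheatChromosomes)
  }
  if (is.null(names(markersPerChromosome)))
    stop("markersPerChromosome must be named by chromosome")
  if (!all(names(markersPerChromosome) %in% wheatChromosomes))
    stop("unknown chromosome in markersPerChromosome")
  if (is.null(chromosomeLengths))
    chromosomeLengths <- stats::setNames(
      rep(160, length(markersPerChromosome)), names(markersPerChromosome))
  if (!all(names(markersPerChromosome) %in% names(chromosomeLengths)))
    stop("chromosomeLengths must cover every simulated chromosome")
  if (identical(selectedBlock, "default"))
    selectedBlock <- if (length(groupSizes) == 2 &&
                         "2D" %in% names(markersPerChromosome))
      list(chrom = "2D", start = 15, end = 35, freq = c(0.9, 0.1))
    else NULL
  if (!is.null(selectedBlock)) {
    sb <- selectedBlock
    if (!all(c("chrom", "start", "end", "freq") %in% names(sb)))
      stop("selectedBlock needs chrom, start, end, freq")
    if (!sb$chrom %in% names(markersPerChromosome))
      stop("selectedBlock chromosome not simulated: ", sb$chrom)
    if (length(sb$freq) != length(groupSizes))
      stop("selectedBlock$freq needs one frequency per group")
    if (any(sb$freq < 0 | sb$freq > 1))
      stop("selectedBlock frequencies must lie in [0, 1]")
    if (sb$start < 0 || sb$end > chromosomeLengths[[sb$chrom]] ||
        sb$start >= sb$end)
      stop("selectedBlock interval outside chromosome")
  }
  structure(list(groupSizes = groupSizes, fst = fst,
                 markersPerChromosome = markersPerChromosome,
                 chromosomeLengths = chromosomeLengths,
                 selectedBlock = selectedBlock,
                 missingRate = missingRate, gap4D = gap4D,
                 seed = as.integer(seed)),
            class = "simConfig")
}

# uniform marker positions, sorted; 4D optionally keeps a marker desert
simulateMapFromConfig <- function(config) {
  out <- lapply(names(config$markersPerChromosome), function(ch) {
    nm <- config$markersPerChromosome[[ch]]
    L <- config$chromosomeLengths[[ch]]
    pos <- stats::runif(nm, 0, L)
    if (ch == "4D" && !is.null(config$gap4D) && L > diff(config$gap4D)) {
      width <- diff(config$gap4D)
      u <- stats::runif(nm, 0, L - width)
      pos <- ifelse(u > config$gap4D[1], u + width, u)
    }
    pos <- sort(pos)
    data.frame(marker = sprintf("m%s.%03d", ch, seq_len(nm)),
               chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a differentiated dominant-marker panel
#'
#' Balding-Nichols generator: each marker draws an ancestral band
#' frequency p uniformly on `[0.05, 0.95]`; each group's frequency comes
#' from a Beta distribution with mean p and variance `p(1-p)*fst`
#' (identical to p when `fst = 0`); each genotype's band is a single
#' Bernoulli draw from its group frequency (haploid scoring for
#' homozygous selfing lines). Markers inside the selected block override
#' the group frequencies with the configured values; calls are masked
#' missing independently at `missingRate`.
#'
#' @param config a [simConfig()].
#' @return A [DartPanel-class] with map annotation, truth group labels
#'   in `colData$group`, and the per-marker per-group truth frequencies
#'   in `metadata(panel)$truthFreqs`.
#' @examples
#' cfg <- simConfig(groupSizes = c(5, 5),
#'                  markersPerChromosome = c("1A" = 20), seed = 7)
#' simulatePanel(cfg)
#' @export
simulatePanel <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  map <- simulateMapFromConfig(config)
  G <- length(config$groupSizes)
  n <- sum(config$groupSizes)
  L <- nrow(map)
  labels <- rep(paste0("G", seq_len(G)), times = config$groupSizes)
  genotypes <- sprintf("gt%03d", seq_len(n))

  p <- stats::runif(L, 0.05, 0.95)
  freqs <- matrix(p, L, G)
  if (config$fst > 0) {
    shape <- (1 - config$fst) / config$fst
    for (g in seq_len(G))
      freqs[, g] <- stats::rbeta(L, p * shape, (1 - p) * shape)
  }
  sb <- config$selectedBlock
  if (!is.null(sb)) {
    inblk <- map$chrom == sb$chrom & map$pos >= sb$start & map$pos <= sb$end
    for (g in seq_len(G)) freqs[inblk, g] <- sb$freq[g]
  }

  gidx <- rep(seq_len(G), times = config$groupSizes)
  calls <- matrix(0L, n, L, dimnames = list(genotypes, map$marker))
  for (i in seq_len(n))
    calls[i, ] <- stats::rbinom(L, 1L, freqs[, gidx[i]])
  if (config$missingRate > 0)
    calls[stats::runif(n * L) < config$missingRate] <- NA_integer_

  panel <- DartPanel(calls, map = map,
                     groups = stats::setNames(labels, genotypes))
  S4Vectors::metadata(panel)$truthFreqs <-
    matrix(freqs, L, G, dimnames = list(map$marker, paste0("G", seq_len(G))))
  S4Vectors::metadata(panel)$config <- config
  panel
}

#' Simulate a panel with distance-dependent linkage disequilibrium
#'
#' Each chromosome is a stationary symmetric two-state Markov walk along
#' the map, run independently per genotype: the first marker is
#' Bernoulli(1/2) and each subsequent marker copies its left neighbour
#' except for a switch with probability `(1 - exp(-2*lambda*d))/2` over
#' an inter-marker gap of d cM. The implied squared allele-frequency
#' correlation decays as `rho2(d) = exp(-c*d)` with `c = 4*lambda`;
#' `lambda` is calibrated so that `rho2(dRef) = blockR2`. Setting
#' `switchProb` overrides the calibration with a fixed per-step switch
#' probability (0 gives perfect linkage, 0.5 independent markers).
#'
#' This is a testing device for the decay estimator, not a model of real
#' haplotype structure.
#'
#' @param config a [simConfig()]; group structure is ignored (one
#'   homogeneous population of `sum(groupSizes)` genotypes).
#' @param blockR2 target squared correlation at the reference distance.
#' @param dRef reference distance in cM.
#' @param switchProb optional fixed switch probability in `[0, 0.5]`.
#' @return A [DartPanel-class] with map annotation;
#'   `metadata(panel)$decayRate` stores the calibrated `c`.
#' @seealso [ldDecayTarget()], [fitDecay()]
#' @export
simulateLdBlock <- function(config, blockR2 = 0.05, dRef = 50,
                            switchProb = NULL) {
  stopifnot(inherits(config, "simConfig"))
  if (is.null(switchProb)) {
    if (blockR2 <= 0 || blockR2 > 1 || dRef <= 0)
      stop("blockR2 must be in (0, 1] and dRef positive")
    cc <- -log(blockR2) / dRef
    if (!is.finite(cc)) stop("non-finite decay calibration")
  } else {
    if (switchProb < 0 || switchProb > 0.5)
      stop("switchProb must lie in [0, 0.5]")
    cc <- NA_real_
  }
  set.seed(config$seed)
  map <- simulateMapFromConfig(config)
  n <- sum(config$groupSizes)
  genotypes <- sprintf("gt%03d", seq_len(n))
  calls <- matrix(0L, n, nrow(map), dimnames = list(genotypes, map$marker))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    state <- stats::rbinom(n, 1L, 0.5)
    calls[, idx[1]] <- state
    for (j in seq_along(idx)[-1]) {
      d <- pos[j] - pos[j - 1]
      s <- if (is.null(switchProb)) (1 - exp(-cc / 2 * d)) / 2 else switchProb
      flip <- stats::rbinom(n, 1L, s)
      state <- ifelse(flip == 1L, 1L - state, state)
      calls[, idx[j]] <- state
    }
  }
  if (config$missingRate > 0)
    calls[stats::runif(length(calls)) < config$missingRate] <- NA_integer_
  panel <- DartPanel(calls, map = map)
  S4Vectors::metadata(panel)$decayRate <- cc
  S4Vectors::metadata(panel)$config <- config
  panel
}

#' Calibrated LD-decay crossing distance
#'
#' For a walk generated by [simulateLdBlock()] the implied correlation
#' curve is `rho2(d) = exp(-c*d)`; the distance at which it falls to a
#' background level b is `-log(b)/c`. Used as the ground truth in decay
#' recovery experiments.
#'
#' @param background background r2 level in `(0, 1)`.
#' @param blockR2,dRef the calibration passed to [simulateLdBlock()].
#' @return distance in cM.
#' @export
ldDecayTarget <- function(background, blockR2 = 0.05, dRef = 50) {
  stopifnot(background > 0, background < 1)
  cc <- -log(blockR2) / dRef
  -log(background) / cc
}
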