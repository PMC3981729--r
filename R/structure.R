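#' Fit the Bayesian admixture model by Gibbs sampling
#'
#' Clusters haploid-scored dominant markers into K ancestral
#' populations. Latent origins z, band frequencies p (Beta(1,1) prior)
#' and memberships q (symmetric Dirichlet(alpha) prior) are Gibbs
#' sampled; alpha gets a reflected Metropolis random walk with a uniform
#' prior on (0, `alphaMax`]. Missing cells contribute no likelihood and
#' are skipped. The model evidence ln Pr(X|K) is estimated from the
#' recorded data log-likelihoods as `mean - var/2`.
#'
#' @param panel a [DartPanel-class]; optionally subset to a pruned
#'   marker set first (see [pruneByLd()]).
#' @param K number of ancestral populations (`>= 1`).
#' @param burnin,iters burn-in and sampling iterations.
#' @param thin record every `thin`-th post-burn-in iteration.
#' @param seed integer seed, or `NULL` to continue the session RNG.
#' @param markers optional character vector restricting the run to a
#'   marker subset.
#' @param alphaSd,alphaMax Metropolis proposal sd and prior upper bound
#'   for alpha.
#' @return A [StructureFit-class].
#' @examples
#' cfg <- simConfig(groupSizes = c(6, 6),
#'                  markersPerChromosome = c("1A" = 40), seed = 3)
#' fit <- runAdmixture(simulatePanel(cfg), K = 2,
#'                     burnin = 200, iters = 200, seed = 3)
#' fit
#' @export
runAdmixture <- function(panel, K, burnin = 9999L, iters = 9999L,
                         thin = 10L, seed = NULL, markers = NULL,
                         alphaSd = 0.25, alphaMax = 10) {
  x <- markerCalls(panel)
  if (!is.null(markers)) x <- x[, markers, drop = FALSE]
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(x)) stop("K exceeds the number of genotypes")
  if (burnin < 1 || iters < 1) stop("burnin and iters must be positive")
  if (nrow(x) < 2) stop("need at least two genotypes")
  if (!is.null(seed)) set.seed(seed)
  res <- .admixture_gibbs(x, as.integer(K), as.integer(burnin),
                          as.integer(iters), as.integer(thin),
                          1.0, alphaSd, alphaMax)
  ll <- res$loglik
  v <- if (length(ll) > 1) stats::var(ll) else 0
  q <- res$q
  dimnames(q) <- list(rownames(x), paste0("K", seq_len(K)))
  p <- res$p
  dimnames(p) <- list(paste0("K", seq_len(K)), colnames(x))
  methods::new("StructureFit", K = as.integer(K), q = q, p = p,
               alphaTrace = as.numeric(res$alpha), loglik = as.numeric(ll),
               lnEvidence = mean(ll) - v / 2,
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Evanno delta-K model selection
#'
#' Summarizes replicate admixture runs across a range of K by the
#' second-order rate of change of the estimated ln Pr(X|K):
#' `L'(K) = L(K) - L(K-1)`, `L''(K) = L'(K+1) - L'(K)` on the replicate
#' means, and `deltaK = |L''(K)| / sd(L(K))`. deltaK is defined for
#' interior K only; where the replicate standard deviation is zero it is
#' reported missing and excluded from the argmax.
#'
#' @param fits list of [StructureFit-class] objects, replicates over a
#'   contiguous range of K (at least 3 replicates per K recommended).
#' @return list with `table` (data.frame `K`, `nReps`, `meanLnE`,
#'   `sdLnE`, `l1`, `l2`, `deltaK`) and `bestK` (argmax of deltaK over
#'   interior K, `NA` if undefined everywhere).
#' @export
selectKEvanno <- function(fits) {
  Ks <- vapply(fits, function(f) f@K, integer(1))
  lnE <- vapply(fits, lnEvidence, numeric(1))
  uk <- sort(unique(Ks))
  meanL <- vapply(uk, function(k) mean(lnE[Ks == k]), numeric(1))
  sdL <- vapply(uk, function(k) stats::sd(lnE[Ks == k]), numeric(1))
  nR <- vapply(uk, function(k) sum(Ks == k), integer(1))
  m <- length(uk)
  l1 <- c(NA, diff(meanL))                       # L'(K) = L(K) - L(K-1)
  l2 <- rep(NA_real_, m)                         # L''(K), interior only
  if (m >= 3) l2[2:(m - 1)] <- diff(meanL, differences = 2)
  deltaK <- abs(l2) / sdL
  deltaK[!is.na(sdL) & sdL == 0] <- NA_real_
  tab <- data.frame(K = uk, nReps = nR, meanLnE = meanL, sdLnE = sdL,
                    l1 = l1, l2 = l2, deltaK = deltaK,
                    stringsAsFactors = FALSE)
  bestK <- if (all(is.na(deltaK))) NA_integer_
           else uk[which.max(deltaK)]
  list(table = tab, bestK = bestK)
}

#' Hard group assignment from a membership matrix
#'
#' Assigns each genotype to the population with the largest membership;
#' ties break toward the lowest group index. Genotypes whose maximum
#' membership is below `threshold` are flagged admixed (they are still
#' assigned).
#'
#' @param q genotype x K membership matrix (rows sum to 1), e.g.
#'   `membership(fit)`.
#' @param threshold admixture flag threshold on the maximum membership.
#' @return data.frame with `genotype`, `group` (`"G<k>"`), `maxQ`,
#'   `admixed`.
#' @export
assignGroups <- function(q, threshold = 0.6) {
  stopifnot(is.matrix(q), nrow(q) >= 1)
  k <- apply(q, 1, which.max)     # which.max takes the first (lowest) index
  mx <- q[cbind(seq_len(nrow(q)), k)]
  data.frame(genotype = rownames(q), group = paste0("G", k), maxQ = mx,
             admixed = mx < threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Greedy column alignment of replicate membership matrices
#'
#' Resolves label switching between replicate runs: columns of `q` are
#' greedily matched to the columns of `ref` by decreasing inner product.
#'
#' @param q,ref genotype x K membership matrices over the same genotypes.
#' @return `q` with columns permuted to match `ref`.
#' @export
alignQ <- function(q, ref) {
  stopifnot(identical(dim(q), dim(ref)))
  K <- ncol(q)
  sim <- crossprod(ref, q)     # ref-col x q-col similarity
  perm <- integer(K)
  for (step in seq_len(K)) {
    idx <- arrayInd(which.max(sim), dim(sim))
    perm[idx[1]] <- idx[2]
    sim[idx[1], ] <- -Inf      # ref column matched
    sim[, idx[2]] <- -Inf      # q column used
  }
  out <- q[, perm, drop = FALSE]
  colnames(out) <- colnames(ref)
  out
}

#' LD-based marker pruning
#'
#' Greedy reduction of a mapped marker set to approximately independent
#' loci: markers are scanned in (chromosome, position) order and a
#' marker is retained only if its r2 permutation test against every
#' already-retained marker on the same chromosome is non-significant at
#' `alpha`. Unmapped markers are excluded.
#'
#' @param panel a [DartPanel-class].
#' @param map genetic map; defaults to the panel annotation.
#' @param alpha significance level of the per-pair permutation test.
#' @param nPerm permutations per pair test.
#' @param seed integer seed.
#' @return character vector of retained marker ids.
#' @export
pruneByLd <- function(panel, map = markerMap(panel), alpha = 0.05,
                      nPerm = 199L, seed = NULL) {
  map <- validateMap(map)
  if (!nrow(map)) stop("empty map")
  x <- markerCalls(panel)
  map <- map[map$marker %in% colnames(x), , drop = FALSE]
  map <- map[order(map$chrom, map$pos, map$marker), , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  keep <- character(0)
  for (ch in unique(map$chrom)) {
    ids <- map$marker[map$chrom == ch]
    retained <- integer(0)
    cols <- match(ids, colnames(x))
    for (j in seq_along(cols)) {
      ok <- TRUE
      for (r in retained) {
        res <- .pair_r2_perm(x, r, cols[j], as.integer(nPerm))
        pv <- res$p[1]
        if (!is.na(pv) && pv < alpha) { ok <- FALSE; break }
      }
      if (ok) retained <- c(retained, cols[j])
    }
    keep <- c(keep, colnames(x)[retained])
  }
  keep
}
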