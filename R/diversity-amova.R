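#' Gene diversity of a dominant-marker panel
#'
#' Per-marker gene diversity under the biallelic homozygous model is
#' `h = 2*f*(1-f)` with f the band frequency among non-missing calls;
#' the report gives the mean of h over the analysis markers, pooled and
#' per group. Groups with fewer than two members are excluded with a
#' warning.
#'
#' @param panel a [DartPanel-class].
#' @param labels optional genotype-to-group labels; defaults to the
#'   stored panel groups (pass `NULL` for a pooled-only report).
#' @return list with `total` (pooled mean diversity), `perGroup`
#'   (data.frame `group`, `n`, `H`), and `perMarker` (pooled h values).
#' @export
geneDiversity <- function(panel, labels = genotypeGroups(panel)) {
  x <- markerCalls(panel)
  hbar <- function(m) {
    nc <- colSums(!is.na(m))
    f <- ifelse(nc > 0, colSums(m == 1L, na.rm = TRUE) / nc, NA_real_)
    2 * f * (1 - f)
  }
  h <- hbar(x)
  perGroup <- data.frame(group = character(), n = integer(), H = numeric(),
                         stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    labels <- labels[rownames(x)]
    for (g in sort(unique(labels))) {
      idx <- which(labels == g)
      if (length(idx) < 2) {
        warning("group ", g, " has fewer than two members; excluded")
        next
      }
      hg <- hbar(x[idx, , drop = FALSE])
      perGroup <- rbind(perGroup,
                        data.frame(group = g, n = length(idx),
                                   H = mean(hg, na.rm = TRUE),
                                   stringsAsFactors = FALSE))
    }
  }
  list(total = mean(h, na.rm = TRUE), perGroup = perGroup, perMarker = h)
}

# pairwise squared Euclidean distances on 0/1 profiles, rescaled for
# missingness: d2_ij = mismatches * L / comparable
binarySquaredDist <- function(x) {
  P <- x == 1L; P[is.na(P)] <- FALSE; storage.mode(P) <- "numeric"
  A <- x == 0L; A[is.na(A)] <- FALSE; storage.mode(A) <- "numeric"
  M11 <- tcrossprod(P); M00 <- tcrossprod(A)
  M10 <- tcrossprod(P, A); M01 <- t(M10)
  comp <- M11 + M00 + M10 + M01
  mism <- M10 + M01
  d2 <- mism * ncol(x) / comp
  d2[comp == 0] <- NA_real_
  diag(d2) <- 0
  d2
}

# SS decomposition for a label vector over a fixed squared-distance matrix
amovaSS <- function(d2, gidx) {
  N <- nrow(d2)
  ssTotal <- sum(d2[upper.tri(d2)]) / N
  ssWithin <- 0
  for (g in unique(gidx)) {
    sel <- gidx == g
    ssWithin <- ssWithin + sum(d2[sel, sel][upper.tri(d2[sel, sel])]) / sum(sel)
  }
  c(total = ssTotal, within = ssWithin, among = ssTotal - ssWithin)
}

#' Analysis of molecular variance for dominant markers
#'
#' One-level AMOVA on squared Euclidean distances of 0/1 profiles
#' (missing cells handled by rescaling each pair's mismatch count to the
#' full marker count). Sums of squares follow the distance-based
#' decomposition `SS_total = sum d2 / N`, `SS_within = sum_g sum d2 / n_g`;
#' variance components are `sigma2_w = SS_within/(N-G)` and
#' `sigma2_a = (SS_among/(G-1) - sigma2_w)/n0` with
#' `n0 = (N - sum n_g^2/N)/(G-1)`. `Phi_PT = sigma2_a/(sigma2_a+sigma2_w)`
#' with significance from permutations of genotype labels:
#' `p = (1 + #{Phi_perm >= Phi_obs}) / (1 + nPerm)`.
#'
#' A negative among-group component is reported as estimated, together
#' with a clamped-at-zero Phi (`phiPtClamped`).
#'
#' @param panel a [DartPanel-class].
#' @param labels genotype-to-group labels (>= 2 groups, each >= 2
#'   members); defaults to the stored panel groups.
#' @param nPerm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list of class `"amova"` with `dfAmong`, `dfWithin`,
#'   `ssAmong`, `ssWithin`, `sigma2Among`, `sigma2Within`,
#'   `percentAmong`, `phiPt`, `phiPtClamped`, `pValue`, `nPerm`.
#' @export
amova <- function(panel, labels = genotypeGroups(panel), nPerm = 999L,
                  seed = NULL) {
  x <- markerCalls(panel)
  if (is.null(labels)) stop("no group labels")
  labels <- labels[rownames(x)]
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("singleton group: ",
                           names(sizes)[sizes < 2][1])
  d2 <- binarySquaredDist(x)
  if (anyNA(d2)) stop("genotype pair with no comparable markers")
  gidx <- as.integer(factor(labels))
  N <- nrow(d2); G <- length(sizes)
  phiFromLabels <- function(gi) {
    ss <- amovaSS(d2, gi)
    s2w <- ss["within"] / (N - G)
    n0 <- (N - sum(table(gi)^2) / N) / (G - 1)
    s2a <- (ss["among"] / (G - 1) - s2w) / n0
    unname(s2a / (s2a + s2w))
  }
  ss <- amovaSS(d2, gidx)
  s2w <- unname(ss["within"] / (N - G))
  n0 <- (N - sum(sizes^2) / N) / (G - 1)
  s2a <- unname((ss["among"] / (G - 1) - s2w) / n0)
  phi <- s2a / (s2a + s2w)
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  for (b in seq_len(nPerm))
    if (phiFromLabels(sample(gidx)) >= phi - 1e-12) ge <- ge + 1L
  s2aC <- max(s2a, 0)
  structure(list(dfAmong = G - 1L, dfWithin = N - G,
                 ssAmong = unname(ss["among"]),
                 ssWithin = unname(ss["within"]),
                 sigma2Among = s2a, sigma2Within = s2w,
                 percentAmong = 100 * s2a / (s2a + s2w),
                 phiPt = phi,
                 phiPtClamped = s2aC / (s2aC + s2w),
                 pValue = (1 + ge) / (1 + nPerm),
                 nPerm = as.integer(nPerm)),
            class = "amova")
}

#' @export
print.amova <- function(x, ...) {
  cat("AMOVA (dominant 0/1 profiles)\n")
  cat(sprintf("  among groups:  df = %d, SS = %.3f, sigma2 = %.4f\n",
              x$dfAmong, x$ssAmong, x$sigma2Among))
  cat(sprintf("  within groups: df = %d, SS = %.3f, sigma2 = %.4f\n",
              x$dfWithin, x$ssWithin, x$sigma2Within))
  cat(sprintf("  Phi_PT = %.4f (%.1f%% among), p = %.4g (%d permutations)\n",
              x$phiPt, x$percentAmong, x$pValue, x$nPerm))
  invisible(x)
}

#' Pairwise Phi_PT between groups
#'
#' Runs [amova()] on every pair of groups.
#'
#' @inheritParams amova
#' @return list with symmetric matrices `phi` (zero diagonal) and
#'   `pValue` (`NA` diagonal).
#' @export
pairwisePhi <- function(panel, labels = genotypeGroups(panel),
                        nPerm = 999L, seed = NULL) {
  if (is.null(labels)) stop("no group labels")
  labels <- labels[rownames(markerCalls(panel))]
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least two groups")
  k <- length(groups)
  phi <- matrix(0, k, k, dimnames = list(groups, groups))
  pv <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  if (!is.null(seed)) set.seed(seed)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    sel <- labels %in% groups[c(a, b)]
    sub <- panel[, names(labels)[sel]]
    res <- amova(sub, labels = labels[sel], nPerm = nPerm, seed = NULL)
    phi[a, b] <- phi[b, a] <- res$phiPt
    pv[a, b] <- pv[b, a] <- res$pValue
  }
  list(phi = phi, pValue = pv)
}
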