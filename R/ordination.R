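#' Jaccard dissimilarity between genotypes
#'
#' For genotypes i and j, over markers where both calls are non-missing:
#' `d = (M01 + M10) / (M01 + M10 + M11)` where M01/M10 count discordant
#' bands and M11 counts shared bands. Double absences are ignored, as
#' they cannot be distinguished from missing data for dominant markers.
#' When a pair shares no comparable informative marker the entry is
#' `NA` with a warning.
#'
#' @param panel a [DartPanel-class] with at least two genotypes.
#' @return A symmetric genotype x genotype matrix of dissimilarities in
#'   `[0, 1]` with zero diagonal.
#' @export
jaccardDistance <- function(panel) {
  x <- markerCalls(panel)
  if (nrow(x) < 2) stop("need at least two genotypes")
  P <- x == 1L; P[is.na(P)] <- FALSE; storage.mode(P) <- "numeric"
  A <- x == 0L; A[is.na(A)] <- FALSE; storage.mode(A) <- "numeric"
  M11 <- tcrossprod(P)
  M10 <- tcrossprod(P, A)
  M01 <- t(M10)
  den <- M01 + M10 + M11
  d <- (M01 + M10) / den
  if (any(den == 0))
    warning("genotype pair(s) with no comparable informative markers; ",
            "distance reported NA")
  d[den == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a dissimilarity matrix: the squared
#' distances are double-centered, eigendecomposed, and coordinates are
#' eigenvectors scaled by the square root of their eigenvalues.
#' Explained fractions use positive eigenvalues only (negative
#' eigenvalues, which arise for non-Euclidean dissimilarities such as
#' Jaccard, are dropped from the denominator). Missing entries are
#' imputed by the off-diagonal mean, with a message.
#'
#' @param d symmetric dissimilarity matrix (e.g. [jaccardDistance()]).
#' @param nAxes number of axes to return.
#' @return list of class `"ordination"`: `coordinates` (genotype x
#'   axis), `explained` (per-axis fraction), `eigenvalues`, `loadings`
#'   (`NULL` for PCoA), `method = "PCoA"`.
#' @export
runPcoa <- function(d, nAxes = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  if (anyNA(d)) {
    message("imputing ", sum(is.na(d[upper.tri(d)])),
            " missing distance(s) by the matrix mean")
    fill <- mean(d[upper.tri(d)], na.rm = TRUE)
    d[is.na(d)] <- fill
    d <- (d + t(d)) / 2
    diag(d) <- 0
  }
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-9
  nAxes <- min(nAxes, sum(pos))
  coords <- e$vectors[, seq_len(nAxes), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(nAxes)]), nAxes)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(nAxes))
  structure(list(coordinates = coords,
                 explained = e$values[seq_len(nAxes)] / sum(e$values[pos]),
                 eigenvalues = e$values,
                 loadings = NULL, method = "PCoA"),
            class = "ordination")
}

#' Principal component analysis of a marker panel
#'
#' Genotypes are observations, markers variables. Missing calls are
#' imputed by the marker band frequency; columns are centered but not
#' variance-scaled (all markers share the 0/1 scale). Returns scores,
#' marker loadings and explained variance fractions.
#'
#' @param panel a [DartPanel-class].
#' @param nAxes number of axes to return.
#' @return list of class `"ordination"`: `coordinates` (genotype
#'   scores), `explained`, `eigenvalues`, `loadings` (marker x axis),
#'   `method = "PCA"`.
#' @export
runPca <- function(panel, nAxes = 2) {
  x <- markerCalls(panel)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 genotypes and >= 2 markers")
  storage.mode(x) <- "numeric"
  if (anyNA(x)) {
    f <- colMeans(x, na.rm = TRUE)
    f[is.nan(f)] <- 0
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- f[idx[, 2]]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  nAxes <- min(nAxes, ncol(pc$x))
  coords <- pc$x[, seq_len(nAxes), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(nAxes))
  loads <- pc$rotation[, seq_len(nAxes), drop = FALSE]
  colnames(loads) <- paste0("Axis", seq_len(nAxes))
  structure(list(coordinates = coords,
                 explained = ev[seq_len(nAxes)] / sum(ev),
                 eigenvalues = ev, loadings = loads, method = "PCA"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d observations, %d axes\n", x$method,
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("explained:", paste(sprintf("%.1f%%", 100 * x$explained),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Flag ordination outliers
#'
#' A genotype is flagged when its Euclidean distance from the centroid
#' of the first two axes exceeds `kSd` times the radial spread
#' `sqrt(sd(axis1)^2 + sd(axis2)^2)`. The spread deliberately includes
#' any between-cluster separation, so ordinary subpopulation structure
#' is not flagged while a genuinely aberrant genotype (e.g. a failed
#' assay) far outside the cloud is. Flagging is symmetric under axis
#' sign flips; removal is left to the caller.
#'
#' @param ord an `"ordination"` result with at least 3 observations.
#' @param kSd flag threshold multiplier.
#' @return character vector of flagged genotype ids (possibly empty).
#' @export
flagOutliers <- function(ord, kSd = 4.0) {
  coords <- ord$coordinates[, seq_len(min(2, ncol(ord$coordinates))),
                            drop = FALSE]
  if (nrow(coords) < 3) stop("need at least three genotypes")
  ctr <- colMeans(coords)
  r <- sqrt(rowSums(sweep(coords, 2, ctr)^2))
  spread <- sqrt(sum(apply(coords, 2, stats::sd)^2))
  if (spread <= 0) return(character(0))
  rownames(coords)[r > kSd * spread]
}

#' Top-loading markers on an ordination axis
#'
#' Ranks markers by absolute loading on the chosen axis and returns the
#' top `ceiling(fraction * nMarkers)`.
#'
#' @param ord a PCA `"ordination"` result (with loadings).
#' @param fraction fraction of markers to keep, in `(0, 1]`.
#' @param axis axis number.
#' @return data.frame `marker`, `loading`, `rank`.
#' @export
topLoadingMarkers <- function(ord, fraction = 0.05, axis = 1) {
  if (is.null(ord$loadings)) stop("ordination has no loadings (need PCA)")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  l <- ord$loadings[, axis]
  k <- ceiling(fraction * length(l))
  ord2 <- order(-abs(l))
  top <- ord2[seq_len(k)]
  data.frame(marker = rownames(ord$loadings)[top], loading = l[top],
             rank = seq_len(k), row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker-group association tests
#'
#' Scores each marker's 2x2 band-presence by group table with a
#' continuity-corrected chi-square test, falling back to Fisher's exact
#' test when any expected cell count is below 5. Benjamini-Hochberg
#' q-values accompany the raw p-values.
#'
#' @param panel a [DartPanel-class].
#' @param labels genotype-to-group labels (exactly two groups); defaults
#'   to the stored panel groups.
#' @return data.frame `marker`, `p`, `q`, `effect` (band-frequency
#'   difference, group 1 minus group 2), `test` (`"chisq"` or
#'   `"fisher"`). Markers without carriers or without complete calls in
#'   both groups get `NA` p-values.
#' @export
markerGroupAssociation <- function(panel, labels = genotypeGroups(panel)) {
  x <- markerCalls(panel)
  if (is.null(labels)) stop("no group labels")
  labels <- labels[rownames(x)]
  groups <- sort(unique(labels))
  if (length(groups) != 2)
    stop("exactly two groups required; run one-vs-rest for more")
  g1 <- labels == groups[1]
  p <- q <- eff <- rep(NA_real_, ncol(x))
  test <- rep(NA_character_, ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ok <- !is.na(v)
    tab <- table(factor(v[ok], levels = c(0, 1)),
                 factor(g1[ok], levels = c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd < 5)) {
      p[j] <- stats::fisher.test(tab)$p.value
      test[j] <- "fisher"
    } else {
      p[j] <- stats::chisq.test(tab, correct = TRUE)$p.value
      test[j] <- "chisq"
    }
    f1 <- mean(v[ok & g1] == 1)
    f2 <- mean(v[ok & !g1] == 1)
    eff[j] <- f1 - f2
  }
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  data.frame(marker = colnames(x), p = p, q = q, effect = eff, test = test,
             row.names = NULL, stringsAsFactors = FALSE)
}
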