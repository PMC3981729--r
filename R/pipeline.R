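#' Pipeline configuration
#'
#' Collects the knobs of [runFull()]. Every stochastic stage derives its
#' seed deterministically from `seed`.
#'
#' @param kMin,kMax range of K for the admixture scan.
#' @param reps replicate runs per K.
#' @param burnin,iters,thin MCMC settings per run.
#' @param pruneAlpha,pruneNPerm LD-pruning significance level and
#'   permutations per pair test.
#' @param pcaFraction,pcaAxis top-loading marker fraction and axis.
#' @param amovaNPerm AMOVA label permutations.
#' @param ldNPerm,ldSpan LD permutations per pair and loess span.
#' @param outlierKSd ordination outlier threshold ([flagOutliers()]).
#' @param dropOutliers exclude flagged outliers and repeat once.
#' @param seed master seed (mandatory).
#' @return list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(kMin = 1L, kMax = 4L, reps = 3L,
                           burnin = 2000L, iters = 2000L, thin = 10L,
                           pruneAlpha = 0.05, pruneNPerm = 199L,
                           pcaFraction = 0.05, pcaAxis = 1L,
                           amovaNPerm = 999L, ldNPerm = 199L,
                           ldSpan = 0.5, outlierKSd = 4.0,
                           dropOutliers = TRUE, seed = 1L) {
  stopifnot(kMin >= 1, kMax >= kMin, reps >= 1, is.numeric(seed))
  structure(as.list(environment()), class = "pipelineConfig")
}

stageSeed <- function(seed, offset) as.integer((seed + offset) %% .Machine$integer.max)

runStages <- function(panel, config) {
  stats <- markerStatistics(panel)
  polyIds <- stats$marker[stats$polymorphic]
  if (length(polyIds) < 2) stop("stage marker_filter: fewer than 2 polymorphic markers")
  poly <- panel[polyIds, ]
  map <- markerMap(poly)

  pruned <- pruneByLd(poly, alpha = config$pruneAlpha,
                      nPerm = config$pruneNPerm,
                      seed = stageSeed(config$seed, 11))

  fits <- list()
  for (K in config$kMin:config$kMax)
    for (r in seq_len(config$reps))
      fits[[length(fits) + 1]] <-
        runAdmixture(poly, K = K, burnin = config$burnin,
                     iters = config$iters, thin = config$thin,
                     markers = pruned,
                     seed = stageSeed(config$seed, 1000 + 101 * K + r))
  evanno <- selectKEvanno(fits)
  bestK <- evanno$bestK
  if (is.na(bestK)) bestK <- 2L
  kFits <- Filter(function(f) f@K == bestK, fits)
  best <- kFits[[which.max(vapply(kFits, lnEvidence, numeric(1)))]]
  groups <- assignGroups(membership(best))
  labels <- stats::setNames(groups$group, groups$genotype)

  jac <- jaccardDistance(poly)
  pcoa <- runPcoa(jac, nAxes = 3)
  pca <- runPca(poly, nAxes = 5)
  outliers <- flagOutliers(pca, kSd = config$outlierKSd)
  topMarkers <- topLoadingMarkers(pca, fraction = config$pcaFraction,
                                  axis = config$pcaAxis)
  assoc <- markerGroupAssociation(poly, labels = labels)

  genotypeGroups(poly) <- labels
  div <- geneDiversity(poly, labels = labels)
  am <- amova(poly[pruned, ], labels = labels, nPerm = config$amovaNPerm,
              seed = stageSeed(config$seed, 23))
  phis <- pairwisePhi(poly[pruned, ], labels = labels, nPerm = config$amovaNPerm,
                      seed = stageSeed(config$seed, 29))

  ldFor <- function(genos, offset) {
    pr <- pairR2(poly, nPerm = config$ldNPerm,
                 seed = stageSeed(config$seed, offset), genotypes = genos)
    bg <- tryCatch(backgroundLd(pr), error = function(e) NA_real_)
    dec <- if (is.na(bg)) NULL else
      tryCatch(fitDecay(pr, bg, span = config$ldSpan),
               error = function(e) NULL)
    list(pairs = pr, background = bg, decay = dec,
         summaries = ldSummaries(pr, map))
  }
  ld <- list(total = ldFor(NULL, 37))
  for (g in sort(unique(labels)))
    ld[[g]] <- ldFor(names(labels)[labels == g], 37 + match(g, sort(unique(labels))))

  list(markerStats = stats, polymorphic = polyIds, pruned = pruned,
       fits = fits, evanno = evanno, bestK = bestK, bestFit = best,
       groups = groups, labels = labels, jaccard = jac, pcoa = pcoa,
       pca = pca, outliers = outliers, topMarkers = topMarkers,
       association = assoc, diversity = div, amova = am,
       pairwisePhi = phis, ld = ld)
}

#' Run the full population-structure workflow
#'
#' Executes the study workflow on a marker panel: polymorphic-marker
#' filtering, LD pruning, replicate admixture runs over a K range with
#' Evanno delta-K selection, hard group assignment, Jaccard/PCoA and PCA
#' ordination with outlier flagging (flagged genotypes are excluded and
#' the workflow repeated once), top-loading marker detection and
#' marker-group association, gene diversity, AMOVA and pairwise Phi on
#' the pruned set, and intra-chromosomal LD (r2, background, loess
#' decay) for the whole panel and within each inferred group.
#'
#' @param panel a [DartPanel-class] with map annotation.
#' @param config a [pipelineConfig()].
#' @param outDir optional directory; when given, result tables are
#'   written via [writeResults()].
#' @param trait optional named vector of trait categories per genotype
#'   for a group-by-trait cross-tabulation.
#' @return list with all stage results (`markerStats`, `pruned`, `fits`,
#'   `evanno`, `bestK`, `groups`, `labels`, `pcoa`, `pca`, `topMarkers`,
#'   `association`, `diversity`, `amova`, `pairwisePhi`, `ld`, ...),
#'   plus `report` (markdown lines), `manifest` (when `outDir` given)
#'   and `excluded` (outliers dropped before the final pass).
#' @export
runFull <- function(panel, config = pipelineConfig(), outDir = NULL,
                    trait = NULL) {
  res <- runStages(panel, config)
  excluded <- character(0)
  if (length(res$outliers) && config$dropOutliers) {
    excluded <- res$outliers
    keep <- setdiff(colnames(panel), excluded)
    res <- runStages(panel[, keep], config)
  }
  res$excluded <- excluded
  if (!is.null(trait))
    res$traitCrosstab <- crosstabTraitGroups(res$labels, trait)

  gsz <- table(res$labels)
  decLine <- function(l) {
    if (is.null(l$decay)) return("not estimated")
    if (l$decay$noIntercept)
      sprintf("no intercept (curve extends to %.0f cM)", l$decay$maxExtent)
    else sprintf("%.1f cM", l$decay$decayCM)
  }
  res$report <- c(
    "# dartpop run report",
    sprintf("- genotypes: %d (excluded as outliers: %s)",
            length(res$labels),
            if (length(excluded)) paste(excluded, collapse = ", ") else "none"),
    sprintf("- polymorphic markers: %d; LD-pruned set: %d",
            length(res$polymorphic), length(res$pruned)),
    sprintf("- delta-K argmax: K = %d; group sizes: %s", res$bestK,
            paste(sprintf("%s = %d", names(gsz), gsz), collapse = ", ")),
    sprintf("- gene diversity H: total %.3f; %s", res$diversity$total,
            paste(sprintf("%s %.3f", res$diversity$perGroup$group,
                          res$diversity$perGroup$H), collapse = ", ")),
    sprintf("- AMOVA: Phi_PT = %.3f (%.1f%% among groups), p = %.4g",
            res$amova$phiPt, res$amova$percentAmong, res$amova$pValue),
    vapply(names(res$ld), function(nm)
      sprintf("- LD decay (%s): %s", nm, decLine(res$ld[[nm]])), character(1)))

  if (!is.null(outDir)) {
    tabs <- list(
      q_matrix = data.frame(genotype = rownames(membership(res$bestFit)),
                            membership(res$bestFit), check.names = FALSE),
      delta_k = res$evanno$table,
      group_labels = res$groups,
      marker_summary = res$markerStats,
      diversity = data.frame(group = c("total", res$diversity$perGroup$group),
                             n = c(length(res$labels), res$diversity$perGroup$n),
                             H = c(res$diversity$total, res$diversity$perGroup$H)),
      amova = data.frame(stratum = c("among", "within"),
                         df = c(res$amova$dfAmong, res$amova$dfWithin),
                         SS = c(res$amova$ssAmong, res$amova$ssWithin),
                         sigma2 = c(res$amova$sigma2Among, res$amova$sigma2Within),
                         phiPt = res$amova$phiPt, p = res$amova$pValue),
      pcoa_coords = data.frame(genotype = rownames(res$pcoa$coordinates),
                               res$pcoa$coordinates),
      pca_coords = data.frame(genotype = rownames(res$pca$coordinates),
                              res$pca$coordinates),
      pca_loadings = data.frame(marker = rownames(res$pca$loadings),
                                res$pca$loadings),
      marker_association = res$association,
      ld_pairs = res$ld$total$pairs,
      ld_summary = res$ld$total$summaries$perChromosome,
      adjacent_profile = res$ld$total$summaries$adjacentProfile)
    if (!is.null(res$ld$total$decay))
      tabs$ld_decay <- res$ld$total$decay$curve
    res$manifest <- writeResults(tabs, outDir,
                                 config = unclass(config)[
                                   vapply(unclass(config), is.atomic, logical(1))],
                                 seed = config$seed)
    writeLines(res$report, file.path(outDir, "report.md"))
  }
  res
}

#' Cross-tabulate inferred groups against a categorical trait
#'
#' Group x trait-category contingency table with an association test:
#' Pearson chi-square, switching to a Monte-Carlo p-value when any
#' expected count falls below 5.
#'
#' @param labels named genotype-to-group labels.
#' @param trait named genotype-to-category labels (missing categories
#'   dropped); only genotypes present in both enter the table.
#' @param B Monte-Carlo replicates for small tables.
#' @return list with `table`, `pValue`, `method`.
#' @export
crosstabTraitGroups <- function(labels, trait, B = 2000L) {
  trait <- trait[!is.na(trait)]
  common <- intersect(names(labels), names(trait))
  if (!length(common)) stop("no genotypes shared between labels and trait")
  tab <- table(group = labels[common], trait = trait[common])
  if (length(unique(trait[common])) < 2 || nrow(tab) < 2)
    stop("need at least two trait categories and two groups with carriers")
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd < 5)) {
    tst <- stats::chisq.test(tab, simulate.p.value = TRUE, B = B)
    method <- "chisq-montecarlo"
  } else {
    tst <- stats::chisq.test(tab)
    method <- "chisq"
  }
  list(table = tab, pValue = tst$p.value, method = method)
}
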