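#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @useDynLib dartpop, .registration = TRUE
NULL

#' The 21 bread-wheat chromosome names
#'
#' Chromosomes 1-7 of the A, B and D genomes, the label alphabet accepted
#' by [readMapTable()] and the synthetic-panel generator.
#'
#' @format Character vector of length 21 (`"1A"` ... `"7D"`).
#' @export
wheatChromosomes <- paste0(rep(1:7, times = 3), rep(c("A", "B", "D"), each = 7))

#' DartPanel: a dominant-marker score panel
#'
#' S4 container for a genotypes-by-markers table of dominant
#' (presence/absence) scores, stored as a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with markers as rows and genotypes as columns. The single assay
#' `"calls"` holds integer codes: `1` band present, `0` band absent,
#' `NA` missing. Genetic-map annotation (chromosome, position in cM)
#' lives in `rowData` columns `chrom` and `pos`; group labels, when
#' known or inferred, live in `colData$group`.
#'
#' @seealso [DartPanel()], [markerCalls()], [markerMap()], [genotypeGroups()]
#' @export
setClass("DartPanel", contains = "SummarizedExperiment")

setValidity("DartPanel", function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    calls <- SummarizedExperiment::assay(object, "calls")
    bad <- calls[!is.na(calls)]
    if (length(bad) && !all(bad %in% c(0L, 1L)))
      msg <- c(msg, "calls must be 0, 1 or NA")
  }
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "marker and genotype names are required")
  else {
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, sprintf("duplicated marker id: %s",
                            rownames(object)[duplicated(rownames(object))][1]))
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, sprintf("duplicated genotype id: %s",
                            colnames(object)[duplicated(colnames(object))][1]))
  }
  if (length(msg)) msg else TRUE
})

#' StructureFit: one admixture-model MCMC run
#'
#' Posterior summaries from a single Gibbs-sampler run of the Bayesian
#' admixture model at a fixed number of ancestral populations K.
#'
#' @slot K integer, number of ancestral populations.
#' @slot q genotype x K matrix of posterior mean memberships; rows sum to 1.
#' @slot p K x marker matrix of posterior mean band frequencies.
#' @slot alphaTrace numeric, recorded values of the Dirichlet
#'   concentration parameter alpha.
#' @slot loglik numeric, recorded data log-likelihoods (one per kept
#'   iteration after thinning).
#' @slot lnEvidence numeric(1), estimate of ln Pr(X | K) computed as
#'   mean(loglik) - var(loglik)/2.
#' @slot seed integer(1) or NA, the seed the run was started from.
#' @export
setClass("StructureFit",
         representation(K = "integer", q = "matrix", p = "matrix",
                        alphaTrace = "numeric", loglik = "numeric",
                        lnEvidence = "numeric", seed = "integer"))

setValidity("StructureFit", function(object) {
  msg <- character()
  if (ncol(object@q) != object@K) msg <- c(msg, "q must have K columns")
  if (nrow(object@p) != object@K) msg <- c(msg, "p must have K rows")
  if (any(abs(rowSums(object@q) - 1) > 1e-9))
    msg <- c(msg, "q rows must sum to 1")
  pp <- object@p
  if (any(pp < -1e-12 | pp > 1 + 1e-12))
    msg <- c(msg, "p entries must lie in [0, 1]")
  if (!is.finite(object@lnEvidence)) msg <- c(msg, "lnEvidence must be finite")
  if (length(msg)) msg else TRUE
})
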