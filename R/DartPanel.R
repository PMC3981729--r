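#' Construct a DartPanel
#'
#' Builds the package's central container from a genotypes-by-markers
#' score matrix. Scores are coerced to integer codes 1 (band present),
#' 0 (band absent) and `NA` (missing); character inputs may use
#' `"X"`, `"-"`, `"NA"` or `""` for missing.
#'
#' @param calls matrix with one row per genotype and one column per
#'   marker; dimnames give genotype and marker ids.
#' @param map optional genetic map as returned by [readMapTable()]: a
#'   data.frame with columns `marker`, `chrom`, `pos`. Markers absent
#'   from the map keep `NA` annotation; map rows for markers not in
#'   `calls` are ignored.
#' @param groups optional named character/factor of group labels,
#'   names = genotype ids (or unnamed, in row order).
#' @return A [DartPanel-class] object (markers as rows).
#' @examples
#' m <- matrix(c(1, 0, NA, 1), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("m1", "m2")))
#' DartPanel(m)
#' @export
DartPanel <- function(calls, map = NULL, groups = NULL) {
  if (is.data.frame(calls)) calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("'calls' needs genotype row names and marker column names")
  codes <- normalizeCalls(calls)
  a <- t(codes)   # markers as rows, SummarizedExperiment convention
  rd <- S4Vectors::DataFrame(chrom = rep(NA_character_, nrow(a)),
                             pos = rep(NA_real_, nrow(a)),
                             row.names = rownames(a))
  if (!is.null(map)) {
    map <- validateMap(map)
    hit <- match(rownames(a), map$marker)
    rd$chrom <- map$chrom[hit]
    rd$pos <- map$pos[hit]
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(a))
  if (!is.null(groups)) {
    if (!is.null(names(groups))) {
      miss <- setdiff(colnames(a), names(groups))
      if (length(miss))
        stop("no group label for genotype: ", miss[1])
      groups <- groups[colnames(a)]
    } else if (length(groups) != ncol(a)) {
      stop("'groups' must be named or have one entry per genotype")
    }
    cd$group <- as.character(groups)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = a), rowData = rd, colData = cd)
  methods::new("DartPanel", se)
}

# map 0/1/X/-/NA/"" (numeric or character) to integer codes
normalizeCalls <- function(m) {
  if (is.numeric(m) || is.logical(m)) {
    out <- m
    storage.mode(out) <- "integer"
    bad <- which(!is.na(out) & !(out %in% c(0L, 1L)))
  } else {
    v <- trimws(as.character(m))
    out <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
    out[v == "1"] <- 1L
    out[v == "0"] <- 0L
    known <- v %in% c("0", "1", "X", "x", "-", "NA", "na", "") | is.na(v)
    bad <- which(!known)
  }
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf("invalid score '%s' at genotype %s, marker %s",
                 as.character(m)[bad[1]],
                 rownames(m)[rc[1]], colnames(m)[rc[2]]))
  }
  out
}

#' @describeIn markerCalls accessors for DartPanel
#' @export
setGeneric("markerCalls", function(x) standardGeneric("markerCalls"))

#' Accessors for DartPanel objects
#'
#' `markerCalls()` returns the score matrix in the genotypes-by-markers
#' orientation of a DArT score sheet (0/1/`NA` integer codes).
#' `markerMap()` returns the genetic-map annotation of the mapped
#' markers; `genotypeGroups()` gets or sets genotype group labels.
#'
#' @param x a [DartPanel-class].
#' @param value for the replacement form, a character/factor of labels,
#'   named by genotype or in genotype order; `NULL` removes them.
#' @return `markerCalls()`: integer matrix; `markerMap()`: data.frame
#'   with columns `marker`, `chrom`, `pos` (mapped markers only);
#'   `genotypeGroups()`: named character vector or `NULL`.
#' @name markerCalls
#' @aliases markerCalls,DartPanel-method
#' @export
setMethod("markerCalls", "DartPanel", function(x)
  t(SummarizedExperiment::assay(x, "calls")))

#' @rdname markerCalls
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname markerCalls
#' @export
setMethod("markerMap", "DartPanel", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  keep <- !is.na(rd$chrom)
  data.frame(marker = rownames(x)[keep],
             chrom = rd$chrom[keep], pos = rd$pos[keep],
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname markerCalls
#' @export
setGeneric("genotypeGroups", function(x) standardGeneric("genotypeGroups"))

#' @rdname markerCalls
#' @export
setMethod("genotypeGroups", "DartPanel", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"group" %in% colnames(cd)) return(NULL)
  stats::setNames(as.character(cd$group), colnames(x))
})

#' @rdname markerCalls
#' @export
setGeneric("genotypeGroups<-",
           function(x, value) standardGeneric("genotypeGroups<-"))

#' @rdname markerCalls
#' @export
setMethod("genotypeGroups<-", "DartPanel", function(x, value) {
  if (is.null(value)) {
    SummarizedExperiment::colData(x)$group <- NULL
    return(x)
  }
  if (!is.null(names(value))) {
    miss <- setdiff(colnames(x), names(value))
    if (length(miss)) stop("no group label for genotype: ", miss[1])
    value <- value[colnames(x)]
  } else if (length(value) != ncol(x)) {
    stop("'value' must be named or have one entry per genotype")
  }
  SummarizedExperiment::colData(x)$group <- as.character(value)
  x
})

setMethod("show", "DartPanel", function(object) {
  calls <- SummarizedExperiment::assay(object, "calls")
  nmiss <- sum(is.na(calls))
  cat(sprintf("DartPanel: %d genotypes x %d markers (%d mapped, %.1f%% missing)\n",
              ncol(object), nrow(object), nrow(markerMap(object)),
              100 * nmiss / length(calls)))
  g <- genotypeGroups(object)
  if (!is.null(g))
    cat("groups:", paste(sprintf("%s (%d)", names(table(g)), table(g)),
                         collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "StructureFit", function(object) {
  cat(sprintf("StructureFit: K = %d, %d genotypes, %d markers\n",
              object@K, nrow(object@q), ncol(object@p)))
  cat(sprintf("  ln Pr(X|K) = %.2f (%d recorded samples)\n",
              object@lnEvidence, length(object@loglik)))
  invisible(NULL)
})

#' @rdname markerCalls
#' @export
setGeneric("lnEvidence", function(x) standardGeneric("lnEvidence"))

#' @rdname markerCalls
#' @export
setMethod("lnEvidence", "StructureFit", function(x) x@lnEvidence)

#' @rdname markerCalls
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname markerCalls
#' @export
setMethod("membership", "StructureFit", function(x) x@q)
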