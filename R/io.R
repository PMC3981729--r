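#' Read a wide marker score table
#'
#' Reads a DArT-style score sheet: first column genotype ids, header row
#' marker ids, cells in `{0, 1, X, -, NA, <empty>}`. `X`, `-`, `NA` and
#' empty cells all become missing. Both orientations occur in the wild;
#' `transpose = TRUE` reads tables with markers in rows.
#'
#' @param path file path.
#' @param sep field separator; by default inferred from the file
#'   extension (`.csv` = comma, otherwise tab).
#' @param transpose logical; `TRUE` if the file has markers as rows and
#'   genotypes as columns.
#' @return A [DartPanel-class] (no map annotation).
#' @seealso [writeMarkerTable()], [readMapTable()]
#' @export
readMarkerTable <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           row.names = NULL, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(tab) < 2) stop("expected an id column plus at least one score column")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicated %s id: %s",
                 if (transpose) "marker" else "genotype",
                 ids[duplicated(ids)][1]))
  cn <- colnames(tab)[-1]
  if (anyDuplicated(cn))
    stop(sprintf("duplicated %s id: %s",
                 if (transpose) "genotype" else "marker",
                 cn[duplicated(cn)][1]))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  if (transpose) m <- t(m)
  DartPanel(m)
}

#' Write a marker score table
#'
#' Writes the genotypes-by-markers score sheet with missing cells coded
#' `X`, the companion of [readMarkerTable()].
#'
#' @param panel a [DartPanel-class] or a genotypes x markers matrix.
#' @param path output path; `.csv` selects comma separation.
#' @param sep optional separator override.
#' @return `path`, invisibly.
#' @export
writeMarkerTable <- function(panel, path, sep = NULL) {
  m <- if (methods::is(panel, "DartPanel")) markerCalls(panel) else panel
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- matrix(as.character(m), nrow(m), ncol(m))
  out[is.na(out)] <- "X"
  df <- data.frame(genotype = rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("genotype", colnames(m))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genetic map table
#'
#' Expects columns `marker`, `chrom`, `pos` (position in cM; header
#' names `marker_id`, `chromosome` and `position_cM` are also accepted).
#' Chromosome labels are validated against the 21 wheat chromosome
#' names ([wheatChromosomes]).
#'
#' @param path file path (TSV, or CSV by `.csv` extension).
#' @param sep optional separator override.
#' @return data.frame with columns `marker`, `chrom`, `pos`.
#' @export
readMapTable <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(colnames(tab))
  pick <- function(cands) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) stop("map table needs columns marker, chrom, pos")
    tab[[i]]
  }
  validateMap(data.frame(
    marker = as.character(pick(c("marker", "marker_id"))),
    chrom = as.character(pick(c("chrom", "chromosome"))),
    pos = as.numeric(pick(c("pos", "position_cm", "pos_cm", "position"))),
    stringsAsFactors = FALSE))
}

#' @rdname readMapTable
#' @param map data.frame to validate (columns `marker`, `chrom`, `pos`).
#' @export
validateMap <- function(map) {
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% colnames(map)))
    stop("map table needs columns marker, chrom, pos")
  map <- map[, need]
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  if (anyDuplicated(map$marker))
    stop("marker mapped more than once: ",
         map$marker[duplicated(map$marker)][1])
  bad <- !map$chrom %in% wheatChromosomes
  if (any(bad))
    stop("unknown chromosome '", map$chrom[bad][1],
         "' for marker ", map$marker[bad][1])
  if (any(!is.finite(map$pos) | map$pos < 0))
    stop("positions must be finite and non-negative (marker ",
         map$marker[!is.finite(map$pos) | map$pos < 0][1], ")")
  map
}

#' @rdname readMapTable
#' @export
writeMapTable <- function(map, path, sep = NULL) {
  map <- validateMap(map)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(map, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write result tables with a run log
#'
#' Writes each table in `tables` as a TSV under `outDir`, plus a
#' `run_log.txt` recording the seed and configuration, and returns the
#' file manifest. Numeric columns are written at full precision so
#' identical seeds reproduce byte-identical files.
#'
#' @param tables named list of data.frames (may be empty).
#' @param outDir output directory, created if absent.
#' @param config optional named list recorded in the run log.
#' @param seed optional integer recorded in the run log.
#' @return data.frame manifest with columns `name`, `file`, `rows`.
#' @export
writeResults <- function(tables, outDir, config = list(), seed = NULL) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  if (file.access(outDir, 2) != 0) stop("directory not writable: ", outDir)
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables)))
    stop("'tables' must be named")
  files <- character(0); rows <- integer(0)
  for (nm in names(tables)) {
    f <- file.path(outDir, paste0(nm, ".tsv"))
    df <- as.data.frame(tables[[nm]])
    utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f); rows <- c(rows, nrow(df))
  }
  log <- file.path(outDir, "run_log.txt")
  lines <- c(paste0("dartpop ", as.character(utils::packageVersion("dartpop"))),
             paste0("seed: ", if (is.null(seed)) "none" else seed),
             vapply(names(config), function(k)
               paste0(k, ": ", paste(format(config[[k]]), collapse = " ")),
               character(1)))
  writeLines(lines, log)
  data.frame(name = c(names(tables), "run_log"),
             file = c(files, log), rows = c(rows, length(lines)),
             stringsAsFactors = FALSE)
}
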