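#' Read a count matrix
#'
#' Reads a samples-by-variables matrix of non-negative integer counts
#' from a delimited text file (CSV/TSV with a header row) or a
#' MatrixMarket triplet file (`.mtx`, with optional sidecar files of
#' row and column names, one per line). Negative or non-integer cells
#' are rejected with their position; all-zero columns are accepted
#' with a warning.
#'
#' @param path input file.
#' @param rowNames,colNames optional sidecar name files for MTX input.
#' @return integer matrix with column names.
#' @export
readCounts <- function(path, rowNames = NULL, colNames = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    if (!is.null(rowNames)) rownames(m) <- readLines(rowNames)
    if (!is.null(colNames)) colnames(m) <- readLines(colNames)
    if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE)
    bad <- !vapply(df, is.numeric, logical(1))
    if (any(bad))
      stop("non-numeric column(s): ", paste(names(df)[bad], collapse = ", "))
    m <- as.matrix(df)
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative count at row %d, column '%s'", neg[1L, 1L],
                 colnames(m)[neg[1L, 2L]]))
  frac <- which(m != round(m), arr.ind = TRUE)
  if (nrow(frac))
    stop(sprintf("non-integer count at row %d, column '%s'", frac[1L, 1L],
                 colnames(m)[frac[1L, 2L]]))
  if (any(colSums(m) == 0))
    warning("all-zero column(s): ",
            paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as TSV
#'
#' @param data count matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an initial DAG from an edge-list file
#'
#' Two-column TSV (header `source`, `target`) whose node names match
#' `labels` (e.g. the data's column names).
#'
#' @param path edge-list file.
#' @param labels character vector of node names, in data column order.
#' @return a [DAGStructure-class].
#' @export
readEdgeList <- function(path, labels) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("source", "target") %in% names(df)))
    stop("edge list needs 'source' and 'target' columns")
  from <- match(df$source, labels)
  to <- match(df$target, labels)
  if (anyNA(from) || anyNA(to))
    stop("unknown node name(s): ",
         paste(unique(c(df$source[is.na(from)], df$target[is.na(to)])),
               collapse = ", "))
  dagStructure(length(labels), cbind(from, to), labels = labels)
}

.nodeLabels <- function(dag) {
  if (length(dag@labels)) dag@labels else paste0("X", seq_len(dag@d))
}

#' Write a fitted graph to disk
#'
#' Writes an edge-list TSV (`edges.tsv` with columns source, target
#' and, when `data` is supplied, the BIC increase caused by deleting
#' the edge), a Graphviz DOT file (`graph.dot`) and a JSON manifest
#' (`manifest.json`) with the total BIC, per-node parameters, sample
#' size, package version and any extra configuration passed in
#' `manifest`.
#'
#' @param fit a [GraphFit-class].
#' @param outdir output directory (created if missing).
#' @param data the count matrix used for fitting; needed for the
#'   per-edge BIC deltas (NA otherwise).
#' @param manifest named list merged into the manifest (e.g. the seed
#'   and run configuration).
#' @param control,cache passed to the refits behind the BIC deltas.
#' @return the output directory, invisibly.
#' @export
writeGraph <- function(fit, outdir, data = NULL, manifest = list(),
                       control = zigControl(), cache = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dag <- fit@dag
  lab <- .nodeLabels(dag)
  E <- dag@edges
  delta <- rep(NA_real_, nrow(E))
  if (!is.null(data) && nrow(E)) {
    data <- .checkData(data)
    if (is.null(cache)) cache <- newFitCache()
    for (r in seq_len(nrow(E))) {
      k <- E[r, 2L]
      pa <- parents(dag, k)
      without <- .localFit(data, k, setdiff(pa, E[r, 1L]),
                           fit@nodeFits[[k]]@family,
                           fit@nodeFits[[k]]@mode, control, cache)
      delta[r] <- without@bic - fit@nodeFits[[k]]@bic
    }
  }
  edf <- data.frame(source = lab[E[, 1L]], target = lab[E[, 2L]],
                    bic_delta_if_deleted = delta)
  utils::write.table(edf, file.path(outdir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dot <- c("digraph fit {",
           paste0("  \"", lab, "\";"),
           if (nrow(E)) paste0("  \"", lab[E[, 1L]], "\" -> \"",
                               lab[E[, 2L]], "\";"),
           "}")
  writeLines(dot, file.path(outdir, "graph.dot"))
  man <- c(list(
    package = "zigdag",
    version = as.character(utils::packageVersion("zigdag")),
    n = fit@n,
    totalBIC = fit@bic,
    nodes = lab,
    edges = edf[, c("source", "target")],
    nodeFits = lapply(fit@nodeFits, function(f)
      list(node = f@node, parents = f@parents, family = f@family,
           mode = f@mode, loglik = f@loglik, npar = f@npar, bic = f@bic,
           coef = f@coef, converged = f@converged))),
    manifest)
  jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
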