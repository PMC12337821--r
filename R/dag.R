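# acyclicity by Kahn's algorithm on the edge list
.isAcyclicEdges <- function(d, edges) {
  if (nrow(edges) == 0L || d <= 1L) return(TRUE)
  indeg <- tabulate(edges[, 2L], nbins = d)
  adj <- split(edges[, 2L], factor(edges[, 1L], levels = seq_len(d)))
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen == d
}

#' Construct a DAG structure
#'
#' @param d number of nodes (labelled 1..d).
#' @param edges two-column matrix (from, to) of directed edges, or NULL
#'   for the empty graph.
#' @param labels optional character node labels.
#' @return a [DAGStructure-class]; construction fails on cycles,
#'   self-loops or duplicate edges.
#' @examples
#' dagStructure(3, rbind(c(1, 3), c(2, 3)))
#' @export
dagStructure <- function(d, edges = NULL, labels = character(0)) {
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  methods::new("DAGStructure", d = as.integer(d), edges = edges,
               labels = as.character(labels))
}

#' DAG accessors
#'
#' `parents()`/`childrenOf()` return the parent/child node indices of
#' `j`; `nonDescendants()` the nodes not reachable from `j` (excluding
#' `j`); `edgeMatrix()` the 2-column edge list; `nNodes()` the node
#' count; `adjacencyMatrix()` a d x d 0/1 matrix with `[j, k] = 1` for
#' j -> k; `topologicalOrder()` a topological ordering of the nodes.
#'
#' @param dag a [DAGStructure-class].
#' @param j a node index.
#' @return see above.
#' @name dag-accessors
NULL

#' @rdname dag-accessors
#' @export
setGeneric("parents", function(dag, j) standardGeneric("parents"))

#' @rdname dag-accessors
#' @export
setMethod("parents", "DAGStructure", function(dag, j) {
  dag@edges[dag@edges[, 2L] == j, 1L]
})

#' @rdname dag-accessors
#' @export
setGeneric("childrenOf", function(dag, j) standardGeneric("childrenOf"))

#' @rdname dag-accessors
#' @export
setMethod("childrenOf", "DAGStructure", function(dag, j) {
  dag@edges[dag@edges[, 1L] == j, 2L]
})

#' @rdname dag-accessors
#' @export
nNodes <- function(dag) dag@d

#' @rdname dag-accessors
#' @export
edgeMatrix <- function(dag) dag@edges

#' @rdname dag-accessors
#' @export
adjacencyMatrix <- function(dag) {
  A <- matrix(0L, dag@d, dag@d)
  if (nrow(dag@edges)) A[dag@edges] <- 1L
  A
}

#' @rdname dag-accessors
#' @export
topologicalOrder <- function(dag) {
  d <- dag@d
  E <- dag@edges
  indeg <- tabulate(E[, 2L], nbins = d)
  adj <- split(E[, 2L], factor(E[, 1L], levels = seq_len(d)))
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) != d) stop("graph contains a directed cycle")
  order
}

#' @rdname dag-accessors
#' @export
nonDescendants <- function(dag, j) {
  # BFS over children
  reach <- logical(dag@d)
  queue <- childrenOf(dag, j)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (!reach[v]) {
      reach[v] <- TRUE
      queue <- c(queue, childrenOf(dag, v))
    }
  }
  setdiff(which(!reach), j)
}

setMethod("show", "DAGStructure", function(object) {
  cat(sprintf("DAGStructure: %d nodes, %d edges\n", object@d,
              nrow(object@edges)))
  if (nrow(object@edges)) {
    lab <- if (length(object@labels)) object@labels else
      as.character(seq_len(object@d))
    e <- apply(object@edges, 1L, function(r)
      paste0(lab[r[1L]], " -> ", lab[r[2L]]))
    cat(" ", paste(e, collapse = ", "), "\n")
  }
})

#' Enumerate all labelled DAGs on d nodes
#'
#' Every unordered node pair takes one of three states (no edge,
#' forward, backward); the 3^(d(d-1)/2) directed graphs are filtered
#' for acyclicity. Intended for exhaustive search on small graphs; the
#' count grows super-exponentially (1, 3, 25, 543, 29281 for d = 1..5),
#' so `d` is guarded.
#'
#' @param d number of nodes (at most 5).
#' @return list of [DAGStructure-class], each labelled DAG exactly once.
#' @export
enumerateDags <- function(d) {
  d <- as.integer(d)
  if (d > 5L)
    stop("exhaustive enumeration is limited to d <= 5; ",
         "use hillClimb() or tabuSearch() for larger graphs")
  if (d < 1L) stop("d must be >= 1")
  if (d == 1L) return(list(dagStructure(1L)))
  pairs <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  npairs <- nrow(pairs)
  states <- do.call(expand.grid, rep(list(0:2), npairs))
  out <- vector("list", nrow(states))
  kept <- 0L
  for (g in seq_len(nrow(states))) {
    st <- as.integer(states[g, ])
    from <- ifelse(st == 1L, pairs[, 1L], pairs[, 2L])
    keep <- st != 0L
    E <- cbind(from[keep], ifelse(st == 1L, pairs[, 2L], pairs[, 1L])[keep])
    if (.isAcyclicEdges(d, E)) {
      kept <- kept + 1L
      out[[kept]] <- dagStructure(d, E)
    }
  }
  out[seq_len(kept)]
}
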