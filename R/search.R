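# --- local-move machinery -------------------------------------------------

# adjacency list of children per node
.adjList <- function(d, edges) {
  split(edges[, 2L], factor(edges[, 1L], levels = seq_len(d)))
}

.hasPath <- function(d, edges, from, to) {
  if (from == to) return(TRUE)
  adj <- .adjList(d, edges)
  seen <- logical(d)
  queue <- adj[[from]]
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (v == to) return(TRUE)
    if (!seen[v]) {
      seen[v] <- TRUE
      queue <- c(queue, adj[[v]])
    }
  }
  FALSE
}

.dropEdgeRow <- function(edges, from, to) {
  keep <- !(edges[, 1L] == from & edges[, 2L] == to)
  edges[keep, , drop = FALSE]
}

# feasible local moves in deterministic lexicographic order
# (type: add < delete < reverse, then source, then target)
.neighborhoodMoves <- function(d, edges, maxInDegree = Inf) {
  A <- matrix(FALSE, d, d)
  if (nrow(edges)) A[edges] <- TRUE
  indeg <- tabulate(edges[, 2L], nbins = d)
  moves <- list()
  for (j in seq_len(d)) for (k in seq_len(d)) {
    if (j == k || A[j, k] || A[k, j]) next
    if (indeg[k] + 1L > maxInDegree) next
    if (.hasPath(d, edges, k, j)) next # j -> k would close a cycle
    moves[[length(moves) + 1L]] <- list(type = "add", from = j, to = k)
  }
  if (nrow(edges)) {
    ord <- order(edges[, 1L], edges[, 2L])
    for (r in ord)
      moves[[length(moves) + 1L]] <-
        list(type = "delete", from = edges[r, 1L], to = edges[r, 2L])
    for (r in ord) {
      j <- edges[r, 1L]; k <- edges[r, 2L]
      if (indeg[j] + 1L > maxInDegree) next
      rest <- .dropEdgeRow(edges, j, k)
      if (.hasPath(d, rest, j, k)) next # k -> j would close a cycle
      moves[[length(moves) + 1L]] <- list(type = "reverse", from = j, to = k)
    }
  }
  moves
}

.applyMove <- function(edges, mv) {
  switch(mv$type,
    add = rbind(edges, c(mv$from, mv$to)),
    delete = .dropEdgeRow(edges, mv$from, mv$to),
    reverse = rbind(.dropEdgeRow(edges, mv$from, mv$to),
                    c(mv$to, mv$from)))
}

.reverseOfMove <- function(mv) {
  switch(mv$type,
    add = list(type = "delete", from = mv$from, to = mv$to),
    delete = list(type = "add", from = mv$from, to = mv$to),
    reverse = list(type = "reverse", from = mv$to, to = mv$from))
}

.sameMove <- function(a, b) {
  a$type == b$type && a$from == b$from && a$to == b$to
}

# BIC change of a move: add/delete refit the target node only,
# reversal refits the two affected nodes (score decomposability)
.moveDelta <- function(data, edges, mv, local, family, mode, control,
                       cache) {
  newE <- .applyMove(edges, mv)
  d <- length(local)
  affected <- if (mv$type == "reverse") c(mv$from, mv$to) else mv$to
  delta <- 0
  newLocal <- local
  for (nd in affected) {
    pa <- newE[newE[, 2L] == nd, 1L]
    fit <- .localFit(data, nd, pa, family, mode, control, cache)
    newLocal[nd] <- fit@bic
    delta <- delta + fit@bic - local[nd]
  }
  list(delta = delta, local = newLocal, edges = newE)
}

.initSearch <- function(data, g0, family, mode, control, cache) {
  d <- ncol(data)
  if (is.null(g0)) g0 <- dagStructure(d)
  if (g0@d != d) stop("initial DAG has ", g0@d, " nodes, data has ", d)
  local <- vapply(seq_len(d), function(j)
    .localFit(data, j, parents(g0, j), family, mode, control, cache)@bic,
    numeric(1))
  list(edges = g0@edges, local = local)
}

.asGraphFit <- function(data, edges, family, mode, control, cache) {
  scoreGraph(data, dagStructure(ncol(data), edges), family = family,
             mode = mode, control = control, cache = cache)
}

#' Hill-climbing structure search
#'
#' Best-improvement greedy minimization of the BIC over the space of
#' DAGs. At each iteration all graphs reachable from the current one
#' by a single edge addition, deletion or reversal (cycle-creating
#' moves skipped) are scored, and the largest BIC decrease is taken;
#' the search stops when no move improves the score by more than
#' `control$improvementTol`. Ties are broken deterministically by
#' (move type, source, target), so the result is reproducible given
#' the data and the initial graph.
#'
#' @param data n x d matrix of non-negative integer counts.
#' @param g0 initial [DAGStructure-class]; default the empty graph.
#' @param family,mode,control see [scoreGraph()].
#' @param cache a [newFitCache()] environment (created when NULL); pass
#'   `FALSE` to disable caching.
#' @param verbose print accepted moves.
#' @return a [GraphFit-class] at the local optimum.
#' @export
hillClimb <- function(data, g0 = NULL, family = "hyper_poisson",
                      mode = c("linear", "nonlinear"),
                      control = zigControl(), cache = NULL,
                      verbose = FALSE) {
  mode <- match.arg(mode)
  data <- .checkData(data)
  if (isFALSE(cache)) cache <- NULL else if (is.null(cache)) cache <- newFitCache()
  st <- .initSearch(data, g0, family, mode, control, cache)
  edges <- st$edges; local <- st$local
  repeat {
    moves <- .neighborhoodMoves(ncol(data), edges, control$maxInDegree)
    best <- NULL
    bestDelta <- -control$improvementTol
    for (mv in moves) {
      cand <- .moveDelta(data, edges, mv, local, family, mode, control,
                         cache)
      if (cand$delta < bestDelta) {
        bestDelta <- cand$delta
        best <- cand
        best$mv <- mv
      }
    }
    if (is.null(best)) break
    if (verbose)
      message(sprintf("%s %d -> %d (delta BIC %.4f)", best$mv$type,
                      best$mv$from, best$mv$to, bestDelta))
    edges <- best$edges
    local <- best$local
  }
  .asGraphFit(data, edges, family, mode, control, cache)
}

#' Tabu structure search
#'
#' Greedy BIC minimization that keeps moving after reaching a local
#' optimum: at every iteration the best feasible non-tabu move is
#' applied even if it worsens the score. Moves applied within the last
#' `t` iterations may not be reversed (adding j -> k forbids deleting
#' it for `t` steps, and vice versa; a reversal forbids the opposite
#' reversal). The search stops after `s` consecutive iterations
#' without improving on the incumbent, and returns the best DAG found
#' anywhere during the search, not the DAG at which it stops.
#'
#' @inheritParams hillClimb
#' @param s number of additionally allowed steps after the last
#'   improvement.
#' @param t tabu-list length.
#' @return a [GraphFit-class] for the best-scoring DAG visited.
#' @export
tabuSearch <- function(data, g0 = NULL, s = 10L, t = 10L,
                       family = "hyper_poisson",
                       mode = c("linear", "nonlinear"),
                       control = zigControl(), cache = NULL,
                       verbose = FALSE) {
  stopifnot(s >= 0L, t >= 0L)
  mode <- match.arg(mode)
  data <- .checkData(data)
  if (isFALSE(cache)) cache <- NULL else if (is.null(cache)) cache <- newFitCache()
  st <- .initSearch(data, g0, family, mode, control, cache)
  edges <- st$edges; local <- st$local
  bestEdges <- edges
  bestTotal <- sum(local)
  tabu <- list()
  lastImprovement <- 0L
  while (lastImprovement < s) {
    moves <- .neighborhoodMoves(ncol(data), edges, control$maxInDegree)
    if (length(tabu)) {
      banned <- lapply(tabu, .reverseOfMove)
      moves <- Filter(function(mv)
        !any(vapply(banned, .sameMove, logical(1), b = mv)), moves)
    }
    best <- NULL
    bestDelta <- Inf
    for (mv in moves) {
      cand <- .moveDelta(data, edges, mv, local, family, mode, control,
                         cache)
      if (cand$delta < bestDelta) {
        bestDelta <- cand$delta
        best <- cand
        best$mv <- mv
      }
    }
    if (is.null(best)) {
      # every neighborhood move is tabu: counts as a non-improving step
      if (verbose) message("all moves tabu; counting a non-improving step")
      lastImprovement <- lastImprovement + 1L
      next
    }
    edges <- best$edges
    local <- best$local
    if (t > 0L) {
      tabu <- c(tabu, list(best$mv))
      if (length(tabu) > t) tabu <- tabu[-1L]
    }
    total <- sum(local)
    if (total < bestTotal - control$improvementTol) {
      bestTotal <- total
      bestEdges <- edges
      lastImprovement <- 0L
    } else {
      lastImprovement <- lastImprovement + 1L
    }
    if (verbose)
      message(sprintf("%s %d -> %d | BIC %.4f | best %.4f | stale %d",
                      best$mv$type, best$mv$from, best$mv$to, total,
                      bestTotal, lastImprovement))
  }
  .asGraphFit(data, bestEdges, family, mode, control, cache)
}
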