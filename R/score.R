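#' Fit cache
#'
#' Local scores are decomposable: a node's fit depends only on its
#' parent set (plus mode/family), so fits are cached by
#' `(node, parent set, mode, family)` and reused across graphs and
#' search iterations. Fitting the same key twice returns the identical
#' object.
#'
#' @return an environment usable as the `cache` argument of
#'   [scoreGraph()], [hillClimb()] and [tabuSearch()].
#' @export
newFitCache <- function() new.env(parent = emptyenv())

.cacheKey <- function(node, pa, mode, family) {
  paste(node, paste(sort(pa), collapse = ","), mode, family, sep = "|")
}

.localFit <- function(data, node, pa, family, mode, control, cache) {
  pa <- sort(pa)
  if (!is.null(cache)) {
    key <- .cacheKey(node, pa, mode, family)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  # warm starts from cached fits of one-smaller parent sets: the
  # optimizer is seeded at the nested optimum with zero coefficients
  # for the new parent, so a superset never scores a worse likelihood
  warm <- list()
  if (!is.null(cache) && length(pa)) {
    for (q in pa) {
      red <- setdiff(pa, q)
      rf <- cache[[.cacheKey(node, red, mode, family)]]
      if (!is.null(rf) && length(rf@coef) &&
          length(rf@details$design$keep) == length(red)) {
        th <- .expandTheta(rf@coef, red, pa, mode, family, control)
        if (!is.null(th)) warm[[length(warm) + 1L]] <- th
      }
    }
  }
  fit <- fitNode(data[, node], data[, pa, drop = FALSE], family = family,
                 mode = mode, control = control, node = node,
                 parentSet = pa, warmStarts = warm)
  if (!is.null(cache)) cache[[key]] <- fit
  fit
}

# embed a fitted theta for parent set `red` into the parameter space of
# the superset `pa` (sorted), zero-filling the new parent's block
.expandTheta <- function(coef, red, pa, mode, family, control) {
  ne <- .nExtras(family)
  bf <- if (mode == "linear") 1L else control$Mf
  bg <- if (mode == "linear") 1L else control$Mg
  Pr <- 1L + bf * length(red); Qr <- 1L + bg * length(red)
  if (length(coef) != Pr + Qr + ne) return(NULL)
  P <- 1L + bf * length(pa); Q <- 1L + bg * length(pa)
  th <- numeric(P + Q + ne)
  th[1L] <- coef[1L]
  th[P + 1L] <- coef[Pr + 1L]
  pos <- match(red, pa)
  for (i in seq_along(red)) {
    th[1L + (pos[i] - 1L) * bf + seq_len(bf)] <-
      coef[1L + (i - 1L) * bf + seq_len(bf)]
    th[P + 1L + (pos[i] - 1L) * bg + seq_len(bg)] <-
      coef[Pr + 1L + (i - 1L) * bg + seq_len(bg)]
  }
  if (ne) th[P + Q + 1L] <- coef[Pr + Qr + 1L]
  th
}

.checkData <- function(data) {
  data <- as.matrix(data)
  if (any(data < 0) || any(data != round(data)))
    stop("data must be a matrix of non-negative integer counts")
  storage.mode(data) <- "integer"
  data
}

#' Score a DAG by BIC
#'
#' Fits each node's conditional model given its parents in `dag` and
#' returns the fitted graph with its total BIC
#' \eqn{\mathrm{BIC}(\mathcal{G}) = -2 \sum_i \log p(x^{(i)} \mid
#' \hat\theta, \mathcal{G}) + |\theta| \log n}, which decomposes
#' exactly as the sum of the per-node local scores. Lower is better.
#'
#' @param data n x d matrix of non-negative integer counts (columns =
#'   variables).
#' @param dag a [DAGStructure-class] with `d` nodes.
#' @param family GHPD family for the node conditionals.
#' @param mode `"linear"` or `"nonlinear"`.
#' @param control a [zigControl()] list.
#' @param cache optional [newFitCache()] environment.
#' @return a [GraphFit-class].
#' @export
scoreGraph <- function(data, dag, family = "hyper_poisson",
                       mode = c("linear", "nonlinear"),
                       control = zigControl(), cache = NULL) {
  mode <- match.arg(mode)
  data <- .checkData(data)
  if (ncol(data) != dag@d)
    stop("data has ", ncol(data), " columns but the DAG has ", dag@d,
         " nodes")
  fits <- lapply(seq_len(dag@d), function(j)
    .localFit(data, j, parents(dag, j), family, mode, control, cache))
  methods::new("GraphFit", dag = dag, nodeFits = fits,
               bic = sum(vapply(fits, function(f) f@bic, numeric(1))),
               n = nrow(data))
}

#' Exhaustive search over all DAGs
#'
#' Scores every labelled DAG on `d <= 5` nodes (see [enumerateDags()])
#' and returns the BIC-minimizing fit. Local scores are shared across
#' graphs through the fit cache, so the cost is one fit per distinct
#' (node, parent set) pair.
#'
#' @inheritParams scoreGraph
#' @param cache optional fit cache; created internally when NULL.
#' @return a [GraphFit-class] attaining the minimum BIC.
#' @export
exhaustiveSearch <- function(data, family = "hyper_poisson",
                             mode = c("linear", "nonlinear"),
                             control = zigControl(), cache = NULL) {
  mode <- match.arg(mode)
  data <- .checkData(data)
  if (is.null(cache)) cache <- newFitCache()
  dags <- enumerateDags(ncol(data))
  best <- NULL
  for (g in dags) {
    fit <- scoreGraph(data, g, family = family, mode = mode,
                      control = control, cache = cache)
    if (is.null(best) || fit@bic < best@bic) best <- fit
  }
  best
}

setMethod("show", "GraphFit", function(object) {
  cat(sprintf("GraphFit: %d nodes, %d edges, n = %d, BIC = %.4f\n",
              object@dag@d, nrow(object@dag@edges), object@n, object@bic))
  methods::show(object@dag)
})

#' GraphFit accessors
#'
#' @param fit a [GraphFit-class].
#' @return `totalBIC()`: the total BIC; `dagOf()`: the
#'   [DAGStructure-class]; `nodeFits()`: the list of per-node
#'   [NodeFit-class] objects.
#' @name graphfit-accessors
NULL

#' @rdname graphfit-accessors
#' @export
totalBIC <- function(fit) fit@bic

#' @rdname graphfit-accessors
#' @export
dagOf <- function(fit) fit@dag

#' @rdname graphfit-accessors
#' @export
nodeFits <- function(fit) fit@nodeFits
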