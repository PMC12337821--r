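#' @title Core classes
#' @description S4 classes for generalized hypergeometric count
#'   distributions, zero-inflated mixtures, DAG structures and fitted
#'   graphs.
#' @name zigdag-classes
#' @keywords internal
NULL

.FAMILY_TAGS <- c("poisson", "hyper_poisson", "negative_binomial", "custom")

#' GHPDFamily: a generalized hypergeometric probability distribution
#'
#' A count distribution whose probability generating function is the
#' ratio \eqn{F_{pq}(a; b; \lambda s) / F_{pq}(a; b; \lambda)} of
#' generalized hypergeometric functions. Supported named families:
#' Poisson (\eqn{{}_0F_0}), hyper-Poisson (\eqn{{}_1F_1(1;\psi;\cdot)})
#' and negative binomial (\eqn{{}_1F_0(k;;\cdot)} with
#' \eqn{\lambda = q \in (0,1)}). Arbitrary positive-parameter families
#' are accepted as `custom` (no sampling guarantees).
#'
#' @slot familyTag character, one of `"poisson"`, `"hyper_poisson"`,
#'   `"negative_binomial"`, `"custom"`.
#' @slot a numeric, numerator parameters (length p).
#' @slot b numeric, denominator parameters (length q, each > 0).
#' @slot lam numeric(1), power parameter \eqn{\lambda > 0}; for the
#'   negative binomial (literal parametrization) \eqn{\lambda \in (0,1)}.
#' @exportClass GHPDFamily
setClass("GHPDFamily",
  representation(familyTag = "character", a = "numeric", b = "numeric",
                 lam = "numeric"),
  prototype(familyTag = "poisson", a = numeric(0), b = numeric(0), lam = 1))

setValidity("GHPDFamily", function(object) {
  msg <- character(0)
  if (length(object@familyTag) != 1L || !object@familyTag %in% .FAMILY_TAGS)
    msg <- c(msg, sprintf("familyTag must be one of: %s",
                          paste(.FAMILY_TAGS, collapse = ", ")))
  if (length(object@lam) != 1L || !is.finite(object@lam) || object@lam <= 0)
    msg <- c(msg, "lam must be a single finite value > 0")
  if (any(!is.finite(object@a))) msg <- c(msg, "a must be finite")
  if (any(!is.finite(object@b)) || any(object@b <= 0))
    msg <- c(msg, "b entries must be finite and > 0")
  if (object@familyTag == "negative_binomial" &&
      length(object@lam) == 1L && object@lam >= 1)
    msg <- c(msg, "negative binomial requires lam = q in (0,1)")
  # series must converge: p <= q, or p = q+1 with |lam| < 1
  p <- length(object@a); q <- length(object@b)
  if (p > q + 1L)
    msg <- c(msg, "divergent series: need p <= q + 1")
  if (p == q + 1L && length(object@lam) == 1L && abs(object@lam) >= 1)
    msg <- c(msg, "divergent series: p = q + 1 requires |lam| < 1")
  if (length(msg)) msg else TRUE
})

#' ZICount: a zero-inflated GHPD
#'
#' Mixture placing extra mass `pi` at zero on top of a [GHPDFamily-class]
#' base distribution: \eqn{P(X=0) = \pi + (1-\pi)\,\mathrm{GHP}(0)} and
#' \eqn{P(X=x) = (1-\pi)\,\mathrm{GHP}(x)} for \eqn{x \ge 1}.
#'
#' @slot pi numeric(1), zero-inflation probability in \[0, 1); `pi = 0`
#'   is the degenerate pass-through.
#' @slot base a [GHPDFamily-class].
#' @exportClass ZICount
setClass("ZICount",
  representation(pi = "numeric", base = "GHPDFamily"),
  prototype(pi = 0))

setValidity("ZICount", function(object) {
  if (length(object@pi) != 1L || !is.finite(object@pi) ||
      object@pi < 0 || object@pi >= 1)
    return("pi must be a single value in [0, 1)")
  TRUE
})

#' DAGStructure: a directed acyclic graph on d labelled nodes
#'
#' Nodes are `1..d`; edges are ordered pairs (j, k) meaning j -> k.
#' Acyclicity is enforced by the validity method.
#'
#' @slot d integer(1), number of nodes.
#' @slot edges integer matrix with 2 columns (from, to); zero rows for
#'   the empty graph.
#' @slot labels character, optional node labels (length d).
#' @exportClass DAGStructure
setClass("DAGStructure",
  representation(d = "integer", edges = "matrix", labels = "character"),
  prototype(d = 0L, edges = matrix(integer(0), ncol = 2), labels = character(0)))

setValidity("DAGStructure", function(object) {
  d <- object@d
  E <- object@edges
  if (length(d) != 1L || is.na(d) || d < 0L) return("d must be a single non-negative integer")
  if (!is.matrix(E) || ncol(E) != 2L) return("edges must be a 2-column matrix")
  if (nrow(E) > 0) {
    if (any(E < 1L) || any(E > d)) return("edge endpoints must be in 1..d")
    if (any(E[, 1L] == E[, 2L])) return("self-loops are not allowed")
    key <- (E[, 1L] - 1L) * d + E[, 2L]
    if (anyDuplicated(key)) return("duplicate edges")
  }
  if (length(object@labels) && length(object@labels) != d)
    return("labels must have length d")
  if (!.isAcyclicEdges(d, E)) return("graph contains a directed cycle")
  TRUE
})

#' NodeFit: one node's fitted conditional model
#'
#' @slot node integer(1), the child node.
#' @slot parents integer, parent node indices (possibly empty).
#' @slot mode character(1), `"linear"` or `"nonlinear"`.
#' @slot family character(1), GHPD family tag.
#' @slot coef numeric, fitted parameters on the unconstrained scale
#'   (zero-inflation block, intensity block, extras).
#' @slot loglik numeric(1), maximized log-likelihood.
#' @slot npar integer(1), number of free parameters.
#' @slot bic numeric(1), local BIC contribution
#'   \eqn{-2\,\ell + |\theta|\log n}.
#' @slot converged logical(1).
#' @slot details list, optimizer diagnostics and spline bookkeeping.
#' @exportClass NodeFit
setClass("NodeFit",
  representation(node = "integer", parents = "integer", mode = "character",
                 family = "character", coef = "numeric", loglik = "numeric",
                 npar = "integer", bic = "numeric", converged = "logical",
                 details = "list"),
  prototype(converged = TRUE, details = list()))

#' GraphFit: a scored DAG
#'
#' A [DAGStructure-class] with per-node maximum-likelihood fits, local
#' BICs and the total BIC (the exact sum of the local scores).
#'
#' @slot dag a [DAGStructure-class].
#' @slot nodeFits list of [NodeFit-class], one per node.
#' @slot bic numeric(1), total BIC.
#' @slot n integer(1), sample size used for scoring.
#' @exportClass GraphFit
setClass("GraphFit",
  representation(dag = "DAGStructure", nodeFits = "list", bic = "numeric",
                 n = "integer"))

setValidity("GraphFit", function(object) {
  if (length(object@nodeFits) != object@dag@d)
    return("need one NodeFit per node")
  tot <- sum(vapply(object@nodeFits, function(f) f@bic, numeric(1)))
  if (is.finite(object@bic) && abs(tot - object@bic) > 1e-8 * max(1, abs(tot)))
    return("total BIC must equal the sum of local BICs")
  TRUE
})

#' SimConfig: a synthetic-data generative design
#'
#' @slot scenario character(1): `"zi_linear"`, `"zi_nonlinear"`,
#'   `"nb_no_zi"`, `"confounder_a"` or `"confounder_b"`.
#' @slot d integer(1), number of nodes.
#' @slot n integer(1), sample size.
#' @slot nEdges integer(1), number of edges in the random sparse DAG.
#' @slot family character(1), GHPD family of the node conditionals.
#' @slot ranges list, parameter-sampling ranges (uniform endpoints).
#' @slot seed integer(1) or NA, RNG seed.
#' @slot options list, scenario-specific switches (e.g. `sigma` for the
#'   confounding designs, `f3Form` for the exponential nonlinearity).
#' @exportClass SimConfig
setClass("SimConfig",
  representation(scenario = "character", d = "integer", n = "integer",
                 nEdges = "integer", family = "character", ranges = "list",
                 seed = "integer", options = "list"),
  prototype(scenario = "zi_linear", family = "hyper_poisson",
            seed = NA_integer_, options = list()))

setValidity("SimConfig", function(object) {
  ok <- c("zi_linear", "zi_nonlinear", "nb_no_zi", "confounder_a", "confounder_b")
  if (!object@scenario %in% ok)
    return(sprintf("scenario must be one of: %s", paste(ok, collapse = ", ")))
  if (object@d < 1L || object@n < 1L) return("d and n must be >= 1")
  maxE <- object@d * (object@d - 1L) / 2
  if (object@nEdges > maxE)
    return(sprintf("nEdges = %d infeasible for d = %d (max %d)",
                   object@nEdges, object@d, maxE))
  TRUE
})
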