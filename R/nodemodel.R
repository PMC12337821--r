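#' Node conditional models
#'
#' A node's conditional distribution given its parents is a
#' zero-inflated GHPD whose zero-inflation probability and power
#' parameter are driven by the parents through predictors:
#' `logit(pi_j) = sum_k alpha_jk X_k + delta_j` and
#' `h(lambda_j) = sum_k beta_jk X_k + gamma_j` for the linear model, or
#' cubic B-spline additive predictors
#' `logit(pi_j) = sum_k f_jk(X_k) + mu_j`,
#' `h(lambda_j) = sum_k g_jk(X_k) + nu_j` for the nonlinear model.
#' The link `h` is log for exp-domain power parameters (Poisson mean,
#' hyper-Poisson lambda, negative-binomial mean) and logit for the
#' literal negative-binomial success parameter.
#'
#' @name node-models
#' @keywords internal
NULL

#' LinearNodeModel
#'
#' @slot alpha numeric, per-parent coefficients for logit(pi).
#' @slot delta numeric(1), zero-inflation intercept.
#' @slot beta numeric, per-parent coefficients for h(lambda).
#' @slot gamma numeric(1), intensity intercept.
#' @slot extras named numeric, family extras on the natural scale
#'   (`psi` for hyper-Poisson, `size` for negative binomial).
#' @slot link character(1), `"log"` or `"logit"`.
#' @exportClass LinearNodeModel
setClass("LinearNodeModel",
  representation(alpha = "numeric", delta = "numeric", beta = "numeric",
                 gamma = "numeric", extras = "numeric", link = "character"),
  prototype(link = "log", extras = numeric(0)))

#' SplineNodeModel
#'
#' @slot zeta list of per-parent spline coefficients for the f_jk.
#' @slot eta list of per-parent spline coefficients for the g_jk.
#' @slot mu numeric(1), zero-inflation intercept.
#' @slot nu numeric(1), intensity intercept.
#' @slot knotsF,knotsG lists of per-parent `list(knots, boundary)`.
#' @slot Mf,Mg integer(1), basis sizes.
#' @slot centersF,centersG numeric, training-sample means of the
#'   per-parent fitted functions (identifiability normalization: the
#'   centered functions have mean zero over the data, the shift being
#'   absorbed into the intercepts).
#' @slot extras named numeric, family extras on the natural scale.
#' @slot link character(1).
#' @exportClass SplineNodeModel
setClass("SplineNodeModel",
  representation(zeta = "list", eta = "list", mu = "numeric", nu = "numeric",
                 knotsF = "list", knotsG = "list", Mf = "integer",
                 Mg = "integer", centersF = "numeric", centersG = "numeric",
                 extras = "numeric", link = "character"),
  prototype(link = "log", extras = numeric(0)))

#' @rdname node-models
#' @param alpha,delta,beta,gamma,extras,link see the class slots.
#' @export
linearNodeModel <- function(alpha = numeric(0), delta = 0,
                            beta = numeric(0), gamma = 0,
                            extras = numeric(0), link = "log") {
  methods::new("LinearNodeModel", alpha = alpha, delta = delta, beta = beta,
               gamma = gamma, extras = extras, link = link)
}

#' Fitting control parameters
#'
#' @param tol optimizer convergence tolerance (relative).
#' @param maxit maximum optimizer iterations per restart.
#' @param restarts number of optimizer starts (zeros,
#'   moment-informed, deterministic perturbation, in that order).
#' @param maxTerms series truncation cap.
#' @param lamCap upper bound on the intensity parameter enforced by a
#'   soft barrier during fitting (series-safe range).
#' @param Mf,Mg spline basis sizes for the nonlinear model.
#' @param nbParametrization `"mean"` (log link on the mean, default) or
#'   `"literal"` (logit link on the success parameter q).
#' @param sampleCap truncation cap for inverse-CDF sampling.
#' @param improvementTol minimum BIC decrease counted as an improvement
#'   by the searches (guards against float-noise cycling).
#' @param maxInDegree optional cap on the number of parents per node
#'   during search (`Inf` = none).
#' @return a named list of class `zigControl`.
#' @export
zigControl <- function(tol = 1e-8, maxit = 300L, restarts = 3L,
                       maxTerms = 10000L, lamCap = 1e3, Mf = 4L, Mg = 4L,
                       nbParametrization = c("mean", "literal"),
                       sampleCap = 10000L, improvementTol = 1e-9,
                       maxInDegree = Inf) {
  structure(list(tol = tol, maxit = as.integer(maxit),
                 restarts = as.integer(restarts),
                 maxTerms = as.integer(maxTerms), lamCap = lamCap,
                 Mf = as.integer(Mf), Mg = as.integer(Mg),
                 nbParametrization = match.arg(nbParametrization),
                 sampleCap = as.integer(sampleCap),
                 improvementTol = improvementTol,
                 maxInDegree = maxInDegree),
            class = "zigControl")
}

.famCode <- function(family, control) {
  switch(family,
    poisson = 0L,
    hyper_poisson = 1L,
    negative_binomial = if (control$nbParametrization == "literal") 3L else 2L,
    stop("unsupported fitting family: ", family))
}

.nExtras <- function(family) if (family == "poisson") 0L else 1L

.vmaxFor <- function(family, control) {
  if (family == "hyper_poisson") log(control$lamCap) else 50
}

# Build design matrices (intercept first). For the nonlinear mode each
# parent contributes a reduced cubic B-spline block; constant parents
# are skipped with a warning rather than failing the whole search.
.buildDesigns <- function(Xparents, mode, control) {
  n <- nrow(Xparents)
  p <- ncol(Xparents)
  if (mode == "linear" || p == 0L) {
    Z <- cbind(1, Xparents)
    return(list(Zpi = Z, Zlam = Z, keep = seq_len(p),
                knotsF = list(), knotsG = list(),
                nparPi = 1L + p, nparLam = 1L + p))
  }
  keep <- which(apply(Xparents, 2L, function(col) length(unique(col)) > 1L))
  if (length(keep) < p)
    warning("skipping constant parent column(s): ",
            paste(setdiff(seq_len(p), keep), collapse = ", "))
  Zpi <- matrix(1, n, 1L); Zlam <- matrix(1, n, 1L)
  knotsF <- list(); knotsG <- list()
  for (k in keep) {
    Bf <- splineBasis(Xparents[, k], M = control$Mf)
    Bg <- splineBasis(Xparents[, k], M = control$Mg)
    knotsF[[length(knotsF) + 1L]] <- list(knots = attr(Bf, "knots"),
                                          boundary = attr(Bf, "boundary"))
    knotsG[[length(knotsG) + 1L]] <- list(knots = attr(Bg, "knots"),
                                          boundary = attr(Bg, "boundary"))
    Zpi <- cbind(Zpi, Bf)
    Zlam <- cbind(Zlam, Bg)
  }
  list(Zpi = Zpi, Zlam = Zlam, keep = keep, knotsF = knotsF, knotsG = knotsG,
       nparPi = ncol(Zpi), nparLam = ncol(Zlam))
}

.makeObjective <- function(x, Zpi, Zlam, famCode, vmax, maxTerms) {
  lastTheta <- NULL
  lastRes <- NULL
  evalAt <- function(th) {
    if (is.null(lastTheta) || !identical(th, lastTheta)) {
      lastRes <<- zig_nll_cpp(th, x, Zpi, Zlam, famCode, vmax, maxTerms)
      lastTheta <<- th
    }
    lastRes
  }
  list(fn = function(th) evalAt(th)$value,
       gr = function(th) evalAt(th)$gradient)
}

.initThetas <- function(x, des, family, famCode, control) {
  P <- des$nparPi; Q <- des$nparLam
  ne <- .nExtras(family)
  pz <- min(max(mean(x == 0), 0.02), 0.98)
  mu0 <- max(mean(x), 0.1)
  mpos <- if (any(x > 0)) mean(x[x > 0]) else mu0 + 0.1
  vdisp <- if (mu0 > 0) stats::var(x) / mu0 else 1
  gammaOf <- function(m) {
    if (famCode == 3L) stats::qlogis(min(max(m / (m + 1), 0.02), 0.98))
    else log(m)
  }
  # start 1: intercepts from marginal moments, coefficients zero
  th1 <- numeric(P + Q + ne)
  th1[1L] <- stats::qlogis(pz)
  th1[P + 1L] <- gammaOf(mu0)
  # start 2: regression-informed (the standard two-part recipe):
  # logistic regression of the zero indicator for the inflation block,
  # Poisson GLM on the positive counts for the intensity block
  th2 <- th1
  th2[1L] <- stats::qlogis(min(max(0.8 * pz, 0.02), 0.98))
  th2[P + 1L] <- gammaOf(mpos)
  if (P > 1L) {
    piFit <- tryCatch(suppressWarnings(
      stats::glm.fit(des$Zpi, as.numeric(x == 0),
                     family = stats::binomial())$coefficients),
      error = function(e) NULL)
    if (!is.null(piFit) && all(is.finite(piFit))) th2[seq_len(P)] <- piFit
  }
  if (Q > 1L && famCode != 3L && sum(x > 0) > Q) {
    pos <- x > 0
    lamFit <- tryCatch(suppressWarnings(
      stats::glm.fit(des$Zlam[pos, , drop = FALSE], x[pos],
                     family = stats::poisson())$coefficients),
      error = function(e) NULL)
    if (!is.null(lamFit) && all(is.finite(lamFit)))
      th2[P + seq_len(Q)] <- lamFit
  }
  if (ne) th2[P + Q + 1L] <- log(min(max(vdisp, 0.2), 5))
  # start 3: fixed perturbation of the regression start (a
  # deterministic stand-in for a random restart)
  th3 <- th2 + 0.3 * rep_len(c(1, -1), length(th2))
  list(th1, th2, th3)[seq_len(min(3L, control$restarts))]
}

#' Fit one node's conditional model by maximum likelihood
#'
#' Numerically maximizes the zero-inflated GHPD log-likelihood of
#' `xj` given its parents over the unconstrained parametrization
#' (logit/log/link-transformed) by bounded quasi-Newton (L-BFGS-B) with
#' analytic gradients, using several deterministic restarts. Returns
#' the best fit with its local BIC contribution
#' \eqn{-2\ell + |\theta| \log n}.
#'
#' @param xj integer vector, the node's observed counts.
#' @param Xparents integer matrix of parent columns (NULL or 0-column
#'   for a root node).
#' @param family `"poisson"`, `"hyper_poisson"` or
#'   `"negative_binomial"`.
#' @param mode `"linear"` or `"nonlinear"` (cubic B-spline additive).
#' @param control a [zigControl()] list.
#' @param node optional node index recorded in the result.
#' @param parentSet optional integer vector of parent node indices
#'   recorded in the result (defaults to the column positions of
#'   `Xparents`).
#' @param warmStarts optional list of additional starting values on
#'   the unconstrained scale (e.g. nested-model optima); entries whose
#'   length does not match the design are ignored.
#' @return a [NodeFit-class]; if no optimizer start produces a finite
#'   maximum the fit is flagged (`converged = FALSE`) with infinite
#'   BIC.
#' @examples
#' set.seed(1)
#' x <- ziSample(ziCount(0.3, poissonFamily(2)), 400)
#' fitNode(x, NULL, family = "poisson")
#' @export
fitNode <- function(xj, Xparents = NULL, family = "hyper_poisson",
                    mode = c("linear", "nonlinear"),
                    control = zigControl(), node = NA_integer_,
                    parentSet = NULL, warmStarts = list()) {
  mode <- match.arg(mode)
  xj <- as.integer(xj)
  if (any(xj < 0)) stop("counts must be non-negative")
  n <- length(xj)
  if (is.null(Xparents)) Xparents <- matrix(0L, n, 0L)
  Xparents <- as.matrix(Xparents)
  storage.mode(Xparents) <- "double"
  if (nrow(Xparents) != n) stop("xj and Xparents lengths disagree")
  if (is.null(parentSet)) parentSet <- seq_len(ncol(Xparents))
  parentSet <- as.integer(parentSet)

  des <- .buildDesigns(Xparents, mode, control)
  famCode <- .famCode(family, control)
  ne <- .nExtras(family)
  vmax <- .vmaxFor(family, control)
  obj <- .makeObjective(xj, des$Zpi, des$Zlam, famCode, vmax,
                        control$maxTerms)
  starts <- .initThetas(xj, des, family, famCode, control)
  npTotal <- des$nparPi + des$nparLam + .nExtras(family)
  warmStarts <- Filter(function(th) length(th) == npTotal, warmStarts)
  starts <- c(warmStarts, starts)

  best <- NULL
  for (th0 in starts) {
    res <- tryCatch(
      stats::optim(th0, obj$fn, obj$gr, method = "L-BFGS-B",
                   control = list(maxit = control$maxit, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e7) next
    if (is.null(best) || res$value < best$value) best <- res
  }

  npar <- des$nparPi + des$nparLam + ne
  if (is.null(best)) {
    return(methods::new("NodeFit", node = as.integer(node),
                        parents = parentSet, mode = mode,
                        family = family, coef = numeric(0), loglik = -Inf,
                        npar = as.integer(npar), bic = Inf,
                        converged = FALSE,
                        details = list(message = "no start converged")))
  }
  loglik <- -best$value
  bic <- 2 * best$value + npar * log(n)
  model <- .extractModel(best$par, des, Xparents, mode, family, famCode,
                         control)
  methods::new("NodeFit", node = as.integer(node),
               parents = parentSet, mode = mode, family = family,
               coef = best$par, loglik = loglik, npar = as.integer(npar),
               bic = bic, converged = best$convergence == 0L,
               details = list(model = model, design = des[c("keep", "knotsF",
                                                            "knotsG")],
                              optim = best[c("convergence", "counts")]))
}

.extractModel <- function(theta, des, Xparents, mode, family, famCode,
                          control) {
  P <- des$nparPi; Q <- des$nparLam
  link <- if (famCode == 3L) "logit" else "log"
  extras <- if (.nExtras(family)) {
    val <- exp(theta[P + Q + 1L])
    stats::setNames(val, if (family == "hyper_poisson") "psi" else "size")
  } else numeric(0)
  if (mode == "linear") {
    p <- P - 1L
    return(linearNodeModel(alpha = theta[seq_len(p) + 1L],
                           delta = theta[1L],
                           beta = theta[P + 1L + seq_len(Q - 1L)],
                           gamma = theta[P + 1L],
                           extras = extras, link = link))
  }
  # spline model: split coefficient blocks per kept parent and center
  Mf <- control$Mf; Mg <- control$Mg
  nk <- length(des$keep)
  zeta <- list(); eta <- list()
  centersF <- numeric(nk); centersG <- numeric(nk)
  for (i in seq_len(nk)) {
    zi <- theta[1L + (i - 1L) * Mf + seq_len(Mf)]
    ei <- theta[P + 1L + (i - 1L) * Mg + seq_len(Mg)]
    zeta[[i]] <- zi; eta[[i]] <- ei
    k <- des$keep[i]
    Bf <- splineBasis(Xparents[, k], M = Mf,
                      knots = des$knotsF[[i]]$knots,
                      boundary = des$knotsF[[i]]$boundary)
    Bg <- splineBasis(Xparents[, k], M = Mg,
                      knots = des$knotsG[[i]]$knots,
                      boundary = des$knotsG[[i]]$boundary)
    centersF[i] <- mean(Bf %*% zi)
    centersG[i] <- mean(Bg %*% ei)
  }
  methods::new("SplineNodeModel", zeta = zeta, eta = eta,
               mu = theta[1L], nu = theta[P + 1L],
               knotsF = des$knotsF, knotsG = des$knotsG,
               Mf = as.integer(Mf), Mg = as.integer(Mg),
               centersF = centersF, centersG = centersG,
               extras = extras, link = link)
}

#' Evaluate a fitted nonlinear component function
#'
#' Returns the centered fitted `f_jk` (zero-inflation side) or `g_jk`
#' (intensity side) of a [SplineNodeModel-class] at `x`: the raw spline
#' value minus its training-sample mean, so the displayed functions
#' average zero over the data (the shift sits in the intercept).
#'
#' @param model a [SplineNodeModel-class].
#' @param k parent position (index into the model's coefficient lists).
#' @param x evaluation points.
#' @param which `"f"` or `"g"`.
#' @return numeric vector of centered function values.
#' @export
splineFunctionValues <- function(model, k, x, which = c("f", "g")) {
  which <- match.arg(which)
  stopifnot(methods::is(model, "SplineNodeModel"))
  if (which == "f") {
    B <- splineBasis(x, M = model@Mf, knots = model@knotsF[[k]]$knots,
                     boundary = model@knotsF[[k]]$boundary)
    drop(B %*% model@zeta[[k]]) - model@centersF[k]
  } else {
    B <- splineBasis(x, M = model@Mg, knots = model@knotsG[[k]]$knots,
                     boundary = model@knotsG[[k]]$boundary)
    drop(B %*% model@eta[[k]]) - model@centersG[k]
  }
}

#' Log-likelihood of a node model on data
#'
#' Sum of zero-inflated GHPD log-masses of `xj` with per-row
#' `pi` and `lambda` computed from the model's predictors.
#'
#' @param model a [LinearNodeModel-class] or [SplineNodeModel-class].
#' @param xj integer vector of counts.
#' @param Xparents parent count matrix (columns in the model's parent
#'   order), or NULL for a root model.
#' @param family GHPD family tag; inferred from the extras when
#'   missing.
#' @param control a [zigControl()] list.
#' @return numeric(1), the log-likelihood.
#' @export
nodeLoglik <- function(model, xj, Xparents = NULL, family = NULL,
                       control = zigControl()) {
  xj <- as.integer(xj)
  n <- length(xj)
  if (is.null(Xparents)) Xparents <- matrix(0L, n, 0L)
  Xparents <- as.matrix(Xparents)
  storage.mode(Xparents) <- "double"
  if (is.null(family))
    family <- if ("psi" %in% names(model@extras)) "hyper_poisson"
      else if ("size" %in% names(model@extras)) "negative_binomial"
      else "poisson"
  if (model@link == "logit" && family == "negative_binomial")
    control$nbParametrization <- "literal"
  famCode <- .famCode(family, control)
  ne <- .nExtras(family)
  extra <- if (ne) log(unname(model@extras[1L])) else numeric(0)

  if (methods::is(model, "LinearNodeModel")) {
    Z <- cbind(1, Xparents)
    theta <- c(model@delta, model@alpha, model@gamma, model@beta, extra)
    res <- zig_nll_cpp(theta, xj, Z, Z, famCode,
                       .vmaxFor(family, control), control$maxTerms)
    return(-res$value)
  }
  stopifnot(methods::is(model, "SplineNodeModel"))
  Zpi <- matrix(1, n, 1L); Zlam <- matrix(1, n, 1L)
  for (i in seq_along(model@zeta)) {
    Zpi <- cbind(Zpi, splineBasis(Xparents[, i], M = model@Mf,
                                  knots = model@knotsF[[i]]$knots,
                                  boundary = model@knotsF[[i]]$boundary))
    Zlam <- cbind(Zlam, splineBasis(Xparents[, i], M = model@Mg,
                                    knots = model@knotsG[[i]]$knots,
                                    boundary = model@knotsG[[i]]$boundary))
  }
  theta <- c(model@mu, unlist(model@zeta), model@nu, unlist(model@eta),
             extra)
  res <- zig_nll_cpp(theta, xj, Zpi, Zlam, famCode,
                     .vmaxFor(family, control), control$maxTerms)
  -res$value
}

setMethod("show", "NodeFit", function(object) {
  cat(sprintf(
    "NodeFit node %s | parents {%s} | %s/%s | loglik %.4f | npar %d | BIC %.4f%s\n",
    object@node, paste(object@parents, collapse = ","), object@mode,
    object@family, object@loglik, object@npar, object@bic,
    if (object@converged) "" else " [not converged]"))
})

setMethod("show", "LinearNodeModel", function(object) {
  cat("LinearNodeModel:",
      sprintf("logit(pi) = %s%.3f", .coefStr(object@alpha), object@delta),
      sprintf("; %s(lambda) = %s%.3f", object@link, .coefStr(object@beta),
              object@gamma),
      if (length(object@extras))
        sprintf("; %s = %.3f", names(object@extras), object@extras) else "",
      "\n", sep = "")
})

.coefStr <- function(co) {
  if (!length(co)) return("")
  paste0(paste(sprintf("%.3f x%d", co, seq_along(co)), collapse = " + "),
         " + ")
}

setMethod("show", "SplineNodeModel", function(object) {
  cat(sprintf(
    "SplineNodeModel: %d parent(s), Mf = %d, Mg = %d, mu = %.3f, nu = %.3f%s\n",
    length(object@zeta), object@Mf, object@Mg, object@mu, object@nu,
    if (length(object@extras))
      sprintf(", %s = %.3f", names(object@extras), object@extras) else ""))
})
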