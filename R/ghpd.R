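#' Generalized hypergeometric function
#'
#' Evaluates \eqn{{}_pF_q(a_1,\dots,a_p; b_1,\dots,b_q; z) =
#' \sum_{i \ge 0} \frac{(a_1)_i \cdots (a_p)_i}{(b_1)_i \cdots (b_q)_i}
#' \frac{z^i}{i!}} by direct series summation, where \eqn{(a)_i}
#' denotes the ascending factorial. Summation stops when the relative
#' increment falls below `tol` or after `maxTerms` terms.
#'
#' The series converges for all z when p <= q, and for |z| < 1 when
#' p = q + 1; other configurations are rejected.
#'
#' @param a numeric vector of numerator parameters (may be empty).
#' @param b numeric vector of denominator parameters (may be empty;
#'   entries must avoid non-positive integers).
#' @param z numeric(1) evaluation point.
#' @param tol relative-increment stopping tolerance.
#' @param maxTerms maximum number of series terms.
#' @return numeric(1), the value of the series.
#' @examples
#' ghf(numeric(0), numeric(0), 1)    # exp(1)
#' ghf(1, 2, 1)                      # exp(1) - 1
#' @export
ghf <- function(a, b, z, tol = 1e-12, maxTerms = 10000L) {
  p <- length(a); q <- length(b)
  if (p > q + 1L)
    stop("divergent series: p = ", p, " > q + 1 = ", q + 1L)
  if (p == q + 1L && abs(z) >= 1)
    stop("divergent series: p = q + 1 requires |z| < 1, got |z| = ", abs(z))
  if (!is.finite(z)) stop("z must be finite")
  if (any(b <= 0 & b == round(b)))
    stop("denominator parameters must avoid non-positive integers")
  term <- 1; total <- 1
  for (i in seq_len(maxTerms) - 1L) {
    num <- if (p) prod(a + i) else 1
    den <- if (q) prod(b + i) else 1
    term <- term * num * z / (den * (i + 1))
    if (!is.finite(term)) stop("non-finite series term at i = ", i + 1L)
    total <- total + term
    if (abs(term) < tol * max(1, abs(total)) && i > 2L) return(total)
  }
  stop("series did not converge within ", maxTerms, " terms")
}

#' GHPD family constructors
#'
#' Build [GHPDFamily-class] objects for the supported named families,
#' or an arbitrary positive-parameter family via `ghpdFamily()`.
#'
#' * `poissonFamily(lambda)`: pgf \eqn{{}_0F_0(;;\lambda s)/{}_0F_0(;;\lambda)
#'   = e^{\lambda(s-1)}}; `lambda` is the mean.
#' * `hyperPoissonFamily(psi, lambda)`: pgf
#'   \eqn{{}_1F_1(1;\psi;\lambda s)/{}_1F_1(1;\psi;\lambda)};
#'   overdispersed for \eqn{\psi > 1}, underdispersed for \eqn{\psi < 1},
#'   Poisson at \eqn{\psi = 1}.
#' * `nbFamily(size, prob = , mu = )`: negative binomial, pgf
#'   \eqn{{}_1F_0(k;;qs)/{}_1F_0(k;;q)} with success-related power
#'   parameter \eqn{\lambda = q \in (0,1)} and size \eqn{k > 0}. Supply
#'   either `prob` (= q) or the mean `mu` (then q = mu / (mu + size)).
#'
#' @param lambda,psi,size,prob,mu family parameters (see above).
#' @param a,b,lam raw \eqn{F_{pq}} parameters for `ghpdFamily()`.
#' @return a [GHPDFamily-class] object.
#' @examples
#' hyperPoissonFamily(psi = 2, lambda = 1)
#' nbFamily(size = 2, mu = 3)
#' @name ghpd-families
NULL

#' @rdname ghpd-families
#' @export
poissonFamily <- function(lambda) {
  methods::new("GHPDFamily", familyTag = "poisson", a = numeric(0),
               b = numeric(0), lam = as.numeric(lambda))
}

#' @rdname ghpd-families
#' @export
hyperPoissonFamily <- function(psi, lambda) {
  stopifnot(psi > 0)
  methods::new("GHPDFamily", familyTag = "hyper_poisson", a = 1,
               b = as.numeric(psi), lam = as.numeric(lambda))
}

#' @rdname ghpd-families
#' @export
nbFamily <- function(size, prob = NULL, mu = NULL) {
  stopifnot(size > 0)
  if (is.null(prob) == is.null(mu))
    stop("supply exactly one of 'prob' (success parameter q) or 'mu'")
  q <- if (!is.null(prob)) prob else mu / (mu + size)
  methods::new("GHPDFamily", familyTag = "negative_binomial",
               a = as.numeric(size), b = numeric(0), lam = as.numeric(q))
}

#' @rdname ghpd-families
#' @export
ghpdFamily <- function(a, b, lam) {
  methods::new("GHPDFamily", familyTag = "custom", a = as.numeric(a),
               b = as.numeric(b), lam = as.numeric(lam))
}

# log ascending factorial log (a)_x for a > 0
.lpoch <- function(a, x) lgamma(a + x) - lgamma(a)

#' GHPD probability mass function
#'
#' \eqn{P(X = x) = \frac{(a_1)_x \cdots (a_p)_x \lambda^x}
#' {(b_1)_x \cdots (b_q)_x \, x!} \big/ F_{pq}(a; b; \lambda)}.
#' Ascending factorials are computed in log space; parameters are
#' restricted to the positive-parameter families.
#'
#' @param fam a [GHPDFamily-class].
#' @param x vector of non-negative integers.
#' @param log logical, return log-probabilities.
#' @return numeric vector of (log-)probabilities.
#' @examples
#' ghpdPmf(poissonFamily(1), 2)          # dpois(2, 1)
#' ghpdPmf(hyperPoissonFamily(2, 1), 0)  # 1 / (e - 1)
#' @export
ghpdPmf <- function(fam, x, log = FALSE) {
  stopifnot(methods::is(fam, "GHPDFamily"))
  methods::validObject(fam)
  if (any(x < 0) || any(x != round(x)))
    stop("x must contain non-negative integers")
  lognorm <- log(ghf(fam@a, fam@b, fam@lam))
  lp <- vapply(x, function(xi) {
    sum(.lpoch(fam@a, xi)) - sum(.lpoch(fam@b, xi)) +
      xi * log(fam@lam) - lgamma(xi + 1)
  }, numeric(1)) - lognorm
  if (log) lp else exp(lp)
}

#' GHPD probability generating function
#'
#' \eqn{G(s) = F_{pq}(a; b; \lambda s) / F_{pq}(a; b; \lambda)};
#' \eqn{G(1) = 1}.
#'
#' @param fam a [GHPDFamily-class].
#' @param s numeric vector of evaluation points.
#' @return numeric vector, G(s).
#' @export
ghpdPgf <- function(fam, s) {
  stopifnot(methods::is(fam, "GHPDFamily"))
  den <- ghf(fam@a, fam@b, fam@lam)
  vapply(s, function(si) ghf(fam@a, fam@b, fam@lam * si) / den, numeric(1))
}

# pmf table p_0..p_cap via the term ratio recurrence
# p_{x+1}/p_x = prod(a+x) * lam / (prod(b+x) * (x+1))
.ghpdPmfTable <- function(fam, cap = 10000L, tol = 1e-12) {
  p0 <- 1 / ghf(fam@a, fam@b, fam@lam)
  probs <- numeric(256L)
  probs[1L] <- p0
  cdf <- p0
  x <- 0L
  while (cdf < 1 - tol && x < cap) {
    num <- if (length(fam@a)) prod(fam@a + x) else 1
    den <- if (length(fam@b)) prod(fam@b + x) else 1
    nxt <- probs[x + 1L] * num * fam@lam / (den * (x + 1))
    x <- x + 1L
    if (x + 1L > length(probs)) probs <- c(probs, numeric(length(probs)))
    probs[x + 1L] <- nxt
    cdf <- cdf + nxt
  }
  if (cdf < 1 - tol)
    stop("cumulative mass reached only ", format(cdf),
         " before cap = ", cap, "; increase the cap")
  probs[seq_len(x + 1L)]
}

#' Sample from a GHPD
#'
#' Inverse-CDF sampling by cumulative series accumulation: the pmf is
#' accumulated through the term-ratio recurrence until the cumulative
#' mass reaches 1 - `tol` (an error names the cap if it is hit first).
#'
#' @param fam a [GHPDFamily-class].
#' @param n number of draws.
#' @param cap truncation cap for the support.
#' @param tol cumulative-mass tolerance.
#' @return integer vector of length n.
#' @export
ghpdSample <- function(fam, n, cap = 10000L, tol = 1e-12) {
  stopifnot(n >= 1)
  probs <- .ghpdPmfTable(fam, cap = cap, tol = tol)
  findInterval(stats::runif(n), cumsum(probs))
}

#' Zero-inflated GHPD construction and evaluation
#'
#' `ziCount()` wraps a [GHPDFamily-class] with a zero-inflation
#' probability `pi`; `ziPmf()` evaluates the mixture mass
#' \eqn{P(X=0) = \pi + (1-\pi)\mathrm{GHP}(0)},
#' \eqn{P(X=x) = (1-\pi)\mathrm{GHP}(x)} for \eqn{x \ge 1};
#' `ziSample()` draws a zero-inflation indicator with probability `pi`
#' and otherwise samples the base GHPD by inverse CDF.
#'
#' @param pi zero-inflation probability in \[0, 1); `pi = 0` is the
#'   degenerate pass-through to the base distribution.
#' @param base,m a [GHPDFamily-class] / [ZICount-class].
#' @param x vector of non-negative integers.
#' @param log logical, return log-probabilities.
#' @param n number of draws.
#' @param cap,tol see [ghpdSample()].
#' @return `ziCount`: a [ZICount-class]; `ziPmf`: numeric vector;
#'   `ziSample`: integer vector.
#' @examples
#' m <- ziCount(0.3, poissonFamily(1))
#' ziPmf(m, 0:2)
#' @export
ziCount <- function(pi, base) {
  methods::new("ZICount", pi = as.numeric(pi), base = base)
}

#' @rdname ziCount
#' @export
ziPmf <- function(m, x, log = FALSE) {
  stopifnot(methods::is(m, "ZICount"))
  methods::validObject(m)
  base <- ghpdPmf(m@base, x, log = FALSE)
  p <- ifelse(x == 0, m@pi + (1 - m@pi) * base, (1 - m@pi) * base)
  if (log) base::log(p) else p
}

#' @rdname ziCount
#' @export
ziSample <- function(m, n, cap = 10000L, tol = 1e-12) {
  stopifnot(methods::is(m, "ZICount"), n >= 1)
  inflated <- stats::runif(n) < m@pi
  out <- integer(n)
  k <- sum(!inflated)
  if (k > 0) out[!inflated] <- ghpdSample(m@base, k, cap = cap, tol = tol)
  out
}

setMethod("show", "GHPDFamily", function(object) {
  cat(sprintf("GHPDFamily '%s': %dF%d(a = [%s]; b = [%s]; lam = %g)\n",
              object@familyTag, length(object@a), length(object@b),
              paste(format(object@a), collapse = ", "),
              paste(format(object@b), collapse = ", "), object@lam))
})

setMethod("show", "ZICount", function(object) {
  cat(sprintf("ZICount: pi = %g over\n  ", object@pi))
  methods::show(object@base)
})

#' GHPD moments via the probability generating function
#'
#' Mean and variance from the factorial moments
#' \eqn{G'(1)} and \eqn{G''(1)}: differentiating the series gives
#' \eqn{F_{pq}'(a;b;z) = \frac{\prod_i a_i}{\prod_j b_j}
#' F_{pq}(a+1; b+1; z)}, so both derivatives are ratios of shifted
#' series.
#'
#' @param fam a [GHPDFamily-class].
#' @return named numeric vector `c(mean, var)`.
#' @examples
#' ghpdMoments(poissonFamily(3))       # mean = var = 3
#' ghpdMoments(nbFamily(2, prob = 0.4))
#' @export
ghpdMoments <- function(fam) {
  stopifnot(methods::is(fam, "GHPDFamily"))
  a <- fam@a; b <- fam@b; lam <- fam@lam
  F0 <- ghf(a, b, lam)
  c1 <- (if (length(a)) prod(a) else 1) / (if (length(b)) prod(b) else 1)
  F1 <- ghf(a + 1, b + 1, lam)
  c2 <- (if (length(a)) prod(a * (a + 1)) else 1) /
        (if (length(b)) prod(b * (b + 1)) else 1)
  F2 <- ghf(a + 2, b + 2, lam)
  m1 <- lam * c1 * F1 / F0          # G'(1) = E X
  fm2 <- lam^2 * c2 * F2 / F0      # G''(1) = E X(X-1)
  c(mean = m1, var = fm2 + m1 - m1^2)
}
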