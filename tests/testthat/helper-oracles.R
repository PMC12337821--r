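# Independent oracles, deliberately implemented apart from the package
# internals they check.

# ascending factorial (a)_x by direct product
pochDirect <- function(a, x) {
  if (x == 0) return(1)
  prod(a + seq_len(x) - 1)
}

# unnormalized GHPD series term, direct products (no logs)
ghpdTermDirect <- function(a, b, lam, x) {
  num <- if (length(a)) prod(vapply(a, pochDirect, numeric(1), x = x)) else 1
  den <- if (length(b)) prod(vapply(b, pochDirect, numeric(1), x = x)) else 1
  num * lam^x / (den * factorial(x))
}

# generalized hypergeometric function by naive partial sums; the
# term is built multiplicatively (still log-free) so it decays before
# the raw factorials can overflow
ghfDirect <- function(a, b, z, terms = 300) {
  term <- 1
  total <- 1
  for (i in 0:(terms - 1)) {
    num <- if (length(a)) prod(a + i) else 1
    den <- if (length(b)) prod(b + i) else 1
    term <- term * num * z / (den * (i + 1))
    total <- total + term
    if (abs(term) < 1e-16 * total) break
  }
  total
}

# Cox-de Boor recursion for B-spline basis evaluation (textbook form)
coxDeBoor <- function(x, knots, ord) {
  nb <- length(knots) - ord
  B <- matrix(0, length(x), nb)
  for (j in seq_len(nb)) {
    B[, j] <- vapply(x, function(xi) {
      bspl <- function(i, k) {
        if (k == 1)
          return(as.numeric(xi >= knots[i] & xi < knots[i + 1]))
        d1 <- knots[i + k - 1] - knots[i]
        d2 <- knots[i + k] - knots[i + 1]
        t1 <- if (d1 > 0) (xi - knots[i]) / d1 * bspl(i, k - 1) else 0
        t2 <- if (d2 > 0) (knots[i + k] - xi) / d2 * bspl(i + 1, k - 1) else 0
        t1 + t2
      }
      bspl(j, ord)
    }, numeric(1))
  }
  B
}

# brute-force count of labelled DAGs: every subset of ordered pairs,
# acyclicity via igraph
countDagsBrute <- function(d) {
  pairs <- expand.grid(from = seq_len(d), to = seq_len(d))
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- nrow(pairs)
  count <- 0L
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    g <- igraph::graph_from_data_frame(pairs[sel, , drop = FALSE],
                                       directed = TRUE,
                                       vertices = data.frame(seq_len(d)))
    if (igraph::is_dag(g)) count <- count + 1L
  }
  count
}

# small linear zero-inflated hyper-Poisson dataset with a known graph,
# built through the package generator
makeLinearSim <- function(d = 3, n = 500, seed = 1, ...) {
  simulateLinear(simConfig("zi_linear", d = d, n = n, seed = seed,
                           nEdges = min(d, d * (d - 1) / 2), ...))
}
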