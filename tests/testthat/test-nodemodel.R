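test_that("spline basis matches the Cox-de Boor recursion oracle", {
  x <- 0:10
  # full basis, one interior knot at 5: partition of unity inside
  B <- splineBasis(x, M = 5, knots = 5)
  expect_equal(rowSums(B), rep(1, length(x)), tolerance = 1e-12)
  kv <- c(rep(0, 4), 5, rep(10, 4))
  pts <- seq(0.25, 9.75, by = 0.5) # off-knot points: the textbook
  O <- coxDeBoor(pts, kv, 4)       # recursion uses half-open intervals
  expect_equal(unname(splineBasis(pts, M = 5, knots = 5,
                                  boundary = c(0, 10))[, ]), O,
               tolerance = 1e-12)
  # intercept-adjusted convention drops the first function
  B4 <- splineBasis(x, M = 4, knots = 5)
  expect_equal(ncol(B4), 4)
  expect_equal(unname(B4[, ]), unname(B[, -1]))
  # finite and non-negative at the boundary knots
  Bb <- splineBasis(c(0, 10), M = 5, knots = 5)
  expect_true(all(is.finite(Bb)) && all(Bb >= 0))
  expect_error(splineBasis(rep(2, 10), M = 4), "degenerate")
})

test_that("intercept-only fits reproduce the iid zero-inflated likelihood", {
  set.seed(3)
  x <- ziSample(ziCount(0.35, hyperPoissonFamily(2, 2)), 800)
  f0 <- fitNode(x, NULL, family = "hyper_poisson")
  expect_true(is.finite(f0@bic))
  expect_equal(f0@npar, 3L) # delta, gamma, log psi
  expect_equal(f0@bic, -2 * f0@loglik + 3 * log(800), tolerance = 1e-10)
  # all-coefficients-zero model evaluated through nodeLoglik equals the
  # same intercepts without parents
  mod <- f0@details$model
  llNoPar <- nodeLoglik(mod, x, NULL)
  withPar <- linearNodeModel(alpha = 0, delta = mod@delta, beta = 0,
                             gamma = mod@gamma, extras = mod@extras)
  junk <- sample(0:3, 800, replace = TRUE)
  expect_equal(nodeLoglik(withPar, x, matrix(junk)), llNoPar,
               tolerance = 1e-10)
  # a pure-noise parent cannot decrease -2 loglik but raises the BIC
  f1 <- fitNode(x, matrix(junk), family = "hyper_poisson",
                control = zigControl())
  expect_gte(f1@loglik, f0@loglik - 1e-4)
  expect_gt(f1@bic, f0@bic)
})

test_that("maximum likelihood recovers generating parameters within 3 SE", {
  set.seed(11)
  n <- 5000
  xp <- zigdag:::.ziSampleVec(rep(plogis(-1), n), rep(exp(1), n),
                              "hyper_poisson", psi = 5)
  x <- zigdag:::.ziSampleVec(plogis(-1 + xp), exp(1 - xp),
                             "hyper_poisson", psi = 5)
  fit <- fitNode(x, matrix(xp), family = "hyper_poisson")
  truth <- c(-1, 1, 1, -1, log(5)) # delta, alpha, gamma, beta, log psi
  Z <- cbind(1, as.double(xp))
  nll <- function(th)
    zigdag:::zig_nll_cpp(th, as.integer(x), Z, Z, 1L, log(1e3), 10000L)$value
  se <- sqrt(diag(solve(optimHess(fit@coef, nll))))
  expect_true(all(abs(fit@coef - truth) <= 3 * se))
})

test_that("degenerate all-zero response is flagged rather than crashing", {
  x <- rep(0L, 100)
  f <- fitNode(x, NULL, family = "hyper_poisson")
  # boundary fit: finite or flagged, never an uncaught error
  expect_true(is.finite(f@bic) || !f@converged)
})

test_that("constant parent columns are skipped with a warning in spline mode", {
  set.seed(8)
  x <- ziSample(ziCount(0.3, hyperPoissonFamily(2, 2)), 300)
  Xp <- cbind(rep(2L, 300), sample(0:5, 300, replace = TRUE))
  expect_warning(f <- fitNode(x, Xp, mode = "nonlinear"), "constant")
  expect_true(is.finite(f@bic))
})

test_that("fitted spline component functions are centered over the data", {
  set.seed(21)
  sim <- simulateNonlinear(simConfig("zi_nonlinear", d = 3, n = 400,
                                     seed = 21))
  j <- sim$dag@edges[1, 2]; pa <- sim$dag@edges[1, 1]
  f <- fitNode(sim$data[, j], sim$data[, pa, drop = FALSE],
               mode = "nonlinear")
  mod <- f@details$model
  fv <- splineFunctionValues(mod, 1, sim$data[, pa], which = "f")
  gv <- splineFunctionValues(mod, 1, sim$data[, pa], which = "g")
  expect_equal(mean(fv), 0, tolerance = 1e-8)
  expect_equal(mean(gv), 0, tolerance = 1e-8)
})

test_that("parameter error decreases with sample size (consistency)", {
  errAt <- function(n, seed) {
    set.seed(seed)
    xp <- zigdag:::.ziSampleVec(rep(plogis(-1), n), rep(exp(1), n),
                                "hyper_poisson", psi = 5)
    x <- zigdag:::.ziSampleVec(plogis(-1 + xp), exp(1 - xp),
                               "hyper_poisson", psi = 5)
    fit <- fitNode(x, matrix(xp), family = "hyper_poisson")
    median(abs(fit@coef - c(-1, 1, 1, -1, log(5))))
  }
  errs <- vapply(c(500, 2000, 8000), function(n)
    median(vapply(1:3, function(s) errAt(n, 100 + s), numeric(1))),
    numeric(1))
  # monotone decrease within Monte-Carlo noise: allow small slack
  expect_lt(errs[3], errs[1] + 0.02)
  expect_lt(errs[2], errs[1] + 0.1)
})
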