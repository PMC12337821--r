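test_that("series evaluation matches closed forms and the direct-sum oracle", {
  # 0F0(;;z) = e^z and 1F1(1;2;z) = (e^z - 1)/z
  expect_equal(ghf(numeric(0), numeric(0), 1), exp(1), tolerance = 1e-12)
  expect_equal(ghf(numeric(0), numeric(0), 0), 1)
  for (z in c(0.3, 1, 2.5))
    expect_equal(ghf(1, 2, z), (exp(z) - 1) / z, tolerance = 1e-10)
  # against naive partial sums for assorted parameter sets
  cases <- list(list(a = 1, b = 2.5, z = 1.7),
                list(a = numeric(0), b = 3, z = 2),
                list(a = c(0.5, 1.5), b = c(2, 3), z = 0.8))
  for (cs in cases)
    expect_equal(ghf(cs$a, cs$b, cs$z), ghfDirect(cs$a, cs$b, cs$z),
                 tolerance = 1e-10)
  expect_error(ghf(c(1, 2), numeric(0), 0.5), "divergent")
  expect_error(ghf(1, numeric(0), 1.5), "divergent")
})

test_that("pmf agrees with closed forms, the term oracle, and normalizes", {
  expect_equal(ghpdPmf(poissonFamily(1), 2), dpois(2, 1), tolerance = 1e-12)
  # hyper-Poisson with psi = 1 reduces to Poisson pointwise
  hp1 <- hyperPoissonFamily(psi = 1, lambda = 2)
  expect_equal(ghpdPmf(hp1, 0:30), dpois(0:30, 2), tolerance = 1e-12)
  expect_equal(ghpdPmf(hp1, 0), exp(-2), tolerance = 1e-12)
  # 1/1F1(1;2;1) = 1/(e-1)
  expect_equal(ghpdPmf(hyperPoissonFamily(2, 1), 0), 1 / (exp(1) - 1),
               tolerance = 1e-12)
  # negative binomial literal parametrization equals dnbinom
  nb <- nbFamily(size = 3, prob = 0.4)
  expect_equal(ghpdPmf(nb, 0:20), dnbinom(0:20, size = 3, prob = 0.6),
               tolerance = 1e-12)
  # unnormalized-term oracle and normalization across a parameter grid
  for (fam in list(hyperPoissonFamily(0.5, 3), hyperPoissonFamily(5, 1),
                   nbFamily(2, prob = 0.7), poissonFamily(4))) {
    p <- ghpdPmf(fam, 0:200)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-10)
    norm <- ghfDirect(fam@a, fam@b, fam@lam)
    for (x in c(0, 1, 5))
      expect_equal(p[x + 1],
                   ghpdTermDirect(fam@a, fam@b, fam@lam, x) / norm,
                   tolerance = 1e-10)
  }
})

test_that("pgf is normalized at 1 and matches the empirical pgf of samples", {
  fam <- hyperPoissonFamily(2, 3)
  expect_equal(ghpdPgf(fam, 1), 1, tolerance = 1e-12)
  set.seed(42)
  x <- ghpdSample(fam, 1e5)
  for (s in c(0.2, 0.5, 0.9)) {
    emp <- mean(s^x)
    expect_equal(emp, ghpdPgf(fam, s), tolerance = 0.01)
  }
})

test_that("zero-inflated mixture mass and sampling behave as specified", {
  base <- poissonFamily(1)
  expect_equal(ziPmf(ziCount(0, base), 0:5), ghpdPmf(base, 0:5))
  m <- ziCount(0.3, base)
  expect_equal(ziPmf(m, 0), 0.3 + 0.7 * exp(-1), tolerance = 1e-12)
  expect_equal(ziPmf(m, 1), 0.7 * exp(-1), tolerance = 1e-12)
  expect_equal(sum(ziPmf(m, 0:50)), 1, tolerance = 1e-10)
  expect_error(ziCount(1.2, base), "pi")
  # dominated by inflation
  set.seed(1)
  z <- ziSample(ziCount(0.999, poissonFamily(5)), 1000)
  expect_gte(mean(z == 0), 0.99)
  # Monte-Carlo mean check and determinism
  set.seed(7)
  s1 <- ziSample(ziCount(0, poissonFamily(2)), 1e5)
  expect_lt(abs(mean(s1) - 2), 3 * sqrt(2 / 1e5))
  set.seed(123); a <- ziSample(m, 500)
  set.seed(123); b <- ziSample(m, 500)
  expect_identical(a, b)
})

test_that("sampling errors out when the cap truncates the support", {
  expect_error(ghpdSample(poissonFamily(50), 5, cap = 10L), "cap")
})

test_that("compiled likelihood agrees with the R-level mixture density", {
  set.seed(5)
  sim <- makeLinearSim(d = 2, n = 60, seed = 5)
  x <- sim$data[, 2]; xp <- sim$data[, 1]
  mod <- linearNodeModel(alpha = -0.2, delta = 0.1, beta = 0.25,
                         gamma = 0.6, extras = c(psi = 1.8))
  ll <- nodeLoglik(mod, x, matrix(xp))
  manual <- sum(vapply(seq_along(x), function(i) {
    pi <- plogis(0.1 - 0.2 * xp[i])
    lam <- exp(0.6 + 0.25 * xp[i])
    log(ziPmf(ziCount(pi, hyperPoissonFamily(1.8, lam)), x[i]))
  }, numeric(1)))
  expect_equal(ll, manual, tolerance = 1e-8)
})

test_that("pgf-derived moments match closed forms and empirical moments", {
  expect_equal(unname(ghpdMoments(poissonFamily(3))), c(3, 3),
               tolerance = 1e-10)
  nb <- nbFamily(size = 2, prob = 0.4) # mean kq/(1-q), var mean/(1-q)
  expect_equal(unname(ghpdMoments(nb)),
               c(2 * 0.4 / 0.6, 2 * 0.4 / 0.6 / 0.6), tolerance = 1e-10)
  hp <- hyperPoissonFamily(2.5, 3)
  mom <- ghpdMoments(hp)
  p <- ghpdPmf(hp, 0:400)
  expect_equal(mom[["mean"]], sum((0:400) * p), tolerance = 1e-8)
  expect_equal(mom[["var"]],
               sum((0:400)^2 * p) - sum((0:400) * p)^2, tolerance = 1e-8)
})
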