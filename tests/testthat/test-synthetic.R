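test_that("simulated data are integer counts from an acyclic truth, reproducibly", {
  for (cfg in list(simConfig("zi_linear", d = 6, n = 200, seed = 3),
                   simConfig("zi_nonlinear", d = 4, n = 150, seed = 3),
                   simConfig("nb_no_zi", d = 5, n = 150, seed = 3))) {
    sim <- simulateScenario(cfg)
    expect_true(all(sim$data >= 0) && all(sim$data == round(sim$data)))
    expect_equal(nrow(sim$dag@edges), cfg@nEdges)
    expect_silent(topologicalOrder(sim$dag))
    again <- simulateScenario(cfg)
    expect_identical(sim$data, again$data)
    expect_identical(sim$dag@edges, again$dag@edges)
  }
})

test_that("zero fraction of the linear design sits near one half", {
  zf <- vapply(1:20, function(s)
    mean(simulateLinear(simConfig("zi_linear", d = 50, n = 200,
                                  seed = 2000 + s))$data == 0),
    numeric(1))
  expect_gte(mean(zf), 0.40)
  expect_lte(mean(zf), 0.60)
})

test_that("no-edge designs give mutually independent columns", {
  sim <- simulateLinear(simConfig("zi_linear", d = 4, n = 400, seed = 31,
                                  nEdges = 0))
  suppressWarnings(p <- apply(combn(4, 2), 2, function(pr)
    cor.test(sim$data[, pr[1]], sim$data[, pr[2]],
             method = "spearman")$p.value))
  expect_gte(mean(p > 0.01), 0.75)
})

test_that("nonlinear candidate functions take their closed-form values", {
  cand <- zigdag:::.nonlinearCandidates()
  expect_equal(cand$f[[1]](0), 0)  # z(z-3)/2 at 0
  expect_equal(cand$f[[2]](0), 0)  # sin
  expect_equal(cand$f[[3]](2), 1)  # exp(z/2 - 1) at 2
  expect_equal(cand$g[[1]](1.5), 0) # parabola vertex
  expect_equal(cand$g[[2]](0), 1)  # cos
  expect_equal(cand$g[[3]](0), 0)  # -log(z+1)/2
  alt <- zigdag:::.nonlinearCandidates("expm1_half")
  expect_equal(alt$f[[3]](0), 0)   # exp(z/2) - 1 at 0
})

test_that("negative binomial network has fewer zeros and is overdispersed", {
  # same seed grid; the drawn graphs differ between generators, so the
  # comparison is on the mean over the grid
  zfPair <- vapply(1:20, function(s) {
    zi <- simulateLinear(simConfig("zi_linear", d = 10, n = 300,
                                   seed = 600 + s))
    nb <- simulateNbBn(simConfig("nb_no_zi", d = 10, n = 300,
                                 seed = 600 + s))
    c(mean(zi$data == 0), nb$zeroFraction)
  }, numeric(2))
  expect_lt(mean(zfPair[2, ]), mean(zfPair[1, ]))
  # root nodes: sample variance exceeds sample mean
  sim <- simulateNbBn(simConfig("nb_no_zi", d = 10, n = 2000, seed = 9))
  roots <- setdiff(seq_len(10), unique(sim$dag@edges[, 2]))
  disp <- vapply(roots, function(j)
    var(sim$data[, j]) > mean(sim$data[, j]), logical(1))
  expect_gte(mean(disp), 0.8)
})

test_that("confounder designs hide the third variable and honour sigma", {
  cfgA <- simConfig("confounder_a", seed = 12, options = list(sigma = 0.4))
  sim <- simulateConfounded(cfgA)
  expect_equal(ncol(sim$data), 2)
  expect_equal(length(sim$hidden), 250) # n = 250 by design
  expect_equal(sim$dag@edges, rbind(c(2L, 1L)))
  expect_equal(nrow(sim$fullDag@edges), 3)
  # sigma = 0 in scenario b: observed columns independent in the
  # generative law -> low correlation
  simB0 <- simulateConfounded(simConfig("confounder_b", seed = 13,
                                        options = list(sigma = 0)))
  expect_equal(nrow(simB0$dag@edges), 0)
  expect_lt(abs(cor(simB0$data[, 1], simB0$data[, 2])), 0.15)
  expect_error(simulateConfounded(
    simConfig("confounder_a", options = list(sigma = 1.5))), "sigma")
  # reproducibility
  expect_identical(simulateConfounded(cfgA)$data,
                   simulateConfounded(cfgA)$data)
})

test_that("root columns are uncorrelated across the generated graph", {
  sim <- simulateLinear(simConfig("zi_linear", d = 12, n = 500, seed = 55))
  roots <- setdiff(seq_len(12), unique(sim$dag@edges[, 2]))
  if (length(roots) >= 2) {
    cors <- abs(cor(sim$data[, roots]))
    expect_lt(max(cors[upper.tri(cors)]), 0.15)
  }
})
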