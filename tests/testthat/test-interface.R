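test_that("count matrices round-trip through TSV, CSV and MTX", {
  td <- withr::local_tempdir()
  m <- matrix(c(0L, 1L, 2L, 5L, 0L, 3L), nrow = 3,
              dimnames = list(NULL, c("geneA", "geneB")))
  tsv <- file.path(td, "counts.tsv")
  writeCounts(m, tsv)
  back <- readCounts(tsv)
  expect_equal(unname(back), unname(m))
  expect_equal(colnames(back), c("geneA", "geneB"))
  csv <- file.path(td, "counts.csv")
  write.csv(as.data.frame(m), csv, row.names = FALSE)
  expect_equal(colnames(readCounts(csv)), c("geneA", "geneB"))
  mtx <- file.path(td, "counts.mtx")
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx)
  cols <- file.path(td, "cols.txt")
  writeLines(colnames(m), cols)
  expect_equal(unname(readCounts(mtx, colNames = cols)), unname(m))
})

test_that("malformed counts are rejected with the offending cell named", {
  td <- withr::local_tempdir()
  bad <- file.path(td, "bad.tsv")
  writeLines(c("a\tb", "1\t-1", "0\t2"), bad)
  expect_error(readCounts(bad), "negative count at row 1, column 'b'")
  frac <- file.path(td, "frac.tsv")
  writeLines(c("a\tb", "1\t0.5"), frac)
  expect_error(readCounts(frac), "non-integer")
  zc <- file.path(td, "zc.tsv")
  writeLines(c("a\tb", "1\t0", "2\t0"), zc)
  expect_warning(readCounts(zc), "all-zero")
})

test_that("written graphs round-trip as initial DAGs and valid DOT", {
  sim <- makeLinearSim(d = 3, n = 200, seed = 19)
  fit <- scoreGraph(sim$data, sim$dag)
  td <- withr::local_tempdir()
  writeGraph(fit, td, data = sim$data, manifest = list(seed = 19))
  # edge list re-read as initial DAG reproduces the structure
  lab <- colnames(sim$data)
  back <- readEdgeList(file.path(td, "edges.tsv"), lab)
  o <- order(back@edges[, 1], back@edges[, 2])
  o2 <- order(sim$dag@edges[, 1], sim$dag@edges[, 2])
  expect_equal(back@edges[o, ], sim$dag@edges[o2, ])
  # DOT structure: one digraph block, one line per edge
  dot <- readLines(file.path(td, "graph.dot"))
  expect_match(dot[1], "^digraph")
  expect_equal(sum(grepl("->", dot)), nrow(sim$dag@edges))
  expect_equal(dot[length(dot)], "}")
  # manifest carries the configuration and a finite total BIC
  man <- jsonlite::read_json(file.path(td, "manifest.json"))
  expect_equal(man$seed, 19)
  expect_true(is.numeric(man$totalBIC))
  # empty graph: header-only edge list
  fit0 <- scoreGraph(sim$data, dagStructure(3))
  td0 <- withr::local_tempdir()
  writeGraph(fit0, td0)
  expect_equal(length(readLines(file.path(td0, "edges.tsv"))), 1)
})

test_that("experiment runner emits one row per method and repeat, reproducibly", {
  cfg <- simConfig("zi_linear", d = 3, n = 200)
  res <- runExperiment(cfg, methods = c("hc", "tabu"), repeats = 2,
                       seed = 5)
  expect_equal(nrow(res), 4)
  expect_setequal(res$method, c("hc", "tabu"))
  res2 <- runExperiment(cfg, methods = c("hc", "tabu"), repeats = 2,
                        seed = 5)
  expect_identical(res, res2)
  summ <- summariseExperiment(res)
  expect_equal(nrow(summ), 6)
  hcT <- res$TPR[res$method == "hc"]
  expect_equal(summ$mean[summ$method == "hc" & summ$metric == "TPR"],
               mean(hcT))
  expect_equal(summ$se[summ$method == "hc" & summ$metric == "TPR"],
               sd(hcT) / sqrt(2))
})

test_that("command-line interface runs the simulate and fit verbs", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "zigdag.R", package = "zigdag")
  skip_if(cli == "")
  td <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(cli, "simulate", "--scenario", "zi_linear",
                            "--d", "3", "--n", "120", "--seed", "2",
                            "--out", td), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(td, "counts.tsv")))
  expect_true(file.exists(file.path(td, "truth_edges.tsv")))
  status <- system2(rscript, c(cli, "fit", "--input",
                               file.path(td, "counts.tsv"),
                               "--algorithm", "hc", "--out",
                               file.path(td, "fit")),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(td, "fit", "edges.tsv")))
  ev <- system2(rscript, c(cli, "evaluate", "--truth",
                           file.path(td, "truth_edges.tsv"),
                           "--estimate", file.path(td, "fit", "edges.tsv"),
                           "--input", file.path(td, "counts.tsv")),
                stdout = TRUE)
  expect_match(paste(ev, collapse = "\n"), "TPR")
})
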