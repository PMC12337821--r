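#' Run a simulate-learn-evaluate experiment
#'
#' Repeats, for `repeats` independent seeds derived from `seed`, the
#' loop: simulate a dataset from `scenario`, learn the structure with
#' each requested algorithm (from the empty graph unless `g0` is
#' given), and compute the directed-edge recovery metrics against the
#' simulation truth. The per-repeat seed is `seed + repeat`, so
#' results do not depend on execution order.
#'
#' @param config a [simConfig()]; its seed slot is ignored in favour
#'   of the derived per-repeat seeds.
#' @param methods subset of `c("hc", "tabu", "exhaustive")`.
#' @param repeats number of repeats.
#' @param seed base seed.
#' @param mode `"linear"` or `"nonlinear"` fitting mode.
#' @param family fitting family (defaults to the generative family).
#' @param s,t tabu-search parameters.
#' @param g0 optional initial [DAGStructure-class].
#' @param control a [zigControl()].
#' @param verbose print per-repeat progress.
#' @return data.frame with one row per (method, repeat): TPR, FDR,
#'   MCC, BIC and the repeat seed.
#' @seealso [summariseExperiment()] for the mean/SE table.
#' @export
runExperiment <- function(config, methods = c("hc", "tabu"), repeats = 10L,
                          seed = 1L, mode = c("linear", "nonlinear"),
                          family = NULL, s = 10L, t = 10L, g0 = NULL,
                          control = zigControl(), verbose = FALSE) {
  mode <- match.arg(mode)
  methods <- match.arg(methods, c("hc", "tabu", "exhaustive"),
                       several.ok = TRUE)
  if (is.null(family)) family <- config@family
  rows <- list()
  for (r in seq_len(repeats)) {
    cfg <- config
    cfg@seed <- as.integer(seed + r)
    sim <- simulateScenario(cfg)
    cache <- newFitCache() # shared across methods for one dataset
    for (m in methods) {
      fit <- switch(m,
        hc = hillClimb(sim$data, g0 = g0, family = family, mode = mode,
                       control = control, cache = cache),
        tabu = tabuSearch(sim$data, g0 = g0, s = s, t = t, family = family,
                          mode = mode, control = control, cache = cache),
        exhaustive = exhaustiveSearch(sim$data, family = family,
                                      mode = mode, control = control,
                                      cache = cache))
      met <- edgeMetrics(sim$dag, fit)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, repeatIdx = r, seed = cfg@seed, TPR = met[["TPR"]],
        FDR = met[["FDR"]], MCC = met[["MCC"]], BIC = fit@bic)
      if (verbose)
        message(sprintf("repeat %d | %s | TPR %.3f FDR %.3f MCC %.3f",
                        r, m, met[["TPR"]], met[["FDR"]], met[["MCC"]]))
    }
  }
  do.call(rbind, rows)
}

#' Summarise an experiment table
#'
#' Mean and standard error (of the mean) per method and metric,
#' matching the usual benchmark-table convention of a mean with the
#' standard error in parentheses.
#'
#' @param results data.frame from [runExperiment()].
#' @return data.frame with columns method, metric, mean, se, n.
#' @export
summariseExperiment <- function(results) {
  metrics <- c("TPR", "FDR", "MCC")
  out <- list()
  for (m in unique(results$method)) {
    sub <- results[results$method == m, , drop = FALSE]
    for (met in metrics) {
      v <- sub[[met]]
      out[[length(out) + 1L]] <- data.frame(
        method = m, metric = met, mean = mean(v),
        se = stats::sd(v) / sqrt(length(v)), n = length(v))
    }
  }
  do.call(rbind, out)
}
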