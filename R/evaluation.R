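#' Directed-edge confusion counts
#'
#' Compares the estimated and true directed edge sets over all
#' d(d-1) ordered node pairs. A reversed edge contributes one false
#' positive and one false negative.
#'
#' @param trueDag,estDag [DAGStructure-class] objects on the same node
#'   set (a [GraphFit-class] is accepted and its DAG taken).
#' @return named integer vector `c(TP, FP, FN, TN)` with
#'   `TP + FP + FN + TN = d(d-1)`.
#' @export
edgeConfusion <- function(trueDag, estDag) {
  trueDag <- .asDag(trueDag); estDag <- .asDag(estDag)
  if (trueDag@d != estDag@d)
    stop("node sets differ: ", trueDag@d, " vs ", estDag@d, " nodes")
  d <- trueDag@d
  tA <- adjacencyMatrix(trueDag) == 1L
  eA <- adjacencyMatrix(estDag) == 1L
  off <- !diag(d)
  TP <- sum(tA & eA)
  FP <- sum(!tA & eA)
  FN <- sum(tA & !eA)
  TN <- sum(!tA & !eA & off)
  c(TP = TP, FP = FP, FN = FN, TN = TN)
}

.asDag <- function(x) {
  if (methods::is(x, "GraphFit")) x@dag
  else if (methods::is(x, "DAGStructure")) x
  else stop("expected a DAGStructure or GraphFit")
}

#' Directed-edge recovery metrics
#'
#' * TPR = TP / (TP + FN), the fraction of true edges recovered with
#'   the right orientation;
#' * FDR = FP / (TP + FP), the fraction of reported edges that are
#'   wrong (0 when nothing is reported);
#' * MCC, the Matthews correlation coefficient
#'   \eqn{(TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#'   over the d(d-1) ordered pairs, in \[-1, 1\] with 1 = perfect
#'   agreement, 0 = random guess (returned when a denominator factor
#'   is 0), -1 = total disagreement.
#'
#' @inheritParams edgeConfusion
#' @return named numeric vector `c(TPR, FDR, MCC)`.
#' @examples
#' truth <- dagStructure(2, rbind(c(1, 2)))
#' edgeMetrics(truth, dagStructure(2, rbind(c(2, 1)))) # reversed: MCC -1
#' @export
edgeMetrics <- function(trueDag, estDag) {
  cm <- as.numeric(edgeConfusion(trueDag, estDag)) # avoid int overflow in MCC
  names(cm) <- c("TP", "FP", "FN", "TN")
  TP <- cm[["TP"]]; FP <- cm[["FP"]]; FN <- cm[["FN"]]; TN <- cm[["TN"]]
  tpr <- if (TP + FN > 0) TP / (TP + FN) else 0
  fdr <- if (TP + FP > 0) FP / (TP + FP) else 0
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom > 0) (TP * TN - FP * FN) / sqrt(denom) else 0
  c(TPR = tpr, FDR = fdr, MCC = mcc)
}

#' Direction accuracy over repeated two-node experiments
#'
#' For the hidden-confounder designs: in scenario `"a"` (a true causal
#' edge X2 -> X1) a repeat counts as correct when the estimated graph
#' is exactly \{X2 -> X1\}; in scenario `"b"` (no causal edge) when
#' the estimate has no edge between X1 and X2.
#'
#' @param estimates list of estimated 2-node [DAGStructure-class] (or
#'   [GraphFit-class]) objects, one per repeat.
#' @param scenario `"a"` or `"b"` (the suffix of the confounder
#'   scenario tag is also accepted).
#' @return numeric(1), the fraction of correct repeats.
#' @export
directionAccuracy <- function(estimates, scenario = c("a", "b")) {
  scenario <- sub("^confounder_", "", scenario)
  scenario <- match.arg(scenario, c("a", "b"))
  ok <- vapply(estimates, function(est) {
    E <- .asDag(est)@edges
    if (scenario == "a")
      nrow(E) == 1L && E[1L, 1L] == 2L && E[1L, 2L] == 1L
    else
      nrow(E) == 0L
  }, logical(1))
  mean(ok)
}
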