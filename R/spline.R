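#' Cubic B-spline basis evaluation
#'
#' Evaluates a cubic B-spline basis at `x`. Boundary knots default to
#' `range(x)` and the interior knots to the empirical median (the 50%
#' quantile), so the default full basis has 5 functions. Two basis
#' counts are supported for a given set of interior knots `kI`:
#'
#' * `M = length(kI) + 4`: the full B-spline basis (partition of unity
#'   - rows sum to 1 inside the boundary);
#' * `M = length(kI) + 3`: the full basis with its first function
#'   dropped, appropriate when the model already carries an intercept.
#'
#' @param x numeric vector of evaluation points (for model building, a
#'   parent's observed counts).
#' @param M number of basis functions (>= 4 for a cubic basis).
#' @param knots interior knot locations; default the median of `x`.
#' @param boundary boundary knots; default `range(x)`.
#' @return an `n x M` matrix with attributes `knots` and `boundary`.
#' @examples
#' B <- splineBasis(0:10, M = 5, knots = 5)
#' rowSums(B)  # all 1
#' @export
splineBasis <- function(x, M = 4L, knots = NULL, boundary = NULL) {
  if (length(unique(x)) < 2L)
    stop("degenerate input: x has a single unique value")
  if (M < 4L) stop("M must be >= 4 for a cubic basis")
  if (is.null(boundary)) boundary <- range(x)
  if (is.null(knots)) {
    # intercept-adjusted convention: M functions need M - 3 interior
    # knots, placed at equally spaced quantiles (M = 4 -> the median)
    knots <- stats::quantile(x, probs = seq_len(M - 3L) / (M - 2L),
                             names = FALSE)
  }
  knots <- as.numeric(knots)
  full <- length(knots) + 4L
  if (!M %in% c(full, full - 1L))
    stop("M = ", M, " incompatible with ", length(knots),
         " interior knot(s): expected ", full, " (full basis) or ",
         full - 1L, " (intercept-adjusted)")
  kv <- sort(c(rep(boundary[1L], 4L), knots, rep(boundary[2L], 4L)))
  xc <- pmin(pmax(x, boundary[1L]), boundary[2L])
  B <- splines::splineDesign(kv, xc, ord = 4L)
  if (M == full - 1L) B <- B[, -1L, drop = FALSE]
  structure(B, knots = knots, boundary = boundary)
}
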