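#' B-spline basis with a difference penalty (P-spline block)
#'
#' Constructs a cubic (by default) B-spline basis on equally spaced knots
#' spanning the observed range of `x`, together with the `penalty_order`-th
#' order difference penalty \eqn{D^T D} of Eilers & Marx P-splines. The block
#' is reparameterised with a sum-to-zero constraint (the constant direction is
#' absorbed by the model intercept), which keeps an additive model with
#' several smooths identifiable. Evaluation is exact inside the training
#' range and extrapolates linearly beyond it.
#'
#' @param x numeric vector of covariate values (at least 2 distinct values).
#' @param n_basis number of B-spline basis functions before constraint
#'   (default 10).
#' @param degree spline degree (default 3, cubic).
#' @param penalty_order order of the difference penalty (default 2, so the
#'   penalty null space contains straight lines).
#' @return an object of class `spline_block` with elements `knots`, `degree`,
#'   `Z` (constraint reparameterisation, `n_basis` x `n_basis - 1`), `X`
#'   (constrained basis evaluated at `x`), `S` (constrained penalty matrix),
#'   `rank` (penalty rank) and `xrange`.
#' @examples
#' blk <- build_spline_basis(runif(50), n_basis = 8)
#' dim(blk$X)
#' @export
build_spline_basis <- function(x, n_basis = 10L, degree = 3L,
                               penalty_order = 2L) {
  if (any(!is.finite(x))) stop("non-finite values in covariate", call. = FALSE)
  if (n_basis < degree + 1L) stop("n_basis must be >= degree + 1", call. = FALSE)
  r <- range(x)
  if (diff(r) <= 0)
    stop("degenerate covariate: all values identical", call. = FALSE)
  n_inner <- n_basis - degree - 1L
  dx <- diff(r) / (n_inner + 1L)
  knots <- seq(r[1] - degree * dx, r[2] + degree * dx,
               length.out = n_basis + degree + 1L)
  eps <- 1e-9 * max(1, diff(r))   # keep evaluations strictly inside knots
  B <- splines::splineDesign(knots, pmin(pmax(x, r[1] + eps), r[2] - eps),
                             ord = degree + 1L)
  D <- diff(diag(n_basis), differences = penalty_order)
  # sum-to-zero constraint: colSums(B) %*% beta = 0, absorbed via QR null space
  C <- matrix(colSums(B), 1L)
  Z <- qr.Q(qr(t(C)), complete = TRUE)[, -1, drop = FALSE]
  DZ <- D %*% Z
  S <- crossprod(DZ)
  structure(
    list(knots = knots, degree = as.integer(degree), Z = Z, X = B %*% Z,
         S = S, rank = qr(DZ)$rank, penalty_order = as.integer(penalty_order),
         n_basis = as.integer(n_basis), xrange = r),
    class = "spline_block")
}

#' Evaluate a spline block at new covariate values
#'
#' In-range points are evaluated exactly; points beyond the training range are
#' continued linearly from the boundary (value plus first derivative).
#'
#' @param blk a `spline_block`.
#' @param x numeric vector.
#' @return matrix with one row per element of `x`.
#' @export
eval_spline_basis <- function(blk, x) {
  if (any(!is.finite(x))) stop("non-finite values in covariate", call. = FALSE)
  eps <- 1e-9 * max(1, diff(blk$xrange))   # guard the exact boundary
  lo <- blk$xrange[1] + eps; hi <- blk$xrange[2] - eps
  xi <- pmin(pmax(x, lo), hi)
  ord <- blk$degree + 1L
  B <- splines::splineDesign(blk$knots, xi, ord = ord)
  out <- which(x < blk$xrange[1] | x > blk$xrange[2])
  if (length(out)) {
    Bd <- splines::splineDesign(blk$knots, xi[out], ord = ord, derivs = 1L)
    B[out, ] <- B[out, ] + (x[out] - xi[out]) * Bd
  }
  B %*% blk$Z
}
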