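# Spline bases and roughness penalties for the penalized-spline logistic
# additive models.  Cubic B-spline bases carry a second-order difference
# penalty on their coefficients (P-splines); the spatial term is a tensor
# product of two marginal cubic B-spline bases with one difference penalty
# (and one smoothing parameter) per direction.

#' Cubic B-spline basis definition with difference penalty
#'
#' Builds a `k`-dimensional cubic B-spline basis on the range of `x` with
#' quantile-based interior knots.  For knot placement, values above the
#' 99.5th percentile are capped (road distances have a long right tail);
#' evaluation outside the training range clamps to the boundary.
#' The roughness penalty is `t(D) %*% D` with `D` the second-order difference
#' operator on the spline coefficients, so straight-line coefficient vectors
#' are unpenalized.
#'
#' @param x numeric covariate vector (at least `k` distinct values).
#' @param k basis dimension, `k >= 4`.
#' @param degree spline degree (3 = cubic).
#' @param cap_quantile quantile at which values are capped for knot placement.
#' @return object of class `bspline_basis`: knot vector, range, `k`,
#'   Greville abscissae `greville`, and penalty matrix `S` (`k x k`,
#'   positive semidefinite).
#' @details The penalty uses second-order *divided* differences on the
#'   Greville abscissae of the basis, so its null space is exactly the
#'   coefficient vectors representing affine functions of `x` (for uniform
#'   knots this reduces to the plain second-difference penalty).  As the
#'   smoothing parameter grows the smooth therefore degenerates to a straight
#'   line, and a model whose parametric part contains the corresponding
#'   linear terms collapses to that parametric model.
#' @export
bspline_basis <- function(x, k = 10, degree = 3, cap_quantile = 0.995) {
  if (k < 4) stop_fmt("basis dimension k must be >= 4, got %d", k)
  ux <- unique(x[is.finite(x)])
  if (length(ux) < k)
    stop_fmt("need at least k = %d distinct covariate values, got %d", k, length(ux))
  xc <- pmin(x, stats::quantile(x, cap_quantile, names = FALSE))
  xl <- min(xc); xu <- max(xc)
  n_int <- k - degree - 1L
  interior <- if (n_int > 0)
    stats::quantile(xc, probs = seq_len(n_int) / (n_int + 1), names = FALSE)
  else numeric(0)
  # strictly increasing interior knots; fall back to an even grid under ties
  if (anyDuplicated(signif(c(xl, interior, xu), 12)))
    interior <- seq(xl, xu, length.out = n_int + 2)[-c(1, n_int + 2)]
  knots <- c(rep(xl, degree + 1), interior, rep(xu, degree + 1))
  g <- vapply(seq_len(k), function(i) mean(knots[(i + 1):(i + degree)]), 0)
  w1 <- diff(g)
  D1 <- diag(1 / w1, nrow = k - 1) %*% diff(diag(k))
  w2 <- (g[3:k] - g[1:(k - 2)]) / 2
  D2 <- diag(1 / w2, nrow = k - 2) %*% diff(diag(k - 1)) %*% D1
  D2 <- D2 * mean(w1)^2  # non-dimensionalize so lambda scales comparably
  structure(list(k = k, degree = degree, knots = knots, xl = xl, xu = xu,
                 greville = g, S = crossprod(D2)),
            class = "bspline_basis")
}

#' Evaluate a B-spline basis
#'
#' @param def a [bspline_basis()].
#' @param x evaluation points; values outside the knot range are evaluated by
#'   linear extrapolation of the basis functions (so affine functions are
#'   reproduced exactly on the whole line, and the penalized limit of a
#'   smooth remains a straight line everywhere).
#' @return `length(x) x k` basis matrix (rows sum to 1: partition of unity).
#' @export
eval_basis <- function(def, x) {
  ord <- def$degree + 1
  xx <- pmin(pmax(x, def$xl), def$xu)
  B <- splines::splineDesign(def$knots, xx, ord = ord)
  out <- x < def$xl | x > def$xu
  if (any(out)) {
    idx <- which(out)
    bnd <- ifelse(x[idx] < def$xl, def$xl, def$xu)
    B0 <- splines::splineDesign(def$knots, bnd, ord = ord)
    B1 <- splines::splineDesign(def$knots, bnd, ord = ord, derivs = rep(1L, length(bnd)))
    B[idx, ] <- B0 + (x[idx] - bnd) * B1
  }
  B
}

#' Tensor-product B-spline basis for a spatial smooth
#'
#' Row-wise Kronecker product of two marginal cubic B-spline bases of
#' dimension `k_marginal`, giving `k_marginal^2` columns, with two
#' Kronecker-structured difference penalties (one per direction, each with
#' its own smoothing parameter).
#'
#' @param x,y paired coordinate vectors.
#' @param k_marginal marginal basis dimension (`>= 4`).
#' @return list with basis matrix `B`, marginal definitions `def_x`, `def_y`,
#'   and penalties `S_x`, `S_y` (`k^2 x k^2`).
#' @export
tensor_basis <- function(x, y, k_marginal = 6) {
  def_x <- bspline_basis(x, k_marginal, cap_quantile = 1)
  def_y <- bspline_basis(y, k_marginal, cap_quantile = 1)
  B <- row_kronecker(eval_basis(def_x, x), eval_basis(def_y, y))
  k <- k_marginal
  list(B = B, def_x = def_x, def_y = def_y,
       S_x = kronecker(def_x$S, diag(k)),
       S_y = kronecker(diag(k), def_y$S))
}

# rows: out[i, ] = A[i, ] %x% B[i, ]  (column index (ia-1)*ncol(B) + ib)
row_kronecker <- function(A, B) {
  ka <- ncol(A); kb <- ncol(B)
  A[, rep(seq_len(ka), each = kb), drop = FALSE] *
    B[, rep(seq_len(kb), times = ka), drop = FALSE]
}

#' Absorb the sum-to-zero constraint into a smooth basis
#'
#' Reparameterizes a smooth block so each retained column sums to zero over
#' the sample, making the smooth identifiable alongside an intercept.  The
#' dimension drops by exactly one; penalties are transformed consistently.
#'
#' @param B basis matrix attached to the data.
#' @param S_list list of penalty matrices on the original coefficients.
#' @return list with centered basis `X`, transformed penalties `S`, and the
#'   `k x (k-1)` null-space transform `Z` (needed for prediction).
#' @export
apply_constraints <- function(B, S_list) {
  C <- matrix(colSums(B), ncol = 1)
  qrC <- qr(C)
  Z <- qr.Q(qrC, complete = TRUE)[, -1, drop = FALSE]
  list(X = B %*% Z,
       S = lapply(S_list, function(S) crossprod(Z, S %*% Z)),
       Z = Z)
}
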