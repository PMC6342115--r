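#' Second-order random-walk (RW2) precision matrix
#'
#' Bayesian smoothing-spline prior over an ordered sequence of `m` effect
#' values: independent Gaussian increments on the second differences give
#' the penalty `Q = D'D` with `D` the (m-2) x m second-difference matrix.
#' `Q` has rank `m - 2`; its null space is spanned by the constant and the
#' linear vector. The matrix is rescaled so that the geometric mean of the
#' marginal variances of the proper part (the generalized variance) equals
#' 1, which makes the precision parameter `rho_d` comparable across
#' covariates with different numbers of knots.
#'
#' @param m Number of knots (>= 3).
#' @return Sparse symmetric `Matrix` of dimension `m`, with attribute
#'   `"scale"` holding the applied scaling factor.
#' @export
build_rw2_precision <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 3L) stop("an RW2 smooth needs at least 3 knots")
  D <- Matrix::bandSparse(m - 2L, m, k = 0:2,
                          diagonals = list(rep(1, m - 2),
                                           rep(-2, m - 2),
                                           rep(1, m - 2)))
  Q <- Matrix::crossprod(D)
  # generalized-variance-1 scaling: geometric mean of the marginal
  # variances of the rank-(m-2) proper part
  e <- eigen(as.matrix(Q), symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  V <- e$vectors[, pos, drop = FALSE]
  Sig <- V %*% (t(V) / e$values[pos])
  scale <- exp(mean(log(diag(Sig))))
  Q <- Q * scale
  Q <- methods::as(Matrix::forceSymmetric(Q), "CsparseMatrix")
  attr(Q, "scale") <- scale
  Q
}
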