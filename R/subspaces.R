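#' Function subspaces in L2(mu)
#'
#' A subspace of functions represented either by node values on an oracle
#' grid (`type = "grid"`, with stationary weights `mu` defining the inner
#' product) or by coefficient vectors in a fixed basis (`type = "coords"`,
#' with the basis Gram matrix as metric).  Distances can only be taken
#' between subspaces sharing a representation space.
#'
#' @param x columns spanning the subspace: node values (`N x k`) or basis
#'   coefficients (`n x k`).
#' @param metric for `"grid"`, the length-`N` vector of positive weights
#'   `mu`; for `"coords"`, the `n x n` Gram (metric) matrix.
#' @param type `"grid"` or `"coords"`.
#' @return an object of class `"function_subspace"` with dimension
#'   `k = ncol(x)`.
#' @export
function_subspace <- function(x, metric, type = c("grid", "coords")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (type == "grid") {
    metric <- as.numeric(metric)
    stopifnot(length(metric) == nrow(x), all(metric > 0))
  } else {
    metric <- as.matrix(metric)
    stopifnot(nrow(metric) == nrow(x), ncol(metric) == nrow(x))
  }
  structure(list(basis = x, metric = metric, type = type, k = ncol(x)),
            class = "function_subspace")
}

.sub_gram <- function(sub) {
  if (sub$type == "grid") crossprod(sub$basis, sub$metric * sub$basis)
  else crossprod(sub$basis, sub$metric %*% sub$basis)
}

.check_compatible <- function(U, W) {
  if (U$type != W$type)
    stop("incompatible subspace representations (grid vs coords)")
  if (nrow(U$basis) != nrow(W$basis))
    stop("subspaces live in spaces of different size")
}

#' Orthonormalize a function subspace
#'
#' Returns a representation whose columns are orthonormal under the
#' subspace's inner product.  Rank-deficient input (smallest Gram
#' eigenvalue below `tol` times the largest) is an error rather than a
#' silent dimension reduction.
#'
#' @param sub a `"function_subspace"`.
#' @param tol relative rank tolerance.
#' @return an orthonormal `"function_subspace"` spanning the same space.
#' @export
orthonormalize <- function(sub, tol = 1e-10) {
  stopifnot(inherits(sub, "function_subspace"))
  G <- .sub_gram(sub)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  if (min(e$values) < tol * max(e$values))
    stop("rank-deficient subspace representation (Gram condition beyond tolerance)")
  R <- e$vectors %*% diag(1 / sqrt(e$values), sub$k)
  function_subspace(sub$basis %*% R, sub$metric, sub$type)
}

# cross inner-product matrix between orthonormalized representations
.cross_cosines <- function(U, W) {
  .check_compatible(U, W)
  A <- orthonormalize(U); B <- orthonormalize(W)
  if (U$type == "grid") crossprod(A$basis, U$metric * B$basis)
  else crossprod(A$basis, U$metric %*% B$basis)
}

#' Projection (Frobenius) distance between subspaces
#'
#' \eqn{d_F(U, W) = \|P_{W^\perp} P_U\|_F}, the root sum of squared
#' principal-angle sines.  When `dim(U) > dim(W)` the value is at least
#' `sqrt(dim(U) - dim(W))` and is interpreted as the distance from `U` to
#' the nearest `dim(U)`-dimensional subspace containing `W`; the result
#' then carries attribute `excess_dim`.
#'
#' @param U,W `"function_subspace"` objects in the same representation
#'   space.
#' @return a value in `[0, sqrt(dim(U))]`.
#' @export
projection_distance <- function(U, W) {
  S <- .cross_cosines(U, W)
  d <- sqrt(max(U$k - sum(S^2), 0))
  if (U$k > W$k) attr(d, "excess_dim") <- U$k - W$k
  d
}

#' Gap (spectral) distance between subspaces
#'
#' \eqn{d_2(U, W) = \|P_{W^\perp} P_U\|_2}, the largest principal-angle
#' sine; always bounded by 1 and by `projection_distance(U, W)`.
#'
#' @inheritParams projection_distance
#' @return a value in `[0, 1]`.
#' @export
gap_distance <- function(U, W) {
  S <- .cross_cosines(U, W)
  if (U$k > W$k) {
    d <- 1
    attr(d, "excess_dim") <- U$k - W$k
    return(d)
  }
  sv <- svd(S, nu = 0, nv = 0)$d
  smin <- min(sv[seq_len(U$k)])
  sqrt(max(1 - min(smin, 1)^2, 0))
}

#' Total / approximation / estimation error decomposition
#'
#' For an estimated subspace (from data), the corresponding idealized
#' subspace (exact correlation matrices) and the true invariant subspace:
#' total error `d_F(est, truth)`, approximation error
#' `d_F(ideal, truth)` (basis limitation), estimation error
#' `d_F(est, ideal)` (finite-data limitation).  The triangle inequality
#' `total <= approximation + estimation` holds.
#'
#' @param est,ideal,truth `"function_subspace"` objects in a common
#'   representation space.
#' @return a list with components `total`, `approximation`, `estimation`.
#' @export
error_decomposition <- function(est, ideal, truth) {
  list(total = as.numeric(projection_distance(est, truth)),
       approximation = as.numeric(projection_distance(ideal, truth)),
       estimation = as.numeric(projection_distance(est, ideal)))
}
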