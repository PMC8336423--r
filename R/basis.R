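#' Indicator basis on a partition of one coordinate axis
#'
#' The Markov-state-model basis: `n = length(edges) - 1` indicator
#' functions on the half-open cells `[e_i, e_{i+1})` of the named axis,
#' with the rightmost cell closed.  Points outside `[e_1, e_{n+1}]`
#' evaluate to an all-zero row (rare excursions are counted, not fatal).
#'
#' @param edges strictly increasing cell edges (>= 2 values); the outer
#'   edges may be `-Inf` / `Inf` for unbounded outer cells (an
#'   equal-mass partition of the stationary law is the common choice).
#' @param dim state dimension the basis applies to.
#' @param axis which coordinate the partition lives on.
#' @return an object of class `"basis_set"`.
#' @export
indicator_basis <- function(edges, dim = 1, axis = 1) {
  edges <- as.numeric(edges)
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stop("edges must be at least 2 strictly increasing values")
  stopifnot(axis >= 1, axis <= dim)
  structure(list(kind = "indicator", n = length(edges) - 1L, edges = edges,
                 axis = as.integer(axis), dim = as.integer(dim),
                 mean_removed = FALSE, means = NULL),
            class = "basis_set")
}

#' Monomial feature basis
#'
#' Functions \eqn{x \mapsto \prod_d x_d^{e_d}} for a set of exponent
#' tuples, e.g. the quadratic set `{1, x1, x2, x1^2, x1 x2, x2^2}`.
#'
#' @param exponents a matrix with one tuple of nonnegative integer
#'   exponents per row (or a list of such tuples).
#' @return an object of class `"basis_set"`.
#' @export
monomial_basis <- function(exponents) {
  if (is.list(exponents)) exponents <- do.call(rbind, exponents)
  exponents <- as.matrix(exponents)
  if (any(exponents < 0) || any(exponents != round(exponents)))
    stop("exponents must be nonnegative integers")
  if (anyDuplicated(apply(exponents, 1, paste, collapse = ",")))
    stop("duplicate exponent tuples")
  structure(list(kind = "monomial", n = nrow(exponents),
                 exponents = exponents, dim = ncol(exponents),
                 mean_removed = FALSE, means = NULL),
            class = "basis_set")
}

#' The quadratic monomial basis in two dimensions
#'
#' `{1, x1, x2, x1^2, x1 x2, x2^2}` (n = 6).
#' @return a `"basis_set"`.
#' @export
quadratic_basis_2d <- function() {
  monomial_basis(rbind(c(0, 0), c(1, 0), c(0, 1),
                       c(2, 0), c(1, 1), c(0, 2)))
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("Basis set: %d %s functions (dim %d)%s\n", x$n, x$kind, x$dim,
              if (x$mean_removed) ", mean-removed" else ""))
  invisible(x)
}

#' Evaluate a basis set at points
#'
#' Returns the `frames x n` matrix of \eqn{\phi_j(x_i)}.  For indicator
#' bases a sparse one-hot matrix can be requested.  If the basis is
#' mean-removed (see [set_basis_means()]), the stored means are
#' subtracted (dense output only).
#'
#' @param basis a `"basis_set"`.
#' @param points `frames x dim` matrix (a vector is taken as a single
#'   coordinate column when `dim == 1`).
#' @param sparse return a sparse `Matrix` (indicator bases only, no mean
#'   removal applied to the sparse path unless means are set, in which
#'   case evaluation is dense).
#' @return a `frames x n` matrix; for indicator bases the attribute
#'   `"n_out_of_range"` counts points falling outside the partition.
#' @export
evaluate_basis <- function(basis, points, sparse = FALSE) {
  stopifnot(inherits(basis, "basis_set"))
  if (is.null(dim(points))) points <- matrix(points, ncol = basis$dim)
  points <- as.matrix(points)
  if (ncol(points) != basis$dim)
    stop("dimension mismatch: points have ", ncol(points),
         " columns, basis expects ", basis$dim)
  if (!all(is.finite(points))) stop("points must be finite")
  nfr <- nrow(points)
  if (basis$kind == "indicator") {
    cell <- findInterval(points[, basis$axis], basis$edges,
                         rightmost.closed = TRUE)
    inside <- cell >= 1 & cell <= basis$n
    n_out <- sum(!inside)
    if (sparse && !basis$mean_removed) {
      out <- sparseMatrix(i = which(inside), j = cell[inside], x = 1,
                          dims = c(nfr, basis$n))
    } else {
      out <- matrix(0, nfr, basis$n)
      out[cbind(which(inside), cell[inside])] <- 1
      if (basis$mean_removed)
        out <- sweep(out, 2, basis$means)
    }
    attr(out, "n_out_of_range") <- n_out
    return(out)
  }
  out <- vapply(seq_len(basis$n), function(j) {
    e <- basis$exponents[j, ]
    v <- rep(1, nfr)
    for (d in which(e > 0)) v <- v * points[, d]^e[d]
    v
  }, numeric(nfr))
  if (nfr == 1) out <- matrix(out, 1, basis$n)
  if (basis$mean_removed) out <- sweep(out, 2, basis$means)
  out
}

#' Remove the empirical mean from a basis
#'
#' Estimates the stationary mean of every basis function from a fitting
#' trajectory and stores it, so that subsequent evaluations are centered.
#' With mean removal the constant function becomes identically zero and
#' is dropped by the rank filter in [solve_vac()]; the trivial unit
#' eigenvalue is then intentionally absent and subspace indices shift
#' down by one.
#'
#' @param basis a `"basis_set"`.
#' @param traj a `"trajectory"` or list of trajectories used to estimate
#'   the means.
#' @return the basis with `mean_removed = TRUE` and `means` set.
#' @export
set_basis_means <- function(basis, traj) {
  stopifnot(inherits(basis, "basis_set"))
  trajs <- if (inherits(traj, "trajectory")) list(traj) else traj
  s <- numeric(basis$n); nfr <- 0
  raw <- basis; raw$mean_removed <- FALSE; raw$means <- NULL
  for (tr in trajs) {
    ev <- evaluate_basis(raw, tr$states)
    s <- s + colSums(ev); nfr <- nfr + nrow(ev)
  }
  basis$means <- s / nfr
  basis$mean_removed <- TRUE
  basis
}
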