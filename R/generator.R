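#' Tensor-product grid domain
#'
#' Regular grid used to discretize a diffusion generator.  Node
#' coordinates are per axis; quadrature is trapezoidal, so cell weights
#' sum to the domain volume.  Points are ordered with the first axis
#' fastest.
#'
#' @param lower,upper numeric vectors of per-axis bounds.
#' @param n integer vector of per-axis node counts (>= 3).
#' @return an object of class `"grid_domain"` with fields `axes` (node
#'   coordinates), `spacing`, `points` (`N x dim` matrix) and
#'   `cell_weights` (length `N`).
#' @export
grid_domain <- function(lower, upper, n) {
  stopifnot(length(lower) == length(upper), length(n) == length(lower),
            all(upper > lower), all(n >= 3))
  dim <- length(lower)
  axes <- lapply(seq_len(dim), function(d) seq(lower[d], upper[d], length.out = n[d]))
  spacing <- vapply(axes, function(a) a[2] - a[1], 0)
  aw <- lapply(seq_len(dim), function(d) {
    w <- rep(spacing[d], n[d]); w[c(1, n[d])] <- spacing[d] / 2; w
  })
  grids <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)  # first axis fastest
  points <- as.matrix(grids)
  dimnames(points) <- NULL
  cw <- Reduce(function(acc, d) acc * aw[[d]][match(points[, d], axes[[d]])],
               seq_len(dim), init = rep(1, nrow(points)))
  structure(list(axes = axes, spacing = spacing, n = as.integer(n),
                 dim = dim, points = points, cell_weights = cw),
            class = "grid_domain")
}

default_grid_domain <- function(model) {
  switch(model$name,
    ou1d = grid_domain(-7.5, 7.5, 751),
    doublewell2d = grid_domain(c(-2, -7.5), c(2, 7.5), c(161, 151)),
    stop("no default grid domain for model '", model$name,
         "'; supply a grid_domain")
  )
}

# forward-difference operator along axis `d` of a tensor grid, with the
# e^{-U} face weights and transverse cell widths needed by the Dirichlet
# form; returns list(D = operator on edges, w = edge weights)
.axis_form <- function(d, n, axes, spacing, U0, aw) {
  nd <- n[d]
  dd <- bandSparse(nd - 1, nd, k = c(0, 1),
                   diag = list(rep(-1, nd - 1), rep(1, nd - 1)))
  D <- if (length(n) == 1) dd
       else if (d == 1) kronecker(Diagonal(n[2]), dd)
       else kronecker(dd, Diagonal(n[1]))
  if (length(n) == 1) {
    Ue <- (U0[-1] + U0[-nd]) / 2
    w <- exp(-Ue)
  } else if (d == 1) {
    Um <- matrix(U0, n[1], n[2])
    Ue <- (Um[-1, , drop = FALSE] + Um[-n[1], , drop = FALSE]) / 2
    w <- exp(-as.numeric(Ue)) * rep(aw[[2]], each = n[1] - 1)
  } else {
    Um <- matrix(U0, n[1], n[2])
    Ue <- (Um[, -1, drop = FALSE] + Um[, -n[2], drop = FALSE]) / 2
    w <- exp(-as.numeric(Ue)) * rep(aw[[1]], times = n[2] - 1)
  }
  list(D = D, w = w)
}

# centered-difference operator (one-sided at the boundary) along axis d
.centered_diff <- function(d, n, spacing) {
  nd <- n[d]; h <- spacing[d]
  g <- bandSparse(nd, nd, k = c(-1, 1),
                  diag = list(rep(-1 / (2 * h), nd - 1), rep(1 / (2 * h), nd - 1)))
  g[1, 1:2] <- c(-1, 1) / h
  g[nd, (nd - 1):nd] <- c(-1, 1) / h
  if (length(n) == 1) g
  else if (d == 1) kronecker(Diagonal(n[2]), g)
  else kronecker(g, Diagonal(n[1]))
}

#' Discretize the generator of a reversible diffusion on a grid
#'
#' Builds a finite-difference discretization of the generator
#' \deqn{A f = \tfrac12 e^{U} \nabla\cdot\big(a\, e^{-U} \nabla f\big),
#'   \qquad a = \sigma\sigma^T,}
#' in divergence form with zero-flux (reflecting) boundaries.  The matrix
#' is assembled from the Dirichlet (energy) form, so detailed balance
#' holds exactly by construction: with `M = diag(mu)`, `M L` is symmetric,
#' `L 1 = 0`, and `mu` is the exact stationary vector.  Direct
#' second-derivative terms use face-weighted forward differences; the
#' mixed term `a[1,2]` uses node-weighted centered differences (second
#' order in the interior).
#'
#' @param model an `"sde_model"` of dimension 1 or 2 with constant
#'   diffusion matrix.
#' @param domain a [grid_domain()]; defaults to a model-specific domain on
#'   which the stationary density has negligible boundary mass.
#' @param boundary_tol maximum allowed relative stationary density
#'   `exp(-(U - min U))` at boundary nodes; exceeding it is an error
#'   (widen the domain).
#' @return an object of class `"discrete_generator"` with the assembled
#'   energy form `K` (sparse, `L = -diag(1/m) K`), unnormalized node
#'   masses `m`, stationary weights `mu`, grid `points`, and the potential
#'   values `U` (shifted so min U = 0).
#' @export
discretize_generator <- function(model, domain = NULL, boundary_tol = 1e-12) {
  stopifnot(inherits(model, "sde_model"))
  if (model$dim > 2) stop("grid oracle supports dimensions 1 and 2 only")
  if (is.null(domain)) domain <- default_grid_domain(model)
  stopifnot(inherits(domain, "grid_domain"), domain$dim == model$dim)
  pts <- domain$points
  U0 <- model$potential(pts)
  U0 <- U0 - min(U0)
  n <- domain$n
  on_boundary <- Reduce(`|`, lapply(seq_len(domain$dim), function(d)
    pts[, d] == domain$axes[[d]][1] | pts[, d] == domain$axes[[d]][n[d]]))
  bmass <- max(exp(-U0[on_boundary]))
  if (bmass > boundary_tol)
    stop(sprintf("boundary-mass error: exp(-U) reaches %.2e at the domain edge (tolerance %.0e); widen the domain",
                 bmass, boundary_tol))
  a <- model$a
  aw <- lapply(seq_len(domain$dim), function(d) {
    w <- rep(domain$spacing[d], n[d]); w[c(1, n[d])] <- domain$spacing[d] / 2; w
  })
  K <- NULL
  for (d in seq_len(domain$dim)) {
    f <- .axis_form(d, n, domain$axes, domain$spacing, U0, aw)
    Kd <- (a[d, d] / (2 * domain$spacing[d])) *
      Matrix::crossprod(f$D, Diagonal(length(f$w), f$w) %*% f$D)
    K <- if (is.null(K)) Kd else K + Kd
  }
  if (domain$dim == 2 && a[1, 2] != 0) {
    G1 <- .centered_diff(1, n, domain$spacing)
    G2 <- .centered_diff(2, n, domain$spacing)
    Wn <- Diagonal(nrow(pts), exp(-U0) * domain$cell_weights)
    K <- K + (a[1, 2] / 2) *
      (Matrix::crossprod(G1, Wn %*% G2) + Matrix::crossprod(G2, Wn %*% G1))
  }
  m <- exp(-U0) * domain$cell_weights
  structure(list(K = K, m = m, mu = m / sum(m), points = pts,
                 domain = domain, model_name = model$name, U = U0),
            class = "discrete_generator")
}

#' Apply the discretized generator to grid functions
#'
#' @param gen a `"discrete_generator"`.
#' @param f vector or matrix of node values.
#' @return `L f` as a base matrix/vector.
#' @export
apply_generator <- function(gen, f) {
  out <- -as.matrix(gen$K %*% f) / gen$m
  if (is.null(dim(f))) drop(out) else out
}

#' Reference spectrum of a discretized generator
#'
#' Computes the `r` smallest rates `sigma_1 <= ... <= sigma_r` (with
#' `sigma_1 = 0`) and mu-orthonormal eigenfunctions `eta_i` of the
#' discrete generator, via the symmetric similarity transform
#' `S = M^{1/2} L M^{-1/2}`.  Small grids are solved densely (giving the
#' complete grid spectrum if `r` equals the node count); large grids use
#' shift-invert Lanczos (sparse Cholesky + ARPACK).
#'
#' @param gen a `"discrete_generator"`.
#' @param r number of eigenpairs.
#' @param method `"auto"`, `"dense"` or `"arpack"`.
#' @param shift positive spectral shift for the shift-invert transform.
#' @return an object of class `"spectral_reference"` with fields `sigma`
#'   (rates, 1/time), `eta` (`N x r`, mu-orthonormal), `mu`, `points`,
#'   `r`, `model_name`.
#' @export
reference_spectrum <- function(gen, r, method = c("auto", "dense", "arpack"),
                               shift = 1) {
  stopifnot(inherits(gen, "discrete_generator"))
  method <- match.arg(method)
  N <- length(gen$m)
  stopifnot(r >= 1, r <= N)
  if (method == "auto") method <- if (N <= 3000) "dense" else "arpack"
  sm <- sqrt(gen$m)
  if (method == "dense") {
    S <- -as.matrix(gen$K) / outer(sm, sm)
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    sig <- -e$values            # ascending rates
    ord <- order(sig)[seq_len(r)]
    sig <- sig[ord]
    vec <- e$vectors[, ord, drop = FALSE]
  } else {
    Dm <- Diagonal(N, 1 / sm)
    S <- -(Dm %*% gen$K %*% Dm)
    P <- Matrix::forceSymmetric(Diagonal(N, shift) - S)
    ch <- Cholesky(P)
    fn <- function(v, extra) as.numeric(Matrix::solve(ch, v))
    res <- arpack(fn, sym = TRUE,
                  options = list(n = N, nev = r, ncv = min(N, max(2 * r + 20, 40)),
                                 which = "LM", maxiter = 10000))
    if (r == 1) res$vectors <- matrix(res$vectors, ncol = 1)
    sig <- 1 / res$values - shift
    ord <- order(sig)
    sig <- sig[ord]
    vec <- res$vectors[, ord, drop = FALSE]
  }
  if (abs(sig[1]) < 1e-6) sig[1] <- max(sig[1], 0)
  eta <- (vec / sm) * sqrt(sum(gen$m))   # mu-orthonormal
  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(ncol(eta))) {
    i <- which.max(abs(eta[, j]))
    if (eta[i, j] < 0) eta[, j] <- -eta[, j]
  }
  structure(list(sigma = sig, eta = eta, mu = gen$mu, points = gen$points,
                 r = as.integer(r), model_name = gen$model_name),
            class = "spectral_reference")
}

#' @export
print.spectral_reference <- function(x, ...) {
  cat(sprintf("Spectral reference for '%s': %d modes on %d nodes\n",
              x$model_name, x$r, nrow(x$eta)))
  cat("  smallest rates:", format(signif(utils::head(x$sigma, 6), 4)), "\n")
  invisible(x)
}

#' Save / load a spectral reference (binary container)
#'
#' @param ref a `"spectral_reference"`.
#' @param file path.
#' @export
write_reference <- function(ref, file) {
  stopifnot(inherits(ref, "spectral_reference"))
  saveRDS(ref, file)
  invisible(file)
}

#' @rdname write_reference
#' @export
read_reference <- function(file) readRDS(file)

# grid evaluation of a basis argument: accepts a basis_set or an N x n
# matrix of node values
.basis_on_grid <- function(basis, ref) {
  if (inherits(basis, "basis_set")) evaluate_basis(basis, ref$points)
  else {
    bv <- as.matrix(basis)
    stopifnot(nrow(bv) == nrow(ref$eta))
    bv
  }
}

#' Exact lagged correlation matrices from the grid oracle
#'
#' Computes `C(0)[i,j] = <phi_i, phi_j>_mu` (the full Gram matrix) and
#' \deqn{C(\tau)_{ij} = \sum_{l \le r} e^{-\sigma_l \tau}
#'   \langle \eta_l, \phi_i\rangle_\mu \langle \eta_l, \phi_j\rangle_\mu}
#' over the truncated reference spectrum.  The neglected tail of each
#' entry is bounded by \eqn{e^{-\sigma_r \tau}\,\|P_\perp\phi_i\|\,
#' \|P_\perp\phi_j\|} where \eqn{P_\perp} removes the first `r` modes;
#' the call errors if this exceeds `tail_tol` relative to
#' \eqn{\|\phi_i\|\|\phi_j\|} (increase `r` or the lag).  A reference
#' computed densely with the complete grid spectrum has zero tail.  The
#' default tolerance keeps the truncation error well below the grid
#' discretization error of the reference itself.
#'
#' @param ref a `"spectral_reference"`.
#' @param basis a `"basis_set"` or an `N x n` matrix of node values.
#' @param tau lag time (>= 0); `tau = 0` returns the Gram matrix for both
#'   entries.
#' @param tail_tol relative truncation tolerance.
#' @return a `"correlation_pair"` with `source = "oracle"`.
#' @export
exact_correlations <- function(ref, basis, tau, tail_tol = 1e-5) {
  stopifnot(inherits(ref, "spectral_reference"), tau >= 0)
  bv <- .basis_on_grid(basis, ref)
  C0 <- crossprod(bv, ref$mu * bv)
  C0 <- (C0 + t(C0)) / 2
  if (tau == 0)
    return(new_correlation_pair(C0, C0, tau = 0, source = "oracle"))
  A <- crossprod(ref$eta, ref$mu * bv)         # r x n overlaps
  Ct <- crossprod(A, exp(-ref$sigma * tau) * A)
  Ct <- (Ct + t(Ct)) / 2
  res <- sqrt(pmax(diag(C0) - colSums(A^2), 0))
  nrm <- sqrt(pmax(diag(C0), .Machine$double.eps))
  tail_rel <- exp(-ref$sigma[ref$r] * tau) * max(outer(res / nrm, res / nrm))
  if (tail_rel > tail_tol)
    stop(sprintf("spectral truncation insufficient at tau = %g: tail bound %.2e exceeds %.0e; increase r in reference_spectrum()",
                 tau, tail_rel, tail_tol))
  new_correlation_pair(C0, Ct, tau = tau, source = "oracle")
}

#' Idealized VAC on the grid oracle
#'
#' Convenience wrapper: exact correlation matrices at lag `tau` followed
#' by the generalized symmetric eigensolve.  The returned solution gains
#' a `gamma` field with the idealized VAC eigenfunctions evaluated on the
#' oracle grid.
#'
#' @inheritParams exact_correlations
#' @param rank_tol relative rank tolerance passed to [solve_vac()].
#' @return a `"vac_solution"` with grid `gamma` values.
#' @export
idealized_vac <- function(ref, basis, tau, rank_tol = 1e-10, tail_tol = 1e-5) {
  bv <- .basis_on_grid(basis, ref)
  corr <- exact_correlations(ref, bv, tau, tail_tol = tail_tol)
  sol <- solve_vac(corr, rank_tol = rank_tol)
  sol$gamma <- bv %*% sol$vectors
  sol
}
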