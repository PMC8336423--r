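new_correlation_pair <- function(C0, Ct, tau, source, n_frames_used = NA_integer_,
                                 delta = NA_real_) {
  C0 <- as.matrix(C0); Ct <- as.matrix(Ct)
  sc <- max(abs(C0), 1e-300)
  if (max(abs(C0 - t(C0))) > 1e-10 * sc || max(abs(Ct - t(Ct))) > 1e-10 * sc)
    stop("correlation matrices must be symmetric")
  structure(list(C0 = C0, Ct = Ct, tau = tau, source = source,
                 n_frames_used = n_frames_used, delta = delta),
            class = "correlation_pair")
}

#' @export
print.correlation_pair <- function(x, ...) {
  cat(sprintf("Correlation pair (%s): n = %d, tau = %g\n",
              x$source, ncol(x$C0), x$tau))
  invisible(x)
}

#' Empirical lagged correlation matrices from trajectory data
#'
#' The symmetrized time-average estimator
#' \deqn{\hat C_{ij}(t) = \frac{1}{\#\mathrm{pairs}} \sum_s
#'   \tfrac12\big[\phi_i(X_{s\Delta})\phi_j(X_{s\Delta+t}) +
#'   \phi_j(X_{s\Delta})\phi_i(X_{s\Delta+t})\big],}
#' with \eqn{\hat C(0)} computed by the same formula at `t = 0` over all
#' frames.  The average over pairs equals the conventional
#' \eqn{\Delta/(T-t)} normalization; VAC eigenvalues and all diagnostics
#' are invariant to this overall scale.  Multiple trajectories are pooled
#' by summing pair contributions before normalizing.
#'
#' @param traj a `"trajectory"` or list of trajectories (same `delta`).
#' @param basis a `"basis_set"`.
#' @param tau lag time; must be an integer multiple of the sampling
#'   interval and leave at least 10 frame pairs.
#' @return a `"correlation_pair"` with `source = "empirical"`.
#' @export
empirical_correlations <- function(traj, basis, tau) {
  trajs <- if (inherits(traj, "trajectory")) list(traj) else traj
  stopifnot(length(trajs) >= 1, inherits(trajs[[1]], "trajectory"))
  delta <- trajs[[1]]$delta
  k <- tau / delta
  if (abs(k - round(k)) > 1e-8 * max(1, abs(k)))
    stop("tau = ", tau, " is not an integer multiple of delta = ", delta)
  k <- as.integer(round(k))
  n <- basis$n
  S0 <- matrix(0, n, n); St <- matrix(0, n, n)
  n0 <- 0L; npairs <- 0L
  use_sparse <- basis$kind == "indicator" && !basis$mean_removed
  for (tr in trajs) {
    stopifnot(abs(tr$delta - delta) < 1e-12)
    E <- evaluate_basis(basis, tr$states, sparse = use_sparse)
    N <- nrow(E)
    if (N - k < 1) stop("tau exceeds the trajectory length")
    S0 <- S0 + as.matrix(crossprod(E))
    n0 <- n0 + N
    if (k == 0) {
      St <- St + as.matrix(crossprod(E)); npairs <- npairs + N
    } else {
      A <- E[seq_len(N - k), , drop = FALSE]
      B <- E[(k + 1):N, , drop = FALSE]
      St <- St + as.matrix(crossprod(A, B))
      npairs <- npairs + (N - k)
    }
  }
  if (npairs < 10) stop("too few frame pairs (", npairs, ") at tau = ", tau)
  C0 <- (S0 + t(S0)) / (2 * n0)
  Ct <- (St + t(St)) / (2 * npairs)
  new_correlation_pair(C0, Ct, tau = tau, source = "empirical",
                       n_frames_used = n0, delta = delta)
}

#' Solve the VAC generalized eigenproblem
#'
#' Solves `C(tau) v = lambda C(0) v` as a symmetric-definite problem:
#' `C(0)` is eigendecomposed, directions with relative eigenvalue below
#' `rank_tol` are dropped (empty indicator cells disappear here), the
#' problem is whitened and a symmetric eigensolve returns real
#' eigenvalues sorted in decreasing order.  Coefficient columns satisfy
#' `t(V) %*% C0 %*% V = I` and `t(V) %*% Ct %*% V = diag(lambda)`; each
#' column is scaled so its largest-magnitude entry is positive.
#'
#' @param corr a `"correlation_pair"`.
#' @param rank_tol relative threshold on `C(0)` eigenvalues.
#' @return an object of class `"vac_solution"` with fields `values`,
#'   `vectors` (`n x m`), `tau`, `rank` (m), `dropped`, `source`.
#' @export
solve_vac <- function(corr, rank_tol = 1e-10) {
  stopifnot(inherits(corr, "correlation_pair"))
  C0 <- corr$C0; Ct <- corr$Ct
  if (!all(is.finite(C0)) || !all(is.finite(Ct)))
    stop("non-finite entries in correlation matrices")
  e0 <- eigen(C0, symmetric = TRUE)
  keep <- e0$values > rank_tol * max(e0$values)
  if (!any(keep)) stop("C(0) is numerically zero")
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  Mt <- crossprod(W, Ct %*% W)
  e <- eigen((Mt + t(Mt)) / 2, symmetric = TRUE)
  V <- W %*% e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(values = e$values, vectors = V, tau = corr$tau,
                 rank = sum(keep), dropped = ncol(C0) - sum(keep),
                 source = corr$source),
            class = "vac_solution")
}

#' @export
print.vac_solution <- function(x, ...) {
  cat(sprintf("VAC solution (%s): tau = %g, rank %d (%d dropped)\n",
              x$source, x$tau, x$rank, x$dropped))
  cat("  leading eigenvalues:", format(signif(utils::head(x$values, 6), 4)), "\n")
  invisible(x)
}

#' Evaluate VAC eigenfunctions at points
#'
#' \eqn{\hat\gamma_i = \sum_j V_{ji} \phi_j}: the basis evaluation matrix
#' times the coefficient matrix.
#'
#' @param sol a `"vac_solution"`.
#' @param basis the `"basis_set"` the solution was fitted with.
#' @param points `frames x dim` matrix.
#' @return `frames x m` matrix of eigenfunction values.
#' @export
eigenfunction_values <- function(sol, basis, points) {
  stopifnot(inherits(sol, "vac_solution"))
  E <- evaluate_basis(basis, points,
                      sparse = basis$kind == "indicator" && !basis$mean_removed)
  if (ncol(E) != nrow(sol$vectors))
    stop("dimension mismatch between basis and solution")
  as.matrix(E %*% sol$vectors)
}

#' Implied timescales
#'
#' \eqn{t_i = -\tau / \log \lambda_i} for eigenvalues in (0, 1); `Inf`
#' for eigenvalues >= 1 (stationary or super-stationary estimates) and
#' `NA` for eigenvalues <= 0 (undefined).  For exact eigenvalues
#' \eqn{e^{-\sigma_i\tau}} the timescales are lag-independent and equal
#' \eqn{1/\sigma_i}.
#'
#' @param sol a `"vac_solution"`, or a numeric vector of eigenvalues (in
#'   which case `tau` must be given).
#' @param tau lag time (taken from the solution when omitted).
#' @return numeric vector of timescales.
#' @export
implied_timescales <- function(sol, tau = NULL) {
  if (inherits(sol, "vac_solution")) {
    lam <- sol$values
    if (is.null(tau)) tau <- sol$tau
  } else lam <- sol
  stopifnot(!is.null(tau), tau > 0)
  out <- rep(NA_real_, length(lam))
  out[lam >= 1] <- Inf
  ok <- lam > 0 & lam < 1
  out[ok] <- -tau / log(lam[ok])
  out
}
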