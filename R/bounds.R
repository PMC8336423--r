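# orthonormal grid representation of the basis span, plus residuals off
# the reference spectrum
.ortho_basis_grid <- function(ref, bv, tol = 1e-10) {
  phi <- function_subspace(bv, ref$mu, "grid")
  orthonormalize(phi, tol = tol)$basis
}

#' Orthogonalized projection functions
#'
#' The Gram--Schmidt sequence built from the projected eigenfunctions
#' \eqn{P_\Phi \eta_1, P_\Phi \eta_2, \ldots}:
#' \deqn{\tilde q_p = P_\Phi \eta_p - \sum_{i<p} \langle q_i, \eta_p\rangle q_i,
#'   \qquad q_p = \tilde q_p / \|\tilde q_p\|.}
#' These are the lag-infinity limits of the idealized VAC eigenfunctions.
#' Note the recursion subtracts \eqn{\langle q_i, \eta_p\rangle q_i}
#' (equal to \eqn{\langle q_i, P_\Phi\eta_p\rangle q_i} since
#' \eqn{q_i \in \Phi}).
#'
#' @param ref a `"spectral_reference"`.
#' @param basis a `"basis_set"` or node-value matrix.
#' @param p number of functions to construct; defaults to
#'   `min(n, r - 1)` so that the overlap table can include row `p + 1`.
#' @return an object of class `"q_set"`: `Q` (`N x p` grid values,
#'   mu-orthonormal, inside the basis span), and `overlaps` with entries
#'   \eqn{\langle \eta_i, q_j\rangle} for `i <= min(p + 1, r)`,
#'   `j <= p`.
#' @export
orthogonalized_projections <- function(ref, basis, p = NULL) {
  stopifnot(inherits(ref, "spectral_reference"))
  bv <- .basis_on_grid(basis, ref)
  A <- .ortho_basis_grid(ref, bv)
  n_eff <- ncol(A)
  if (is.null(p)) p <- min(n_eff, ref$r - 1L)
  stopifnot(p >= 1, p <= min(n_eff, ref$r))
  N <- nrow(A)
  Q <- matrix(0, N, p)
  for (i in seq_len(p)) {
    eta_i <- ref$eta[, i]
    qt <- A %*% crossprod(A, ref$mu * eta_i)       # P_Phi eta_i
    if (i > 1) {
      ov <- crossprod(Q[, seq_len(i - 1), drop = FALSE], ref$mu * eta_i)
      qt <- qt - Q[, seq_len(i - 1), drop = FALSE] %*% ov
    }
    nrm <- sqrt(sum(ref$mu * qt^2))
    if (nrm < 1e-10)
      stop("projections P_Phi eta_i are linearly dependent at i = ", i,
           "; the orthogonalized-projection construction assumes independence")
    Q[, i] <- qt / nrm
  }
  i_max <- min(p + 1L, ref$r)
  overlaps <- crossprod(ref$eta[, seq_len(i_max), drop = FALSE], ref$mu * Q)
  structure(list(Q = Q, overlaps = overlaps, p = as.integer(p), mu = ref$mu),
            class = "q_set")
}

new_bound_report <- function(type, tau, k, lower, upper, observed,
                             applicable = TRUE, extras = list()) {
  structure(c(list(type = type, tau = tau, k = k, lower = lower,
                   upper = upper, observed = observed,
                   applicable = applicable), extras),
            class = "bound_report")
}

#' @export
print.bound_report <- function(x, ...) {
  cat(sprintf("%s bound at tau = %g, k = %d: [%g, %g], observed %g%s\n",
              x$type, x$tau, x$k, x$lower, x$upper, x$observed,
              if (x$applicable) "" else " (inapplicable)"))
  invisible(x)
}

.eta_subspace <- function(ref, idx)
  function_subspace(ref$eta[, idx, drop = FALSE], ref$mu, "grid")

#' Rayleigh--Ritz eigenvalue bound
#'
#' For the k-th idealized VAC eigenvalue,
#' \deqn{1 - d_2^2(\mathrm{span}\,\eta_{1..k}, \Phi) \le
#'   \lambda_k^\tau e^{\sigma_k \tau} \le 1.}
#'
#' @param ref a `"spectral_reference"`.
#' @param basis a `"basis_set"` or node-value matrix.
#' @param tau lag time (> 0).
#' @param k eigenvalue index.
#' @param sol optional pre-computed [idealized_vac()] solution at `tau`.
#' @return a `"bound_report"` with the observed ratio
#'   \eqn{\lambda_k^\tau / e^{-\sigma_k\tau}}.
#' @export
rayleigh_ritz_eigenvalue_bound <- function(ref, basis, tau, k, sol = NULL) {
  bv <- .basis_on_grid(basis, ref)
  if (is.null(sol)) sol <- idealized_vac(ref, bv, tau)
  phi <- function_subspace(bv, ref$mu, "grid")
  d2 <- as.numeric(gap_distance(.eta_subspace(ref, 1:k), phi))
  observed <- sol$values[k] / exp(-ref$sigma[k] * tau)
  new_bound_report("rayleigh_ritz_eigenvalue", tau, k,
                   lower = 1 - d2^2, upper = 1, observed = observed,
                   extras = list(d2 = d2))
}

#' Off-diagonal operator norm of the transition operator
#'
#' \eqn{\|P_{\Phi^\perp} T_\tau P_\Phi\|_2} evaluated on the truncated
#' reference spectrum, plus a tail safety margin
#' \eqn{e^{-\sigma_r\tau} \|P_{>r} P_\Phi\|_2} for the neglected modes
#' (zero when the reference carries the complete grid spectrum).
#'
#' @inheritParams rayleigh_ritz_eigenvalue_bound
#' @return a scalar norm bound.
#' @export
offblock_norm <- function(ref, basis, tau) {
  bv <- .basis_on_grid(basis, ref)
  A <- .ortho_basis_grid(ref, bv)
  X <- crossprod(ref$eta, ref$mu * A)            # r x p mode coefficients
  TA <- ref$eta %*% (exp(-ref$sigma * tau) * X)
  Y <- TA - A %*% crossprod(A, ref$mu * TA)
  G <- crossprod(Y, ref$mu * Y)
  nrm <- sqrt(max(eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values, 0))
  Rm <- diag(ncol(A)) - crossprod(X)
  tail_p <- sqrt(max(eigen((Rm + t(Rm)) / 2, symmetric = TRUE, only.values = TRUE)$values, 0))
  nrm + exp(-ref$sigma[ref$r] * tau) * tail_p
}

# shared observed ratio d_F^2(Gamma_{1..k}, H_{1..k}) / d_F^2(H_{1..k}, Phi)
.observed_subspace_ratio <- function(ref, bv, sol, k) {
  phi <- function_subspace(bv, ref$mu, "grid")
  H <- .eta_subspace(ref, 1:k)
  Gam <- function_subspace(sol$gamma[, 1:k, drop = FALSE], ref$mu, "grid")
  num <- as.numeric(projection_distance(Gam, H))^2
  den <- as.numeric(projection_distance(H, phi))^2
  # basis spans the eigenfunctions exactly: the ratio is 0/0 in exact
  # arithmetic (the theorems force num = 0 when den = 0) and only roundoff
  # remains; report the exact-case value 1
  if (den < 1e-20) return(list(ratio = 1, num = num, den = den))
  list(ratio = num / den, num = num, den = den)
}

#' Rayleigh--Ritz subspace bound
#'
#' For the span of the top k idealized VAC eigenfunctions,
#' \deqn{1 \le \frac{d_F^2(\Gamma_{1..k}, H_{1..k})}{d_F^2(H_{1..k}, \Phi)}
#'   \le 1 + \frac{\|P_{\Phi^\perp} T_\tau P_\Phi\|_2^2}
#'            {|e^{-\sigma_k \tau} - \lambda_{k+1}^\tau|^2}.}
#' The denominator can vanish; the report is then flagged inapplicable.
#' This bound diverges at long lags whenever \eqn{\sigma_k > \sigma_2}
#' even though the observed ratio stabilizes.
#'
#' @inheritParams rayleigh_ritz_eigenvalue_bound
#' @return a `"bound_report"`; when both distances in the observed ratio
#'   are below 1e-12 (invariant basis), the observed value is reported
#'   as 1.
#' @export
rayleigh_ritz_subspace_bound <- function(ref, basis, tau, k, sol = NULL) {
  bv <- .basis_on_grid(basis, ref)
  if (is.null(sol)) sol <- idealized_vac(ref, bv, tau)
  stopifnot(k + 1 <= length(sol$values))
  gap <- exp(-ref$sigma[k] * tau) - sol$values[k + 1]
  nrm <- offblock_norm(ref, bv, tau)
  obs <- .observed_subspace_ratio(ref, bv, sol, k)
  applicable <- abs(gap) > 1e-14
  upper <- if (applicable) 1 + nrm^2 / gap^2 else Inf
  new_bound_report("rayleigh_ritz_subspace", tau, k,
                   lower = 1, upper = upper, observed = obs$ratio,
                   applicable = applicable,
                   extras = list(offblock_norm = nrm, gap = gap,
                                 num = obs$num, den = obs$den))
}

#' Sharp long-lag subspace bound
#'
#' When \eqn{\lambda_k^\tau > e^{-\sigma_{k+1}\tau}},
#' \deqn{1 \le \frac{d_F^2(\Gamma_{1..k}, H_{1..k})}{d_F^2(H_{1..k}, \Phi)}
#'   \le 1 + \frac14\Big(\frac{e^{-\sigma_{k+1}\tau}}
#'        {\lambda_k^\tau - e^{-\sigma_{k+1}\tau}}\Big)^2.}
#' Unlike the Rayleigh--Ritz subspace bound this tends to 1 as
#' \eqn{\tau \to \infty}, matching the stabilization of the observed
#' approximation error.
#'
#' @inheritParams rayleigh_ritz_eigenvalue_bound
#' @return a `"bound_report"`; inapplicable (flagged, upper `Inf`) when
#'   the eigenvalue condition fails.
#' @export
sharp_subspace_bound <- function(ref, basis, tau, k, sol = NULL) {
  bv <- .basis_on_grid(basis, ref)
  if (is.null(sol)) sol <- idealized_vac(ref, bv, tau)
  ek1 <- exp(-ref$sigma[k + 1] * tau)
  applicable <- sol$values[k] > ek1
  upper <- if (applicable) 1 + 0.25 * (ek1 / (sol$values[k] - ek1))^2 else Inf
  obs <- .observed_subspace_ratio(ref, bv, sol, k)
  new_bound_report("sharp_subspace", tau, k, lower = 1, upper = upper,
                   observed = obs$ratio, applicable = applicable,
                   extras = list(num = obs$num, den = obs$den))
}

#' Long-lag limits of idealized VAC
#'
#' Tabulates, over a lag grid, the idealized quantities
#' \eqn{\lambda_k^\tau e^{\sigma_k\tau}} (which converges to
#' \eqn{\langle\eta_k, q_k\rangle^2}) and
#' \eqn{d_F(\Gamma_{1..k}, Q_{1..k})\,\lambda_k^\tau/\lambda_{k+1}^\tau}
#' (which converges to
#' \eqn{|\langle\eta_{k+1}, q_k\rangle / \langle\eta_{k+1}, q_{k+1}\rangle|}),
#' together with their predicted limits.  Rows where the spectral-gap
#' assumptions fail (degenerate `sigma` neighbors) are flagged.
#'
#' @param ref a `"spectral_reference"`.
#' @param basis a `"basis_set"` or node-value matrix.
#' @param tau_grid lag times.
#' @param k_max largest index tabulated (requires `k_max + 1` q-functions).
#' @param qset optional pre-computed [orthogonalized_projections()].
#' @return a data frame with columns `tau`, `k`, `eig_ratio`,
#'   `eig_limit`, `df_ratio`, `df_limit`, `df_gamma_q`, `gap_ok`.
#' @export
long_lag_limits <- function(ref, basis, tau_grid, k_max = 3, qset = NULL) {
  bv <- .basis_on_grid(basis, ref)
  if (is.null(qset)) qset <- orthogonalized_projections(ref, bv, p = k_max + 1L)
  O <- qset$overlaps
  rows <- list()
  for (tau in tau_grid) {
    sol <- idealized_vac(ref, bv, tau)
    for (k in seq_len(k_max)) {
      gap_ok <- (ref$sigma[k + 1] - ref$sigma[k] > 1e-8) &&
        (k == 1 || ref$sigma[k] - ref$sigma[k - 1] > 1e-8) &&
        (ref$sigma[k + 2] - ref$sigma[k + 1] > 1e-8)
      Gam <- function_subspace(sol$gamma[, 1:k, drop = FALSE], ref$mu, "grid")
      Qk <- function_subspace(qset$Q[, 1:k, drop = FALSE], ref$mu, "grid")
      dfq <- as.numeric(projection_distance(Gam, Qk))
      lam_ratio <- sol$values[k] / sol$values[k + 1]
      rows[[length(rows) + 1]] <- data.frame(
        tau = tau, k = k,
        eig_ratio = sol$values[k] * exp(ref$sigma[k] * tau),
        eig_limit = O[k, k]^2,
        df_ratio = dfq * lam_ratio,
        df_limit = abs(O[k + 1, k] / O[k + 1, k + 1]),
        df_gamma_q = dfq,
        gap_ok = gap_ok)
    }
  }
  do.call(rbind, rows)
}

#' Lag-time-independent error bound
#'
#' The squared distance between the orthogonalized projections
#' `span q_{j..k}` and the true invariant subspace `span eta_{j..k}` is
#' bounded by
#' \deqn{d_F^2(Q_{j..k}, H_{j..k}) \le d_F^2(H_{1..j-1}, \Phi) +
#'   d_F^2(H_{1..k}, \Phi),}
#' so enriching the basis drives the lag-independent part of the
#' approximation error to zero.
#'
#' @inheritParams long_lag_limits
#' @param j,k subspace index range (`1 <= j <= k`).
#' @return a list with `lhs`, `rhs`, and `satisfied`.
#' @export
lag_independent_bound <- function(ref, basis, j, k, qset = NULL) {
  stopifnot(j >= 1, k >= j)
  bv <- .basis_on_grid(basis, ref)
  if (is.null(qset)) qset <- orthogonalized_projections(ref, bv, p = k)
  phi <- function_subspace(bv, ref$mu, "grid")
  Qjk <- function_subspace(qset$Q[, j:k, drop = FALSE], ref$mu, "grid")
  lhs <- as.numeric(projection_distance(Qjk, .eta_subspace(ref, j:k)))^2
  rhs_head <- if (j == 1) 0
    else as.numeric(projection_distance(.eta_subspace(ref, 1:(j - 1)), phi))^2
  rhs <- rhs_head + as.numeric(projection_distance(.eta_subspace(ref, 1:k), phi))^2
  list(lhs = lhs, rhs = rhs, satisfied = lhs <= rhs + 1e-10)
}
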