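#' First-order loss matrix
#'
#' \deqn{\hat L_{ij}(\tau) = v_i(\tau)^T\,[\hat C(\tau) -
#'   \lambda_j^\tau \hat C(0)]\,v_j(\tau),}
#' with coefficients and eigenvalues from a (typically idealized)
#' solution and hatted matrices from data.  To first order in the matrix
#' errors, \eqn{\hat\lambda_k - \lambda_k = \hat L_{kk}} and the subspace
#' estimation error is \eqn{(\sum_{l,m} |\hat L_{lm}/(\lambda_l -
#' \lambda_m)|^2)^{1/2}} over pairs straddling the subspace boundary.
#' When the solution was fitted from the same matrices, `L` vanishes.
#'
#' @param corr_hat a `"correlation_pair"` (data estimates).
#' @param sol a `"vac_solution"` normalized against its own `C(0)`.
#' @return an object of class `"loss_matrix"` (an `m x m` matrix with
#'   attributes `tau` and `lambda`).
#' @export
loss_matrix <- function(corr_hat, sol) {
  stopifnot(inherits(corr_hat, "correlation_pair"),
            inherits(sol, "vac_solution"))
  V <- sol$vectors
  if (nrow(V) != ncol(corr_hat$C0)) stop("dimension mismatch")
  A <- crossprod(V, corr_hat$Ct %*% V)
  B <- crossprod(V, corr_hat$C0 %*% V)
  L <- A - sweep(B, 2, sol$values, `*`)
  structure(L, class = c("loss_matrix", "matrix"), tau = corr_hat$tau,
            lambda = sol$values)
}

#' VAC condition number of an eigenfunction subspace
#'
#' For the subspace spanned by eigenfunctions `j` through `k`,
#' \deqn{\kappa = 1 / \min\{\lambda_{j-1} - \lambda_j,\;
#'   \lambda_k - \lambda_{k+1}\},}
#' with the conventions \eqn{\lambda_0 = \infty} and
#' \eqn{\lambda_{m+1} = -\infty}.  It is the first-order amplification
#' factor from correlation-matrix error to subspace error; subspaces
#' whose minimum condition number over all lag times exceeds about 5 are
#' prone to large estimation error.
#'
#' @param values eigenvalues sorted in decreasing order (or a
#'   `"vac_solution"`).
#' @param j,k index range of the subspace (`1 <= j <= k <= m`).
#' @return the condition number (positive; 0 if the whole space is taken).
#' @export
condition_number <- function(values, j, k) {
  if (inherits(values, "vac_solution")) values <- values$values
  m <- length(values)
  if (!(1 <= j && j <= k && k <= m)) stop("need 1 <= j <= k <= m")
  left <- if (j == 1) Inf else values[j - 1] - values[j]
  right <- if (k == m) Inf else values[k] - values[k + 1]
  1 / min(left, right)
}

#' Minimum condition number across lag times
#'
#' Applies [condition_number()] to a family of per-lag solutions and
#' reports the minimum, the rule-of-thumb flag (minimum above 5 signals a
#' subspace prone to large estimation error), and the per-lag values.
#'
#' @param solutions a list of `"vac_solution"` objects (one per lag).
#' @param j,k subspace index range.
#' @return an object of class `"condition_report"`.
#' @export
minimum_condition_number <- function(solutions, j, k) {
  taus <- vapply(solutions, function(s) s$tau, 0)
  kappas <- vapply(solutions, function(s) condition_number(s$values, j, k), 0)
  source <- unique(vapply(solutions, function(s) s$source, ""))
  structure(list(j = j, k = k, tau = taus, kappa = kappas,
                 kappa_min = min(kappas), flagged = min(kappas) > 5,
                 source = paste(source, collapse = "+")),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("VAC condition number for subspace %d..%d (%s eigenvalues)\n",
              x$j, x$k, x$source))
  cat(sprintf("  min over %d lags: %.3g%s\n", length(x$tau), x$kappa_min,
              if (x$flagged) "  [> 5: prone to large estimation error]" else ""))
  invisible(x)
}

# default truncation window for the long-run variance estimator:
# min(N/10, 5 times the slowest implied timescale in frames)
.default_window <- function(sol, delta, n_series) {
  ts <- implied_timescales(sol)
  ts <- ts[-1][is.finite(ts[-1]) & ts[-1] > 0]
  t2 <- if (length(ts)) max(ts) else sol$tau
  max(1L, min(floor(n_series / 10), ceiling(5 * t2 / delta)))
}

#' Plug-in asymptotic mean squared estimation error
#'
#' Data-driven evaluation of the central-limit estimation-error formulas.
#' For each eigenfunction pair `(l, m)` with `l` outside and `m` inside
#' the index range `j..k`, the time series
#' \deqn{F_{lm}(x, y) = \tfrac12[\gamma_l(x)\gamma_m(y) +
#'   \gamma_l(y)\gamma_m(x)] - \tfrac{\lambda_m}{2}
#'   [\gamma_l(x)\gamma_m(x) + \gamma_l(y)\gamma_m(y)]}
#' is formed along the trajectory at the solution's lag, its long-run
#' variance \eqn{E|Z_{lm}|^2 = \Delta \sum_s \mathrm{Cov}} is estimated
#' with a Bartlett-tapered autocovariance sum, and the subspace mean
#' squared error is assembled as
#' \eqn{\sum_{l,m} E|Z_{lm}|^2 / (\lambda_l - \lambda_m)^2 / T}.
#' Idealized eigenfunctions and eigenvalues are replaced by their
#' estimates (plug-in, first-order consistent).  Diagonal terms give
#' per-eigenvalue variances \eqn{E|Z_{ii}|^2 / T}.
#'
#' @param traj the `"trajectory"` the solution was fitted on (or another
#'   stationary trajectory of the same process).
#' @param basis the `"basis_set"` of the fit.
#' @param sol a `"vac_solution"` at the lag of interest.
#' @param j,k subspace index range.
#' @param window truncation window (frames) of the tapered autocovariance
#'   sum; defaults to `min(N/10, 5 t_2 / delta)` with `t_2` the slowest
#'   estimated implied timescale.
#' @return an object of class `"mse_report"`: `pairs` (per-pair long-run
#'   variances, gaps, and exclusion flags for gaps below 1e-12), `mse`,
#'   `root_mse`, `eigen_var` (per-eigenvalue asymptotic variances),
#'   `window`, `T`, `tau`.
#' @export
asymptotic_mse <- function(traj, basis, sol, j, k, window = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(sol, "vac_solution"),
            1 <= j, j <= k, k <= length(sol$values))
  delta <- traj$delta
  kf <- as.integer(round(sol$tau / delta))
  if (abs(sol$tau - kf * delta) > 1e-8) stop("solution lag not on the frame grid")
  G <- eigenfunction_values(sol, basis, traj$states)
  .mse_from_gamma(G, delta, sol, j, k, window)
}

# core of asymptotic_mse, starting from evaluated eigenfunction series
.mse_from_gamma <- function(G, delta, sol, j, k, window = NULL) {
  kf <- as.integer(round(sol$tau / delta))
  N <- nrow(G)
  np <- N - kf
  if (np < 20) stop("trajectory too short for the lag")
  lam <- sol$values
  m_tot <- length(lam)
  inside <- j:k
  outside <- setdiff(seq_len(m_tot), inside)
  pairs <- expand.grid(l = outside, m = inside)
  gap <- lam[pairs$l] - lam[pairs$m]
  excluded <- abs(gap) < 1e-12
  if (is.null(window)) window <- .default_window(sol, delta, np)
  window <- as.integer(window)
  if (window >= np) stop("window exceeds the series length")
  Tlen <- N * delta
  lrv_pairs <- if (nrow(pairs))
    pair_lrvar_cpp(G, kf, lam, pairs$l, pairs$m, window, delta)
    else numeric(0)
  lrv_diag <- pair_lrvar_cpp(G, kf, lam, seq_len(m_tot), seq_len(m_tot),
                             window, delta)
  use <- !excluded
  mse <- sum(lrv_pairs[use] / gap[use]^2) / Tlen
  structure(list(
    pairs = data.frame(l = pairs$l, m = pairs$m, lrv = lrv_pairs,
                       gap = gap, excluded = excluded),
    mse = mse, root_mse = sqrt(mse),
    eigen_var = lrv_diag / Tlen,
    window = window, T = Tlen, tau = sol$tau, n_excluded = sum(excluded)),
    class = "mse_report")
}

#' @export
print.mse_report <- function(x, ...) {
  cat(sprintf("Plug-in estimation error at tau = %g (T = %g, window = %d frames)\n",
              x$tau, x$T, x$window))
  cat(sprintf("  subspace root-MSE: %.4g (%d pairs, %d excluded)\n",
              x$root_mse, nrow(x$pairs), x$n_excluded))
  invisible(x)
}

#' Bartlett long-run variance of stationary series
#'
#' \eqn{\Delta\,[\hat g_0 + 2\sum_{s=1}^{w}(1 - s/(w+1))\,\hat g_s]}
#' per column, where \eqn{\hat g_s} is the lag-`s` sample autocovariance.
#' This is the spectral-density-at-zero estimate entering the
#' central-limit variance of time averages sampled every `delta`.
#'
#' @param x numeric matrix, one stationary series per column.
#' @param window taper width `w` (frames).
#' @param delta sampling interval.
#' @return numeric vector of per-column long-run variances (clamped at 0).
#' @export
long_run_variance <- function(x, window, delta = 1) {
  lrvar_bartlett_cpp(as.matrix(x), as.integer(window), delta)
}
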