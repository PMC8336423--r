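# shared experiment engine: simulate replicates, fit VAC over a lag grid,
# and assemble total / approximation / estimation / calculated error curves
run_experiment <- function(model, basis, ref, tau_grid, subspace,
                           n_replicates, T, delta, sub_steps, seed,
                           compute_mse = TRUE, window = NULL,
                           rank_tol = 1e-10, tail_tol = 1e-5,
                           label = model$name) {
  j <- subspace[1]; k <- subspace[2]
  stopifnot(1 <= j, j <= k)
  bad <- abs(tau_grid / delta - round(tau_grid / delta)) > 1e-8
  if (any(bad)) stop("tau grid must lie on the frame lattice")
  Bgrid <- evaluate_basis(basis, ref$points)
  n_tau <- length(tau_grid)
  H <- function_subspace(ref$eta[, j:k, drop = FALSE], ref$mu, "grid")

  ideal <- lapply(tau_grid, function(tau)
    idealized_vac(ref, Bgrid, tau, rank_tol = rank_tol, tail_tol = tail_tol))
  approx_err <- vapply(ideal, function(s)
    as.numeric(projection_distance(
      function_subspace(s$gamma[, j:k, drop = FALSE], ref$mu, "grid"), H)), 0)
  kappa_ideal <- vapply(ideal, function(s)
    condition_number(s$values, j, k), 0)

  trajs <- simulate_sde(model, total_time = T, delta = delta,
                        sub_steps = sub_steps, seed = seed,
                        n_paths = n_replicates)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)

  k_store <- k + 2L
  total <- est <- rmse <- kap <- matrix(NA_real_, n_tau, n_replicates)
  lam_hat <- array(NA_real_, c(n_tau, n_replicates, k_store))
  use_sparse <- basis$kind == "indicator" && !basis$mean_removed
  for (r in seq_len(n_replicates)) {
    tr <- trajs[[r]]
    E <- evaluate_basis(basis, tr$states, sparse = use_sparse)
    N <- nrow(E)
    C0 <- as.matrix(crossprod(E)) / N
    C0 <- (C0 + t(C0)) / 2
    for (ti in seq_len(n_tau)) {
      kf <- as.integer(round(tau_grid[ti] / delta))
      A <- E[seq_len(N - kf), , drop = FALSE]
      B <- E[(kf + 1):N, , drop = FALSE]
      Ct <- as.matrix(crossprod(A, B))
      Ct <- (Ct + t(Ct)) / (2 * (N - kf))
      corr <- new_correlation_pair(C0, Ct, tau = tau_grid[ti],
                                   source = "empirical",
                                   n_frames_used = N, delta = delta)
      sol <- solve_vac(corr, rank_tol = rank_tol)
      Ghat <- Bgrid %*% sol$vectors[, j:k, drop = FALSE]
      Uhat <- function_subspace(Ghat, ref$mu, "grid")
      total[ti, r] <- as.numeric(projection_distance(Uhat, H))
      Gideal <- function_subspace(ideal[[ti]]$gamma[, j:k, drop = FALSE],
                                  ref$mu, "grid")
      est[ti, r] <- as.numeric(projection_distance(Uhat, Gideal))
      ns <- min(k_store, sol$rank)
      lam_hat[ti, r, seq_len(ns)] <- sol$values[seq_len(ns)]
      kap[ti, r] <- if (sol$rank >= k) condition_number(sol$values, j, k) else NA
      if (compute_mse) {
        G <- as.matrix(E %*% sol$vectors)
        rmse[ti, r] <- .mse_from_gamma(G, delta, sol, j, k,
                                       window = window)$root_mse
      }
    }
  }
  rms <- function(m) sqrt(rowMeans(m^2))
  curves <- data.frame(
    tau = tau_grid,
    approximation = approx_err,
    rms_total = rms(total),
    rms_estimation = rms(est),
    calc_root_mse_median = if (compute_mse)
      apply(rmse, 1, stats::median) else NA_real_,
    kappa_ideal = kappa_ideal,
    kappa_emp_median = apply(kap, 1, stats::median, na.rm = TRUE))
  structure(list(
    curves = curves,
    replicate = list(total = total, estimation = est, root_mse = rmse,
                     kappa = kap, lambda = lam_hat),
    config = list(label = label, model = model$name,
                  n_replicates = n_replicates, T = T, delta = delta,
                  sub_steps = sub_steps, tau_grid = tau_grid,
                  subspace = c(j, k), seed = seed, basis_n = basis$n,
                  basis_kind = basis$kind),
    tau_opt = tau_grid[which.min(rms(total))],
    kappa_min_ideal = min(kappa_ideal),
    kappa_min_emp = min(apply(kap, 1, stats::median, na.rm = TRUE))),
    class = "error_curves")
}

#' @export
print.error_curves <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Error curves '%s': %d replicates, T = %g, n = %d %s basis, subspace %d..%d\n",
              cfg$label, cfg$n_replicates, cfg$T, cfg$basis_n, cfg$basis_kind,
              cfg$subspace[1], cfg$subspace[2]))
  cat(sprintf("  optimal lag (arg-min RMS total error): %g\n", x$tau_opt))
  cat(sprintf("  minimum condition number: %.3g (idealized), %.3g (estimated, median)\n",
              x$kappa_min_ideal, x$kappa_min_emp))
  invisible(x)
}

#' Benchmark experiment: Ornstein--Uhlenbeck trials
#'
#' Estimates the span of the top three transition-operator eigenfunctions
#' of the OU process `dX = -X dt + sqrt(2) dW` with an indicator basis,
#' over a grid of lag times, and decomposes the error of each of
#' `n_replicates` independent stationary trajectories against the grid
#' oracle.  Trial 1 uses a 20-cell basis with trajectory length
#' `T = 1e4` (approximation-error dominated); trial 2 uses a 50-cell
#' basis with `T = 500` (estimation-error dominated).  Cells partition
#' `[-3, 3]` (about three stationary standard deviations) with equal
#' widths.
#'
#' @param trial 1 or 2.
#' @param n_replicates number of independent trajectories (default 30).
#' @param seed integer seed for the replicate ensemble.
#' @param tau_grid lag times (frame-aligned with `delta`).
#' @param T,n_basis optional overrides of the trial defaults.
#' @param layout `"quantile"` (default): equal stationary-mass cells with
#'   unbounded outer cells, the canonical Markov-state-model partition;
#'   `"uniform"`: equal-width cells on `[-basis_range, basis_range]`.
#' @param basis_range half-width of the uniform layout (stationary
#'   standard deviations).
#' @param delta observation spacing.
#' @param sub_steps Euler--Maruyama sub-steps per frame.
#' @param subspace index range `(j, k)` of the estimated subspace.
#' @param compute_mse also compute the plug-in root mean squared
#'   estimation error per replicate and lag (the expensive part).
#' @param window long-run variance window override (frames).
#' @param ref optional pre-computed full-spectrum OU reference.
#' @return an object of class `"error_curves"`.
#' @export
run_ou_trial <- function(trial = 1, n_replicates = 30, seed = 1,
                         tau_grid = seq(0.05, 1.5, by = 0.05),
                         T = NULL, n_basis = NULL,
                         layout = c("quantile", "uniform"), basis_range = 3,
                         delta = 0.05, sub_steps = 5, subspace = c(1, 3),
                         compute_mse = TRUE, window = NULL, ref = NULL) {
  stopifnot(trial %in% c(1, 2))
  layout <- match.arg(layout)
  if (is.null(T)) T <- if (trial == 1) 1e4 else 500
  if (is.null(n_basis)) n_basis <- if (trial == 1) 20 else 50
  edges <- if (layout == "quantile")
    stats::qnorm(seq(0, 1, length.out = n_basis + 1))
  else seq(-basis_range, basis_range, length.out = n_basis + 1)
  model <- make_ou1d()
  basis <- indicator_basis(edges)
  if (is.null(ref)) {
    gen <- discretize_generator(model)
    ref <- reference_spectrum(gen, r = length(gen$m), method = "dense")
  }
  run_experiment(model, basis, ref, tau_grid, subspace, n_replicates,
                 T, delta, sub_steps, seed, compute_mse = compute_mse,
                 window = window, label = sprintf("ou-trial%d", trial))
}

#' Benchmark experiment: 2D double-well diffusion
#'
#' Estimates invariant subspaces of the two-dimensional double-well
#' diffusion from stationary trajectories of length `T = 500` with the
#' quadratic monomial basis `{1, x1, x2, x1^2, x1 x2, x2^2}`.  The
#' subspace `(1, 2)` is well conditioned (wide eigenvalue gap below it);
#' the subspace `(1, 3)` is ill conditioned and shows a sharp V-shaped
#' total-error curve.
#'
#' @param subspace `c(1, 2)` or `c(1, 3)`.
#' @param n_replicates,seed,tau_grid,T,delta,compute_mse,window as in
#'   [run_ou_trial()].
#' @param sub_steps Euler--Maruyama sub-steps per frame (default 50,
#'   i.e. internal step 1e-3).
#' @param r_ref number of oracle modes (spectral truncation).
#' @param ref optional pre-computed reference.
#' @return an object of class `"error_curves"`.
#' @export
run_doublewell <- function(subspace = c(1, 3), n_replicates = 30, seed = 1,
                           tau_grid = seq(0.05, 1.5, by = 0.05),
                           T = 500, delta = 0.05, sub_steps = 50,
                           compute_mse = TRUE, window = NULL,
                           r_ref = 150, ref = NULL) {
  model <- make_doublewell2d()
  basis <- quadratic_basis_2d()
  if (is.null(ref)) {
    gen <- discretize_generator(model)
    ref <- reference_spectrum(gen, r = r_ref)
  }
  run_experiment(model, basis, ref, tau_grid, subspace, n_replicates,
                 T, delta, sub_steps, seed, compute_mse = compute_mse,
                 window = window,
                 label = sprintf("doublewell-%d%d", subspace[1], subspace[2]))
}

#' Implied-timescale report for an experiment
#'
#' Per-lag implied timescales `-tau / log(lambda_hat_i)` for the second
#' and third eigenvalues (median over replicates), with a flatness metric:
#' the relative change of each timescale across the upper half of the lag
#' grid.  Lags where an eigenvalue estimate is not in (0, 1) yield
#' undefined markers and are excluded from the flatness metric.
#'
#' @param curves an `"error_curves"` object.
#' @param indices eigenvalue indices to report (default 2:3).
#' @return a list with a per-lag data frame `table` and named vector
#'   `flatness`.
#' @export
implied_timescale_report <- function(curves, indices = 2:3) {
  stopifnot(inherits(curves, "error_curves"))
  taus <- curves$config$tau_grid
  lam <- curves$replicate$lambda
  tab <- data.frame(tau = taus)
  flat <- numeric(0)
  for (i in indices) {
    li <- lam[, , i, drop = FALSE]
    ts <- vapply(seq_along(taus), function(ti) {
      v <- li[ti, , 1]
      v <- v[!is.na(v) & v > 0 & v < 1]
      if (!length(v)) return(NA_real_)
      stats::median(-taus[ti] / log(v))
    }, 0)
    tab[[paste0("timescale", i)]] <- ts
    upper <- ts[taus >= stats::median(taus)]
    upper <- upper[is.finite(upper)]
    flat[paste0("timescale", i)] <-
      if (length(upper) >= 2) (max(upper) - min(upper)) / stats::median(upper)
      else NA_real_
  }
  list(table = tab, flatness = flat)
}

#' First crossing of an error threshold
#'
#' For the per-replicate plug-in root-MSE curves of an experiment,
#' returns each replicate's first lag at which the curve reaches `level`,
#' their median, and the first crossing of the median curve.
#'
#' @param curves an `"error_curves"` object (run with `compute_mse`).
#' @param level threshold (default 0.2, the practical rule of thumb).
#' @return list with `per_replicate`, `median_crossing`,
#'   `median_curve_crossing` (NA when never crossed).
#' @export
threshold_crossing <- function(curves, level = 0.2) {
  stopifnot(inherits(curves, "error_curves"))
  taus <- curves$config$tau_grid
  rm_ <- curves$replicate$root_mse
  per <- apply(rm_, 2, function(v) {
    i <- which(v >= level)[1]
    if (is.na(i)) NA_real_ else taus[i]
  })
  med_curve <- apply(rm_, 1, stats::median)
  i <- which(med_curve >= level)[1]
  list(per_replicate = per,
       median_crossing = stats::median(per, na.rm = TRUE),
       median_curve_crossing = if (is.na(i)) NA_real_ else taus[i])
}

#' Export experiment results
#'
#' Writes the per-lag curves as CSV and a JSON summary (configuration,
#' optimal lag, minimum condition numbers, threshold crossing).
#'
#' @param curves an `"error_curves"` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_experiment <- function(curves, dir) {
  stopifnot(inherits(curves, "error_curves"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(curves$curves,
                   file.path(dir, paste0(curves$config$label, "_curves.csv")),
                   row.names = FALSE)
  cross <- if (all(is.na(curves$replicate$root_mse))) NULL
           else threshold_crossing(curves)
  summary <- list(config = curves$config, tau_opt = curves$tau_opt,
                  kappa_min_ideal = curves$kappa_min_ideal,
                  kappa_min_emp = curves$kappa_min_emp,
                  crossing_0.2 = cross$median_crossing)
  jsonlite::write_json(summary,
                       file.path(dir, paste0(curves$config$label, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
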