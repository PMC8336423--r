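test_that("the loss matrix vanishes on the matrices that produced the fit", {
  tr <- simulate_sde(make_ou1d(), 300, 0.05, sub_steps = 2, seed = 13)
  b <- ou_quantile_basis(8)
  cp <- empirical_correlations(tr, b, 0.5)
  sol <- solve_vac(cp)
  L <- loss_matrix(cp, sol)
  expect_lt(max(abs(L)), 1e-10)
})

test_that("first-order formulas predict eigenvalue and subspace perturbations", {
  ref <- ou_reference()
  b <- ou_quantile_basis(8)
  cp <- exact_correlations(ref, b, 0.7)
  sol <- solve_vac(cp)
  set.seed(3)
  E <- matrix(rnorm(64), 8); E <- (E + t(E)) / 2; E <- E / norm(E, "F")
  for (eps in c(1e-2, 1e-3)) {
    cph <- vacdiag:::new_correlation_pair(cp$C0, cp$Ct + eps * E, cp$tau, "empirical")
    solh <- solve_vac(cph)
    L <- loss_matrix(cph, sol)
    # eigenvalue error equals the diagonal loss up to O(eps^2)
    expect_lt(abs(solh$values[2] - sol$values[2] - L[2, 2]), 10 * eps^2)
    # subspace error matches the loss-based formula up to O(eps^2)
    pred <- sqrt(sum((L[4:8, 1:3] /
                        outer(sol$values[4:8], sol$values[1:3], `-`))^2))
    est <- function_subspace(solh$vectors[, 1:3], cp$C0, "coords")
    ideal <- function_subspace(sol$vectors[, 1:3], cp$C0, "coords")
    dF <- as.numeric(projection_distance(est, ideal))
    expect_lt(abs(dF - pred), 100 * eps^2)
  }
})

test_that("condition numbers follow the gap formula and index conventions", {
  lam <- c(1.0, 0.8, 0.4, 0.2)
  expect_equal(condition_number(lam, 1, 2), 2.5)        # 1/min(Inf, 0.4)
  expect_equal(condition_number(lam, 2, 2), 5)          # 1/min(0.2, 0.4)
  expect_equal(condition_number(lam, 1, 4), 0)          # whole space: 1/Inf
  expect_error(condition_number(lam, 3, 2), "j <= k")
  sols <- lapply(c(0.2, 0.4), function(tau)
    structure(list(values = c(1, exp(-tau), exp(-3 * tau)), tau = tau,
                   source = "oracle"), class = "vac_solution"))
  rep_ <- minimum_condition_number(sols, 1, 2)
  expect_equal(rep_$kappa_min, min(rep_$kappa))
  expect_true(all(rep_$kappa > 0))
  # invariance under the overall normalization of the correlation matrices
  cp <- vacdiag:::new_correlation_pair(diag(3), diag(c(0.9, 0.5, 0.1)), 1, "oracle")
  cp2 <- vacdiag:::new_correlation_pair(5 * cp$C0, 5 * cp$Ct, 1, "oracle")
  expect_equal(solve_vac(cp)$values, solve_vac(cp2)$values, tolerance = 1e-12)
})

test_that("plug-in estimation error handles degenerate and trivial cases", {
  tr <- simulate_sde(make_ou1d(), 100, 0.05, sub_steps = 2, seed = 17)
  one <- monomial_basis(matrix(0, 1, 1))
  sol <- solve_vac(empirical_correlations(tr, one, 0.5))
  msr <- asymptotic_mse(tr, one, sol, 1, 1)
  expect_equal(msr$mse, 0)                 # no outside pairs
  expect_equal(unname(msr$eigen_var), 0)   # constant eigenfunction: F == 0
  b <- ou_quantile_basis(6)
  sol2 <- solve_vac(empirical_correlations(tr, b, 0.5))
  expect_error(asymptotic_mse(tr, b, sol2, 1, 2, window = 1e6), "window")
  # near-degenerate eigenvalue pairs are excluded, not infinite
  G <- matrix(rnorm(600), 200, 3)
  solx <- structure(list(values = c(0.5, 0.5, 0.2), tau = 1,
                         vectors = diag(3), rank = 3, source = "oracle"),
                    class = "vac_solution")
  rep_ <- vacdiag:::.mse_from_gamma(G, 1, solx, 1, 1, window = 10)
  expect_equal(rep_$n_excluded, 1L)
  expect_true(is.finite(rep_$mse))
})

test_that("plug-in mean squared error scales as 1/T", {
  b <- ou_quantile_basis(10)
  rms_at_T <- function(T, seed) {
    trs <- simulate_sde(make_ou1d(), T, 0.05, sub_steps = 2, seed = seed,
                        n_paths = 4)
    mean(vapply(trs, function(tr) {
      sol <- solve_vac(empirical_correlations(tr, b, 0.5))
      asymptotic_mse(tr, b, sol, 1, 3)$mse
    }, 0))
  }
  ratio <- rms_at_T(400, 41) / rms_at_T(1600, 42)
  expect_gt(sqrt(ratio), 2 * 0.8)
  expect_lt(sqrt(ratio), 2 * 1.2)
})

test_that("the Bartlett long-run variance matches the iid limit", {
  set.seed(5)
  x <- matrix(rnorm(2e4), ncol = 2)
  # iid N(0,1) at window 0: lrv = delta * var
  expect_equal(long_run_variance(x, 0, delta = 2),
               2 * apply(x, 2, function(v) mean((v - mean(v))^2)),
               tolerance = 1e-12)
  # AR(1) series: lrv -> var * (1+rho)/(1-rho)
  rho <- 0.6
  n <- 5e4
  e <- rnorm(n)
  y <- as.numeric(stats::filter(e, rho, method = "recursive"))
  lrv <- long_run_variance(matrix(y), window = 200, delta = 1)
  expect_equal(lrv, (1 / (1 - rho^2)) * (1 + rho) / (1 - rho),
               tolerance = 0.15)
})
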