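test_that("the generalized eigensolve matches closed forms and brute force", {
  cp <- vacdiag:::new_correlation_pair(diag(2), diag(c(0.9, 0.5)), tau = 1,
                                       source = "oracle")
  sol <- solve_vac(cp)
  expect_equal(sol$values, c(0.9, 0.5))
  expect_equal(abs(sol$vectors), diag(2), tolerance = 1e-12)
  # normalization contracts
  expect_lt(max(abs(crossprod(sol$vectors, cp$C0 %*% sol$vectors) - diag(2))), 1e-8)

  set.seed(11)
  for (i in 1:5) {
    A <- matrix(rnorm(64), 8)
    C0 <- crossprod(A) + 0.1 * diag(8)
    B <- matrix(rnorm(64), 8)
    Ct <- (B + t(B)) / 2
    sol <- solve_vac(vacdiag:::new_correlation_pair(C0, Ct, 1, "oracle"))
    brute <- sort(Re(eigen(solve(C0) %*% Ct)$values), decreasing = TRUE)
    expect_equal(sol$values, brute, tolerance = 1e-10)
    expect_lt(max(abs(crossprod(sol$vectors, Ct %*% sol$vectors) -
                        diag(sol$values))), 1e-8)
  }
})

test_that("empirical correlations are symmetric, normalized, and consistent", {
  tr <- simulate_sde(make_ou1d(), 2000, 0.05, sub_steps = 5, seed = 21)
  one <- monomial_basis(matrix(0, 1, 1))
  cp1 <- empirical_correlations(tr, one, 1)
  expect_equal(drop(cp1$Ct), 1)             # constant basis: exactly 1
  b <- ou_quantile_basis(12)
  cp <- empirical_correlations(tr, b, 0.5)
  expect_lt(max(abs(cp$Ct - t(cp$Ct))), 1e-14)
  expect_lt(max(abs(cp$C0 - t(cp$C0))), 1e-14)
  # lag-1 autocorrelation of x within 3 batch-means standard errors
  xb <- monomial_basis(matrix(1, 1, 1))
  cpx <- empirical_correlations(tr, xb, 1)
  x <- tr$states[, 1]; n <- length(x); k <- 20
  ps <- x[seq_len(n - k)] * x[(k + 1):n]
  bm <- tapply(ps, rep(1:20, each = ceiling(length(ps) / 20))[seq_along(ps)], mean)
  expect_lt(abs(drop(cpx$Ct) - exp(-1)), 3 * sd(bm) / sqrt(20) + 0.01)
  # errors
  expect_error(empirical_correlations(tr, b, 0.513), "multiple of delta")
  expect_error(empirical_correlations(tr, b, 1999.95), "too few frame pairs")
  # pooling two half trajectories approximates the full-trajectory estimate
  half1 <- vacdiag:::new_trajectory(tr$states[1:20000, , drop = FALSE], 0.05, 1, "ou1d")
  half2 <- vacdiag:::new_trajectory(tr$states[20001:40000, , drop = FALSE], 0.05, 1, "ou1d")
  cp_pool <- empirical_correlations(list(half1, half2), b, 0.5)
  expect_equal(cp_pool$Ct, cp$Ct, tolerance = 1e-3)
})

test_that("oracle exactness: an invariant basis gives exact eigenvalues", {
  ref <- ou_reference()
  sol <- idealized_vac(ref, ref$eta[, 1:4], 0.6)
  expect_equal(sol$values, exp(-ref$sigma[1:4] * 0.6), tolerance = 1e-8)
})

test_that("idealized eigenvalues obey the variational principle", {
  ref <- ou_reference()
  taus <- seq(0.1, 3, length.out = 8)
  # never exceed the true eigenvalues
  for (tau in taus) {
    sol <- idealized_vac(ref, ou_quantile_basis(20), tau)
    expect_true(all(sol$values[1:4] <= exp(-ref$sigma[1:4] * tau) + 1e-10))
  }
  # nested refinement never decreases an eigenvalue (min-max principle):
  # every 10-cell boundary is also a 20-cell boundary
  e20 <- qnorm(seq(0, 1, length.out = 21))
  for (tau in c(0.5, 1)) {
    l10 <- idealized_vac(ref, indicator_basis(e20[seq(1, 21, by = 2)]), tau)$values
    l20 <- idealized_vac(ref, indicator_basis(e20), tau)$values
    expect_true(all(l20[1:3] >= l10[1:3] - 1e-10))
  }
})

test_that("eigenfunction evaluation and implied timescales behave", {
  ref <- ou_reference()
  sol <- idealized_vac(ref, monomial_basis(rbind(0, 1)), 0.5)
  vals <- eigenfunction_values(sol, monomial_basis(rbind(0, 1)), ref$points)
  # second eigenfunction is x up to scale: correlation 1 in L2(mu)
  co <- sum(ref$mu * vals[, 2] * ref$points[, 1]) /
    sqrt(sum(ref$mu * vals[, 2]^2) * sum(ref$mu * ref$points[, 1]^2))
  expect_gt(abs(co), 0.999)
  expect_equal(implied_timescales(exp(-0.5), tau = 0.5), 1)
  expect_equal(implied_timescales(c(1, 1.2), tau = 0.5), c(Inf, Inf))
  expect_true(is.na(implied_timescales(-0.1, tau = 0.5)))
  expect_equal(implied_timescales(exp(-2 * 0.25), tau = 0.25), 0.5)
})

test_that("mean removal drops the trivial eigenfunction and shifts indices", {
  tr <- simulate_sde(make_ou1d(), 500, 0.05, sub_steps = 2, seed = 31)
  b <- ou_quantile_basis(10)
  sol_full <- solve_vac(empirical_correlations(tr, b, 0.5))
  bm <- set_basis_means(b, tr)
  sol_centered <- solve_vac(empirical_correlations(tr, bm, 0.5))
  expect_equal(sol_centered$rank, sol_full$rank - 1)
  # top centered eigenvalue estimates the first nontrivial mode
  expect_equal(sol_centered$values[1], sol_full$values[2], tolerance = 5e-3)
})
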