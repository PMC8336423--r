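test_that("benchmark models encode the stated potentials, drifts and diffusions", {
  ou <- make_ou1d()
  expect_equal(ou$a, matrix(2, 1, 1))
  expect_equal(drop(ou$drift(matrix(1))), -1)
  expect_equal(drop(ou$drift(matrix(0))), 0)

  dw <- make_doublewell2d()
  expect_equal(dw$a, matrix(c(4, -2, -2, 10), 2, 2))
  expect_equal(drop(dw$grad_potential(matrix(c(0, 0), 1, 2))), c(1, 0))
  expect_equal(drop(dw$drift(matrix(c(0, 0), 1, 2))), c(-2, 1))

  # reversible drift identity -(1/2) a grad U at random points, with the
  # gradient checked by central finite differences of the potential
  set.seed(1)
  for (model in list(ou, dw)) {
    x <- matrix(rnorm(model$dim * 5, sd = 0.8), 5, model$dim)
    h <- 1e-6
    g_fd <- vapply(seq_len(model$dim), function(d) {
      xp <- x; xm <- x
      xp[, d] <- xp[, d] + h; xm[, d] <- xm[, d] - h
      (model$potential(xp) - model$potential(xm)) / (2 * h)
    }, numeric(5))
    expect_equal(model$grad_potential(x), g_fd, tolerance = 1e-6)
    expect_equal(model$drift(x), -0.5 * g_fd %*% model$a, tolerance = 1e-6)
  }
})

test_that("noiseless and driftless limits integrate exactly", {
  decay <- sde_model(1, potential = function(x) 0.5 * x[, 1]^2,
                     grad_potential = function(x) x,
                     sigma = matrix(0, 1, 1), name = "decay",
                     drift = function(x) -x)
  tr <- simulate_sde(decay, total_time = 1, delta = 0.25, sub_steps = 250,
                     seed = 1, init = 1, burn_in = 0)
  expect_equal(tr$states[nrow(tr$states), 1], exp(-1), tolerance = 2e-3)

  frozen <- sde_model(1, potential = function(x) rep(0, nrow(x)),
                      grad_potential = function(x) 0 * x,
                      sigma = matrix(0, 1, 1), name = "frozen")
  tr2 <- simulate_sde(frozen, total_time = 2, delta = 0.5, sub_steps = 10,
                      seed = 1, init = 0.7, burn_in = 0)
  expect_true(all(tr2$states == 0.7))
})

test_that("simulation is reproducible and ensembles are vectorized faithfully", {
  ou <- make_ou1d()
  a <- simulate_sde(ou, 5, 0.1, sub_steps = 5, seed = 42)
  b <- simulate_sde(ou, 5, 0.1, sub_steps = 5, seed = 42)
  expect_identical(a$states, b$states)
  ens <- simulate_sde(ou, 5, 0.1, sub_steps = 5, seed = 42, n_paths = 3)
  expect_length(ens, 3)
  expect_false(identical(ens[[1]]$states, ens[[2]]$states))
})

test_that("simulated OU matches its analytic stationary law and autocorrelation", {
  ou <- make_ou1d()
  tr <- simulate_sde(ou, total_time = 3000, delta = 0.05, sub_steps = 5,
                     seed = 3)
  x <- tr$states[, 1]
  n <- length(x)
  # batch-means standard errors
  nb <- 30
  bm <- tapply(x^2, rep(seq_len(nb), each = ceiling(n / nb))[seq_len(n)], mean)
  se_var <- sd(bm) / sqrt(nb)
  expect_lt(abs(mean(x^2) - 1), 3 * se_var + 0.01)

  k <- round(1 / 0.05)
  prod_series <- x[seq_len(n - k)] * x[(k + 1):n]
  ac <- mean(prod_series) / mean(x^2)
  bmp <- tapply(prod_series, rep(seq_len(nb), each = ceiling((n - k) / nb))[seq_len(n - k)], mean)
  se_ac <- sd(bmp) / sqrt(nb)
  expect_lt(abs(ac - exp(-1)), 3 * se_ac + 0.01)

  # weak consistency: halving the internal step moves the lag-1
  # autocorrelation estimate by less than its Monte Carlo error
  tr2 <- simulate_sde(ou, total_time = 3000, delta = 0.05, sub_steps = 10,
                      seed = 3)
  y <- tr2$states[, 1]
  ac2 <- mean(y[seq_len(n - k)] * y[(k + 1):n]) / mean(y^2)
  expect_lt(abs(ac2 - ac), 3 * se_ac + 0.01)

  # distributional convergence: KS statistic against the standard normal
  # decreases with trajectory length
  ks_stat <- function(v) {
    v <- sort(v); m <- length(v)
    max(abs(pnorm(v) - seq_len(m) / m))
  }
  short <- simulate_sde(ou, total_time = 100, delta = 0.05, sub_steps = 5,
                        seed = 9)
  expect_lt(ks_stat(x), ks_stat(short$states[, 1]))
})

test_that("trajectory files round-trip", {
  tr <- simulate_sde(make_ou1d(), 2, 0.1, sub_steps = 2, seed = 5)
  f1 <- tempfile(fileext = ".rds"); f2 <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f1, "rds")
  expect_identical(read_trajectory(f1, "rds"), tr)   # lossless binary form
  write_trajectory(tr, f2, "tsv")
  back <- read_trajectory(f2, "tsv")
  expect_equal(back$states, tr$states, tolerance = 1e-12)
  expect_equal(back$delta, tr$delta)
  expect_equal(back$model_name, tr$model_name)
  unlink(c(f1, f2))
})

test_that("integration failure is reported with the failing step", {
  blowup <- sde_model(1, potential = function(x) -x[, 1]^4,
                      grad_potential = function(x) -4 * x^3,
                      sigma = matrix(0, 1, 1), name = "blowup",
                      drift = function(x) x^3)
  expect_error(
    simulate_sde(blowup, 50, 1, sub_steps = 10, seed = 1, init = 2,
                 burn_in = 0),
    "integration failure")
})
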