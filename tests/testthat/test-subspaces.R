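test_that("orthonormalization yields unit Gram and rejects rank deficiency", {
  set.seed(7)
  mu <- runif(12); mu <- mu / sum(mu)
  U <- function_subspace(matrix(rnorm(36), 12, 3), mu, "grid")
  On <- orthonormalize(U)
  G <- crossprod(On$basis, mu * On$basis)
  expect_lt(max(abs(G - diag(3))), 1e-10)
  expect_equal(as.numeric(projection_distance(U, On)), 0, tolerance = 1e-10)
  bad <- function_subspace(cbind(1:12, 2 * (1:12)), mu, "grid")
  expect_error(orthonormalize(bad), "rank-deficient")
})

test_that("subspace distances match identity and orthogonality cases", {
  mu <- rep(1 / 8, 8)
  U <- function_subspace(diag(8)[, 1:2], mu, "grid")
  # identical subspaces: zero up to the square root of matrix roundoff
  expect_lt(as.numeric(projection_distance(U, U)), 1e-7)
  expect_lt(as.numeric(gap_distance(U, U)), 1e-7)
  V1 <- function_subspace(diag(8)[, 1, drop = FALSE], mu, "grid")
  V2 <- function_subspace(diag(8)[, 2, drop = FALSE], mu, "grid")
  expect_equal(as.numeric(projection_distance(V1, V2)), 1)
  expect_equal(as.numeric(gap_distance(V1, V2)), 1)
})

test_that("distances agree with dense projectors and are basis-invariant", {
  set.seed(19)
  for (i in 1:20) {
    mu <- runif(10); mu <- mu / sum(mu)
    A <- matrix(rnorm(20), 10, 2)
    B <- matrix(rnorm(30), 10, 3)
    U <- function_subspace(A, mu, "grid")
    W <- function_subspace(B, mu, "grid")
    bf <- projector_distances(A, B, mu)
    expect_equal(as.numeric(projection_distance(U, W)), bf$dF, tolerance = 1e-10)
    expect_equal(as.numeric(gap_distance(U, W)), bf$d2, tolerance = 1e-10)
    expect_lte(as.numeric(gap_distance(U, W)),
               as.numeric(projection_distance(U, W)) + 1e-12)
    # invariance under invertible recombination of the spanning set
    R <- matrix(rnorm(4), 2, 2) + 2 * diag(2)
    U2 <- function_subspace(A %*% R, mu, "grid")
    expect_equal(as.numeric(projection_distance(U2, W)),
                 as.numeric(projection_distance(U, W)), tolerance = 1e-10)
    # symmetry at equal dimensions
    W2 <- function_subspace(B[, 1:2], mu, "grid")
    expect_equal(as.numeric(projection_distance(U, W2)),
                 as.numeric(projection_distance(W2, U)), tolerance = 1e-10)
  }
})

test_that("coordinate representations reproduce grid distances", {
  set.seed(23)
  mu <- runif(40); mu <- mu / sum(mu)
  Phi <- matrix(rnorm(40 * 5), 40, 5)           # basis functions on a grid
  Gram <- crossprod(Phi, mu * Phi)
  Cu <- matrix(rnorm(10), 5, 2); Cw <- matrix(rnorm(10), 5, 2)
  d_coord <- projection_distance(function_subspace(Cu, Gram, "coords"),
                                 function_subspace(Cw, Gram, "coords"))
  d_grid <- projection_distance(function_subspace(Phi %*% Cu, mu, "grid"),
                                function_subspace(Phi %*% Cw, mu, "grid"))
  expect_equal(as.numeric(d_coord), as.numeric(d_grid), tolerance = 1e-10)
  expect_error(projection_distance(function_subspace(Cu, Gram, "coords"),
                                   function_subspace(Phi %*% Cw, mu, "grid")),
               "incompatible")
})

test_that("excess dimensions are flagged and bounded below", {
  mu <- rep(1 / 9, 9)
  U <- function_subspace(diag(9)[, 1:4], mu, "grid")
  W <- function_subspace(diag(9)[, 3:4], mu, "grid")
  d <- projection_distance(U, W)
  expect_equal(attr(d, "excess_dim"), 2)
  expect_gte(as.numeric(d), sqrt(2) - 1e-12)
  expect_equal(as.numeric(gap_distance(U, W)), 1)
})

test_that("the error decomposition obeys the triangle inequality", {
  set.seed(29)
  mu <- runif(15); mu <- mu / sum(mu)
  for (i in 1:10) {
    est <- function_subspace(matrix(rnorm(45), 15, 3), mu, "grid")
    ideal <- function_subspace(matrix(rnorm(45), 15, 3), mu, "grid")
    truth <- function_subspace(matrix(rnorm(45), 15, 3), mu, "grid")
    ed <- error_decomposition(est, ideal, truth)
    expect_lte(ed$total, ed$approximation + ed$estimation + 1e-10)
  }
  same <- function_subspace(matrix(rnorm(45), 15, 3), mu, "grid")
  truth <- function_subspace(matrix(rnorm(45), 15, 3), mu, "grid")
  ed <- error_decomposition(same, same, truth)
  expect_equal(ed$estimation, 0, tolerance = 1e-10)
  expect_equal(ed$total, ed$approximation, tolerance = 1e-10)
})
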