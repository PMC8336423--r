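# Shared grid oracles, built lazily and cached for the whole test run.
.oracles <- new.env(parent = emptyenv())

ou_reference <- function() {
  if (is.null(.oracles$ou)) {
    gen <- discretize_generator(make_ou1d())
    .oracles$ou_gen <- gen
    .oracles$ou <- reference_spectrum(gen, r = length(gen$m), method = "dense")
  }
  .oracles$ou
}

ou_generator <- function() {
  ou_reference()
  .oracles$ou_gen
}

dw_reference <- function() {
  if (is.null(.oracles$dw)) {
    gen <- discretize_generator(make_doublewell2d())
    .oracles$dw_gen <- gen
    .oracles$dw <- reference_spectrum(gen, r = 150)
  }
  .oracles$dw
}

# equal-stationary-mass OU indicator partition (unbounded outer cells)
ou_quantile_basis <- function(n = 20, mean = 0)
  indicator_basis(qnorm(seq(0, 1, length.out = n + 1), mean = mean))

# dense-projector brute force for subspace distances: map grid functions to
# Euclidean coordinates z = sqrt(mu) * x, assemble explicit projectors
projector_distances <- function(U, W, mu) {
  qb <- function(X) qr.Q(qr(sqrt(mu) * X))
  Pu <- tcrossprod(qb(U))
  Pw <- tcrossprod(qb(W))
  M <- (diag(nrow(Pu)) - Pw) %*% Pu
  list(dF = norm(M, "F"), d2 = max(svd(M, nu = 0, nv = 0)$d))
}

# reversible 3-state Metropolis chain and its exact correlation matrices
make_chain <- function(pi = c(0.5, 0.3, 0.2)) {
  n <- length(pi)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) P[i, j] <- pmin(1, pi[j] / pi[i]) / n
  diag(P) <- 1 - rowSums(P)
  stopifnot(max(abs(pi %*% P - pi)) < 1e-12)
  list(P = P, pi = pi)
}

simulate_chain <- function(chain, n_steps, n_paths, seed) {
  set.seed(seed)
  cum <- t(apply(chain$P, 1, cumsum))
  s <- sample.int(length(chain$pi), n_paths, replace = TRUE, prob = chain$pi)
  out <- matrix(0L, n_steps, n_paths)
  for (t in seq_len(n_steps)) {
    u <- runif(n_paths)
    s <- 1L + (u > cum[s, 1]) + (u > cum[s, 2])
    out[t, ] <- s
  }
  out
}

chain_exact_corr <- function(chain, lag) {
  C0 <- diag(chain$pi)
  Pt <- diag(length(chain$pi))
  for (i in seq_len(lag)) Pt <- Pt %*% chain$P
  Ct <- diag(chain$pi) %*% Pt
  vacdiag:::new_correlation_pair(C0, (Ct + t(Ct)) / 2, tau = lag,
                                 source = "oracle")
}

chain_trajectory <- function(states_col)
  vacdiag:::new_trajectory(matrix(as.numeric(states_col), ncol = 1),
                           delta = 1, seed = NA, model_name = "chain3")

chain_basis <- function() indicator_basis(c(0.5, 1.5, 2.5, 3.5))
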