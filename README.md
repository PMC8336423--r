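# vacdiag

Spectral estimation for reversible dynamics — with the error analysis
built in.

## What problem this solves, and for whom

Simulation studies of molecular systems (and of stochastic dynamics
generally) need the functions of state that decorrelate most slowly: they
carry the conformational transitions, set the relaxation timescales, and
are the right coordinates for dimensionality reduction.  For an ergodic
process `X_t` that is reversible with respect to a stationary law μ, those
functions are the leading eigenfunctions η₁ = 1, η₂, η₃, … of the
self-adjoint transition operator

    T_τ f(x) = E[ f(X_τ) | X_0 = x ],      T_τ η_i = e^{-σ_i τ} η_i.

The *variational approach to conformational dynamics* (VAC) — the engine
behind Markov state models and time-lagged independent component analysis
— estimates them from trajectory data: pick basis functions φ₁…φ_n, form
the lagged correlation matrices

    Ĉ_ij(0) ≈ E_μ[φ_i(X_0) φ_j(X_0)],   Ĉ_ij(τ) ≈ E_μ[φ_i(X_0) φ_j(X_τ)],

and solve the generalized eigenproblem `Ĉ(τ) v = λ̂ Ĉ(0) v`.  The hard
part in practice is not the solve but knowing how wrong the answer is, and
that is what this package is for.  It implements, alongside the estimator:

* **the error decomposition** — total subspace error (projection distance
  `d_F` in L²(μ)) split into *approximation* error (basis limitation,
  computed against a grid-discretized generator oracle) and *estimation*
  error (finite data);
* **approximation-error bounds** — the Rayleigh–Ritz eigenvalue and
  subspace bounds, a sharp long-lag bound that stays finite as τ → ∞, and
  the lag-infinity limits (orthogonalized projections q_i and their
  overlaps);
* **estimation-error diagnostics computable from one trajectory** — the
  VAC condition number κ = 1/min{λ_{j−1}−λ_j, λ_k−λ_{k+1}} of a subspace,
  and a plug-in asymptotic root mean squared estimation error built from
  Bartlett long-run variances of the first-order loss series;
* **benchmark systems** — an Ornstein–Uhlenbeck process
  (`dX = −X dt + √2 dW`) and a 2-D double-well diffusion with correlated
  noise, each with a stationary Euler–Maruyama simulator and a
  finite-difference generator oracle (exact μ, spectra, and correlation
  matrices on a grid) for ground truth.

## A worked example

Estimate the top three eigenfunctions of the OU process from a single
stationary trajectory with a 20-state Markov-state-model basis, and ask
the diagnostics how much to trust them:

```r
library(vacdiag)

model <- make_ou1d()
traj  <- simulate_sde(model, total_time = 500, delta = 0.05,
                      sub_steps = 5, seed = 1)
basis <- indicator_basis(qnorm(seq(0, 1, length.out = 21)))  # equal-mass cells

sol <- solve_vac(empirical_correlations(traj, basis, tau = 0.5))
sol
#> VAC solution (empirical): tau = 0.5, rank 20 (0 dropped)
#>   leading eigenvalues: 1.00000 0.59260 0.37960 0.14740 0.06130 0.05141

implied_timescales(sol)[2:3]
#> [1] 0.9555 0.5162            # true OU timescales: 1 and 1/2

condition_number(sol, 1, 3)
#> [1] 4.3071                   # below ~5: subspace is estimable

asymptotic_mse(traj, basis, sol, 1, 3)
#> Plug-in estimation error at tau = 0.5 (T = 500, window = 96 frames)
#>   subspace root-MSE: 0.1436 (51 pairs, 0 excluded)
```

The eigenvalue estimates λ̂ = (1, 0.593, 0.380) sit near the true
e^{−σ τ} = (1, 0.607, 0.368); the implied timescales −τ/log λ̂ recover the
true relaxation times 1 and 0.5 to within a few percent; the condition
number says the top-3 span is well separated at this lag; and the plug-in
root-MSE (0.14) is the estimation error predicted *from this single
trajectory*.  Against the grid oracle the prediction checks out:

```r
gen <- discretize_generator(model)
ref <- reference_spectrum(gen, r = length(gen$m), method = "dense")
idl <- idealized_vac(ref, basis, 0.5)
H   <- function_subspace(ref$eta[, 1:3], ref$mu, "grid")
est <- function_subspace(evaluate_basis(basis, ref$points) %*% sol$vectors[, 1:3],
                         ref$mu, "grid")
error_decomposition(est, function_subspace(idl$gamma[, 1:3], ref$mu, "grid"), H)
#> $total 0.512   $approximation 0.423   $estimation 0.338

sharp_subspace_bound(ref, basis, tau = 0.5, k = 3)
#> sharp_subspace bound at tau = 0.5, k = 3: [1, 2.22738], observed 1.02252
```

The 20-cell basis carries an irreducible approximation error of 0.42 for
the 3-dimensional span (d_F ranges over [0, √3]); the measured estimation
error (0.34 for this realization) is of the size the plug-in diagnostic
predicted as a root mean square; and the observed approximation ratio
(1.02) respects the sharp bound (≤ 2.23).

The benchmark ensembles wrap all of this per lag time over 30 replicate
trajectories:

```r
ec <- run_ou_trial(1, seed = 1)   # n = 20 cells, T = 1e4, tau in 0.05..1.5
ec$tau_opt                        # lag minimizing RMS total error
threshold_crossing(ec, 0.2)       # where the calculated error reaches 0.2
```

A thin command-line front end covers the same operations
(`exec/vac fit|bounds|diagnose|experiment`, see the file header for
usage).

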