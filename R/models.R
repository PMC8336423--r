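#' Define a reversible diffusion model
#'
#' Constructs a model for the overdamped diffusion
#' \deqn{dX = -\tfrac12 \sigma\sigma^T \nabla U(X)\, dt + \sigma\, dW,}
#' whose stationary density is proportional to \eqn{e^{-U}} and whose
#' transition operator is self-adjoint in \eqn{L^2(\mu)} (detailed balance).
#'
#' @param dim state dimension.
#' @param potential function mapping an `n x dim` matrix of states to a
#'   length-`n` vector of energies `U(x)` (dimensionless).
#' @param grad_potential function mapping an `n x dim` matrix to the
#'   `n x dim` matrix of gradients of `U`.
#' @param sigma constant `dim x dim` diffusion factor; the diffusion matrix
#'   is `a = sigma %*% t(sigma)` and must be symmetric positive
#'   semidefinite.
#' @param name identifier used to pick default oracle grids and label
#'   trajectories.
#' @param sample_stationary optional function `n -> n x dim` matrix drawing
#'   exact stationary samples; used to initialize simulations without
#'   burn-in.
#' @param default_burn_in burn-in time (time units) discarded before
#'   recording when no exact stationary sampler is available.
#' @param init_point default starting state when neither a sampler nor an
#'   explicit initial condition is supplied.
#' @param drift optional override for the drift function (`n x dim` matrix
#'   in, `n x dim` matrix out).  By default the reversible drift
#'   `-(1/2) a grad U` is used; an override is useful for deterministic
#'   test flows and breaks the reversibility guarantee.
#'
#' @return an object of class `"sde_model"`.
#' @seealso [make_ou1d()], [make_doublewell2d()], [simulate_sde()]
#' @export
sde_model <- function(dim, potential, grad_potential, sigma, name,
                      sample_stationary = NULL, default_burn_in = 0,
                      init_point = rep(0, dim), drift = NULL) {
  sigma <- as.matrix(sigma)
  stopifnot(is.numeric(dim), dim >= 1, nrow(sigma) == dim, ncol(sigma) == dim)
  a <- sigma %*% t(sigma)
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1))
    stop("sigma %*% t(sigma) must be positive semidefinite")
  if (is.null(drift)) {
    drift <- function(x) -0.5 * (grad_potential(x) %*% a)
  }
  structure(list(dim = as.integer(dim), potential = potential,
                 grad_potential = grad_potential, sigma = sigma, a = a,
                 drift = drift, name = name,
                 sample_stationary = sample_stationary,
                 default_burn_in = default_burn_in,
                 init_point = init_point),
            class = "sde_model")
}

#' @export
print.sde_model <- function(x, ...) {
  cat("Reversible diffusion model:", x$name, "\n")
  cat("  dimension:", x$dim, "\n")
  cat("  diffusion matrix a = sigma sigma^T:\n")
  print(x$a)
  invisible(x)
}

#' One-dimensional Ornstein--Uhlenbeck model
#'
#' The process \eqn{dX = -X\,dt + \sqrt{2}\,dW}, i.e. potential
#' \eqn{U(x) = x^2/2} with diffusion factor \eqn{\sqrt 2}.  Its stationary
#' law is the standard normal and the generator spectrum is
#' \eqn{\sigma_i = i - 1} with Hermite-polynomial eigenfunctions, which
#' makes it the canonical analytically tractable benchmark.
#'
#' @return an `"sde_model"` with an exact stationary sampler.
#' @export
make_ou1d <- function() {
  sde_model(
    dim = 1,
    potential = function(x) 0.5 * x[, 1]^2,
    grad_potential = function(x) x,
    sigma = matrix(sqrt(2), 1, 1),
    name = "ou1d",
    sample_stationary = function(n) matrix(rnorm(n), n, 1)
  )
}

#' Two-dimensional double-well diffusion model
#'
#' The benchmark diffusion with potential
#' \deqn{U(x_1, x_2) = 4x_1^4 - 8x_1^2 + x_1 + 0.5\,x_2^2}
#' and diffusion factor `sigma = rbind(c(2, 0), c(-1, 3))`, so that
#' `a = sigma sigma^T = rbind(c(4, -2), c(-2, 10))`.  The tilted double
#' well in `x_1` creates one slow barrier-crossing mode well separated
#' from all faster relaxations.
#'
#' @return an `"sde_model"`; simulations use a burn-in (default 50 time
#'   units) from the deeper well since no exact stationary sampler exists.
#' @export
make_doublewell2d <- function() {
  sde_model(
    dim = 2,
    potential = function(x) 4 * x[, 1]^4 - 8 * x[, 1]^2 + x[, 1] + 0.5 * x[, 2]^2,
    grad_potential = function(x)
      cbind(16 * x[, 1]^3 - 16 * x[, 1] + 1, x[, 2]),
    sigma = matrix(c(2, 0, -1, 3), 2, 2, byrow = TRUE),
    name = "doublewell2d",
    default_burn_in = 50,
    init_point = c(-1, 0)
  )
}

new_trajectory <- function(states, delta, seed, model_name,
                           burn_in_discarded = 0, replicate = 1L) {
  states <- as.matrix(states)
  stopifnot(delta > 0, nrow(states) >= 2)
  if (!all(is.finite(states))) stop("trajectory contains non-finite states")
  structure(list(states = states, delta = delta, seed = seed,
                 model_name = model_name,
                 burn_in_discarded = burn_in_discarded,
                 replicate = as.integer(replicate)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of '%s': %d frames x %d dims, delta = %g (T = %g), seed = %s\n",
              x$model_name, nrow(x$states), ncol(x$states), x$delta,
              nrow(x$states) * x$delta, format(x$seed)))
  invisible(x)
}

#' Simulate stationary trajectories of a reversible diffusion
#'
#' Euler--Maruyama integration with internal step `delta / sub_steps`.
#' Frames are recorded every `delta` time units after the burn-in is
#' discarded.  When `n_paths > 1` all paths are advanced jointly
#' (vectorized over the ensemble) and a list of trajectories is returned;
#' a given `(seed, n_paths)` pair is bit-reproducible.
#'
#' @param model an `"sde_model"`.
#' @param total_time recorded trajectory length `T` (time units).
#' @param delta sampling interval between recorded frames.
#' @param sub_steps number of internal Euler--Maruyama steps per frame
#'   (integer >= 1).  Default targets an internal step of 1e-3.
#' @param seed integer seed (mandatory); `"auto"` draws one from entropy
#'   and reports it.
#' @param burn_in time discarded before recording.  Defaults to 0 when the
#'   model has an exact stationary sampler, else to the model's
#'   `default_burn_in`.
#' @param n_paths number of independent replicate paths.
#' @param init optional `n_paths x dim` matrix of initial states.
#'
#' @return a `"trajectory"` (if `n_paths == 1`) or a list of trajectories.
#' @export
simulate_sde <- function(model, total_time, delta, sub_steps = NULL,
                         seed, burn_in = NULL, n_paths = 1, init = NULL) {
  stopifnot(inherits(model, "sde_model"), total_time > 0, delta > 0)
  if (is.null(sub_steps)) sub_steps <- max(1L, as.integer(round(delta / 1e-3)))
  sub_steps <- as.integer(sub_steps)
  stopifnot(sub_steps >= 1)
  if (identical(seed, "auto")) {
    seed <- sample.int(.Machine$integer.max, 1)
    message("simulate_sde: drew seed ", seed, " from entropy")
  }
  set.seed(seed)
  h <- delta / sub_steps
  sqh <- sqrt(h)
  d <- model$dim
  sig_t <- t(model$sigma)
  if (is.null(init)) {
    if (!is.null(model$sample_stationary)) {
      init <- model$sample_stationary(n_paths)
      if (is.null(burn_in)) burn_in <- 0
    } else {
      init <- matrix(rep(model$init_point, each = n_paths), n_paths, d)
      if (is.null(burn_in)) burn_in <- model$default_burn_in
    }
  } else {
    init <- matrix(init, n_paths, d)
    if (is.null(burn_in)) burn_in <- 0
  }
  S <- init
  step <- function(S) S + h * model$drift(S) +
    sqh * (matrix(rnorm(n_paths * d), n_paths, d) %*% sig_t)
  n_burn <- as.integer(round(burn_in / h))
  for (i in seq_len(n_burn)) S <- step(S)
  if (!all(is.finite(S)))
    stop("integration failure: non-finite state during burn-in")
  n_frames <- as.integer(floor(total_time / delta + 1e-9))
  if (n_frames < 2) stop("total_time must cover at least 2 frames")
  out <- array(0, dim = c(n_frames, n_paths, d))
  for (f in seq_len(n_frames)) {
    for (s in seq_len(sub_steps)) S <- step(S)
    if (!all(is.finite(S)))
      stop(sprintf("integration failure: non-finite state at frame %d (t = %g)",
                   f, f * delta))
    out[f, , ] <- S
  }
  trajs <- lapply(seq_len(n_paths), function(p)
    new_trajectory(matrix(out[, p, ], n_frames, d), delta, seed,
                   model$name, burn_in_discarded = burn_in, replicate = p))
  if (n_paths == 1) trajs[[1]] else trajs
}

#' Write / read a trajectory
#'
#' `format = "tsv"` stores one frame per row in delimited text with a
#' header comment carrying the sampling interval, model name and seed.
#' `format = "rds"` stores the full object losslessly in R's binary
#' serialization.
#'
#' @param traj a `"trajectory"`.
#' @param file path.
#' @param format `"tsv"` or `"rds"`.
#' @return `write_trajectory` returns `file` invisibly; `read_trajectory`
#'   returns the `"trajectory"`.
#' @export
write_trajectory <- function(traj, file, format = c("tsv", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "trajectory"))
  if (format == "rds") {
    saveRDS(traj, file)
  } else {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("# vacdiag trajectory delta=%.17g model=%s seed=%s burn_in=%.17g replicate=%d",
                       traj$delta, traj$model_name, format(traj$seed),
                       traj$burn_in_discarded, traj$replicate), con)
    write.table(traj$states, con, sep = "\t", row.names = FALSE,
                col.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(file))
  hdr <- readLines(file, n = 1)
  if (!startsWith(hdr, "# vacdiag trajectory"))
    stop("not a vacdiag trajectory file: ", file)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  states <- as.matrix(read.table(file, sep = "\t", comment.char = "#"))
  dimnames(states) <- NULL
  new_trajectory(states, as.numeric(vals[["delta"]]),
                 suppressWarnings(as.integer(vals[["seed"]])),
                 vals[["model"]],
                 burn_in_discarded = as.numeric(vals[["burn_in"]]),
                 replicate = as.integer(vals[["replicate"]]))
}
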