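# Approximate fixed points of the noise-free update map F(h, u*) for a frozen
# task-period input u*, their Jacobian linearization, and stability labels.

#' Residual of a candidate fixed point
#'
#' `q = 0.5 * ||h - F(h, u)||^2` where `F` is the noise-free discrete update.
#'
#' @param params `network_params`.
#' @param h State vector (or matrix of column states).
#' @param u Frozen input vector.
#' @return Numeric residual(s), one per column of `h`.
#' @export
fp_residual <- function(params, h, u) {
  h <- as.matrix(h)
  r <- h - update_map(h, matrix(u, length(u), ncol(h)), params)
  0.5 * colSums(r^2)
}

# analytic gradient of q wrt h: (I - J_F)^T (h - F(h,u))
# with J_F = (1-gamma) I + gamma diag(sigma'(i)) W_rec this reduces to
# gamma * (r - W_rec^T (sigma'(i) * r))
fp_residual_grad <- function(params, h, u) {
  i <- drop(params$W_rec %*% h + params$W_in %*% u + params$b_in)
  f <- (1 - params$gamma) * h + params$gamma *
    activation_fn(params$activation, i)
  r <- h - f
  g <- params$gamma * (r - drop(crossprod(params$W_rec,
                                          activation_fn(params$activation, i,
                                                        deriv = TRUE) * r)))
  list(q = 0.5 * sum(r^2), grad = g)
}

#' Jacobian of the discrete update at a state
#'
#' `J = (1 - gamma) I + gamma diag(sigma'(i)) W_rec` evaluated at
#' `i = W_rec h + W_in u + b_in`.
#'
#' @inheritParams fp_residual
#' @return \[n_rec x n_rec\] matrix.
#' @export
fp_jacobian <- function(params, h, u) {
  i <- drop(params$W_rec %*% h + params$W_in %*% u + params$b_in)
  dphi <- activation_fn(params$activation, i, deriv = TRUE)
  (1 - params$gamma) * diag(params$n_rec) +
    params$gamma * (dphi * params$W_rec)
}

MARGINAL_BAND <- 0.01

#' Linearize a fixed point and classify its stability
#'
#' Attaches the eigenvalues of the discrete-update Jacobian at
#' `(h_star, u_star)`. Classification uses the maximum real part against the
#' discrete stability threshold 1: `unstable` if any eigenvalue has real part
#' above `1 + marginal_band`, `marginal` if the largest real part lies within
#' the band around 1, `stable` otherwise. The spectral radius is stored as a
#' diagnostic alongside the real-part criterion.
#'
#' @param params `network_params`.
#' @param fp A `fixed_point` (or a list with `h_star`, `u_star`).
#' @param marginal_band Half-width of the marginal band around 1.
#' @return The `fixed_point` with `jacobian_eigs`, `max_re`, `spectral_radius`,
#'   `n_unstable`, `n_marginal` and `stability` filled in.
#' @export
linearize_and_classify <- function(params, fp, marginal_band = MARGINAL_BAND) {
  J <- fp_jacobian(params, fp$h_star, fp$u_star)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  fp$jacobian_eigs <- ev
  fp$max_re <- max(re)
  fp$spectral_radius <- max(Mod(ev))
  fp$n_unstable <- sum(re > 1 + marginal_band)
  fp$n_marginal <- sum(abs(re - 1) <= marginal_band)
  fp$stability <- if (fp$n_unstable > 0) "unstable"
                  else if (fp$n_marginal > 0) "marginal"
                  else "stable"
  fp
}

new_fixed_point <- function(h_star, u_star, q, source = NA_character_) {
  structure(list(h_star = h_star, u_star = u_star, q = q,
                 jacobian_eigs = NULL, stability = NA_character_,
                 n_unstable = NA_integer_, source = source),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("<fixed_point> q=%.3g stability=%s max Re(eig)=%s\n",
              x$q, x$stability,
              if (is.null(x$jacobian_eigs)) "?" else sprintf("%.4f", x$max_re)))
  invisible(x)
}

#' Locate approximate fixed points for a frozen input
#'
#' Minimizes the residual `q(h) = 0.5 ||h - F(h, u_star)||^2` from each seed
#' state by gradient-based descent (L-BFGS-B with the analytic gradient),
#' keeps converged points with `q <= tol_q`, deduplicates points closer than
#' `dedup_eps` (keeping the lower-q member), and attaches the Jacobian
#' eigen-structure of every retained point.
#'
#' @param params `network_params`.
#' @param u_star Frozen input vector (length 20).
#' @param seed_states Matrix \[n_rec x n_seeds\] of optimization starts,
#'   typically sampled from trajectories under `u_star`.
#' @param tol_q Acceptance tolerance on the residual (default 1e-3; use 1e-8
#'   for the high-quality tier).
#' @param max_iter Iteration cap per seed.
#' @param dedup_eps Merge radius; default `1e-2 * sqrt(n_rec)`.
#' @return List of `fixed_point` objects sorted by increasing `q` (may be
#'   empty, with a warning, if no seed converges). The sorted residuals of
#'   every optimization run, accepted or not, are attached as attribute
#'   `candidate_q`.
#' @export
find_fixed_points <- function(params, u_star, seed_states, tol_q = 1e-3,
                              max_iter = 500, dedup_eps = NULL) {
  check_params(params)
  seed_states <- as.matrix(seed_states)
  if (is.null(dedup_eps)) dedup_eps <- 1e-2 * sqrt(params$n_rec)
  pts <- list()
  candidate_q <- numeric(ncol(seed_states))
  for (s in seq_len(ncol(seed_states))) {
    opt <- optim(seed_states[, s],
                 fn = function(h) fp_residual_grad(params, h, u_star)$q,
                 gr = function(h) fp_residual_grad(params, h, u_star)$grad,
                 method = "L-BFGS-B",
                 control = list(maxit = max_iter, factr = 10))
    candidate_q[s] <- opt$value
    if (opt$value <= tol_q)
      pts[[length(pts) + 1L]] <- new_fixed_point(opt$par, u_star, opt$value,
                                                 source = sprintf("seed%d", s))
  }
  if (!length(pts)) {
    warning("no fixed-point candidate reached tol_q = ", tol_q)
    return(structure(list(), candidate_q = sort(candidate_q)))
  }
  pts <- pts[order(vapply(pts, `[[`, numeric(1), "q"))]
  kept <- list()
  for (p in pts) {
    dup <- any(vapply(kept, function(k)
      sqrt(sum((k$h_star - p$h_star)^2)) < dedup_eps, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- p
  }
  structure(lapply(kept, function(p) linearize_and_classify(params, p)),
            candidate_q = sort(candidate_q))
}

#' Seed states for fixed-point searches
#'
#' Runs noise-free trials over a condition grid, pools the states inside the
#' requested period, and returns `n_seeds` of them (uniformly subsampled)
#' with small Gaussian jitter.
#'
#' @param params `network_params`.
#' @param task Task name.
#' @param period Period name.
#' @param n_seeds Number of seed states.
#' @param n_angles Condition-grid resolution.
#' @param jitter_sd Jitter scale.
#' @param dt_ms Timestep in ms.
#' @return Matrix \[n_rec x n_seeds\].
#' @export
sample_seed_states <- function(params, task, period, n_seeds = 128,
                               n_angles = 16, jitter_sd = 0.01, dt_ms = 20) {
  spec <- get_task(task)
  if (!period %in% spec$period_sequence)
    stop("task ", spec$name, " has no period ", period)
  grid <- condition_grid(task, n_angles)
  batch <- make_batch(task, length(grid), conditions = grid, noise_on = FALSE,
                      dt_ms = dt_ms, fixed_durations = TRUE)
  traj <- run_batch(params, batch, noise_on = FALSE)
  pb <- batch$period_bounds[[1]] # fixed durations: same bounds for all trials
  ps <- pb$start[pb$period == period]
  pe <- pb$end[pb$period == period]
  pool <- matrix(aperm(traj$states[ps:pe, , , drop = FALSE], c(3, 1, 2)),
                 nrow = params$n_rec)
  idx <- round(seq(1, ncol(pool), length.out = min(n_seeds, ncol(pool))))
  seeds <- pool[, idx, drop = FALSE]
  seeds + matrix(rnorm(length(seeds), sd = jitter_sd), nrow(seeds))
}

#' Fixed points of one task period
#'
#' Convenience driver: builds the frozen period input for a reference
#' condition, seeds from noise-free trajectories across the condition grid,
#' and runs [find_fixed_points()].
#'
#' @inheritParams sample_seed_states
#' @param condition Reference `trial_condition` for the frozen input
#'   (default: first grid condition).
#' @param tol_q,n_seeds Passed to [find_fixed_points()] / seeding.
#' @param ... Passed to [find_fixed_points()].
#' @return List of `fixed_point`s.
#' @export
task_fixed_points <- function(params, task, period, condition = NULL,
                              tol_q = 1e-3, n_seeds = 128, n_angles = 16,
                              dt_ms = 20, ...) {
  if (is.null(condition)) condition <- condition_grid(task, n_angles)[[1]]
  u_star <- period_input(task, period, condition)
  seeds <- sample_seed_states(params, task, period, n_seeds, n_angles,
                              dt_ms = dt_ms)
  find_fixed_points(params, u_star, seeds, tol_q = tol_q, ...)
}
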