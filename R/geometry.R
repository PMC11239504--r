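# State-space geometry: PCA cross-projection variance between task periods,
# end-of-context distance versus stimulus-onset trajectory angle, and the
# effective (context-modulated) input response at a fixed point.

# flatten a [time x cond x unit] slab to samples x units
period_samples <- function(traj, period) {
  batch <- traj$source_batch
  pb <- batch$period_bounds[[1]]
  stopifnot(period %in% pb$period)
  sl <- traj$states[pb$start[pb$period == period]:pb$end[pb$period == period],
                    , , drop = FALSE]
  matrix(sl, ncol = dim(traj$states)[3])
}

#' Fraction of one trajectory's variance explained by another's PCs
#'
#' Centers each sample set by its own mean, computes the top-k principal
#' axes of B, and reports the fraction of A's total variance captured by
#' projecting A onto B's axes -- alongside the fraction captured by A's own
#' top-k axes (always at least as large).
#'
#' @param samples_a,samples_b Matrices \[samples x units\] (e.g. from a task
#'   period's states across a condition grid).
#' @param k Number of principal components.
#' @return A `subspace_report`: `own_fraction`, `foreign_fraction`, `k`,
#'   `rank_limited` flag.
#' @export
pca_cross_projection <- function(samples_a, samples_b, k = 2) {
  a <- scale(samples_a, center = TRUE, scale = FALSE)
  b <- scale(samples_b, center = TRUE, scale = FALSE)
  if (k > ncol(a)) stop("k exceeds the state dimension")
  sv_b <- svd(b, nu = 0, nv = min(k, ncol(b)))
  sv_a <- svd(a, nu = 0, nv = min(k, ncol(a)))
  rank_b <- sum(sv_b$d > 1e-12 * sv_b$d[1])
  total_a <- sum(a^2)
  if (total_a == 0) stop("degenerate (constant) trajectory A")
  foreign <- sum((a %*% sv_b$v)^2) / total_a
  own <- sum((a %*% sv_a$v)^2) / total_a
  structure(list(own_fraction = own, foreign_fraction = foreign, k = k,
                 rank_limited = rank_b < k),
            class = "subspace_report")
}

#' @export
print.subspace_report <- function(x, ...) {
  cat(sprintf("<subspace_report> k=%d own=%.3f foreign=%.3f%s\n", x$k,
              x$own_fraction, x$foreign_fraction,
              if (x$rank_limited) " (rank-limited)" else ""))
  invisible(x)
}

#' End-of-context distance and stimulus-onset angle between two tasks
#'
#' Runs matched noise-free trials (same stimulus angle theta, deterministic
#' durations) for both tasks. Reports the Euclidean distance between the two
#' end-of-context states, and the cosine of the angle between the two tasks'
#' first state-update vectors at stimulus onset (`h(t0+1) - h(t0)`), averaged
#' over the theta grid. Related tasks sit close after context and launch
#' their stimulus responses in similar directions.
#'
#' @param params `network_params`.
#' @param task_a,task_b Task names.
#' @param n_angles Number of matched stimulus angles.
#' @param dt_ms Timestep in ms.
#' @return List with `distance` (mean end-of-context distance) and `cosine`
#'   (mean cosine angle between onset updates).
#' @export
context_distance_angle <- function(params, task_a, task_b, n_angles = 8,
                                   dt_ms = 20) {
  onset_info <- function(task, theta) {
    spec <- get_task(task)
    grid <- condition_grid(task, n_angles)
    cond <- grid[[which.min(abs(vapply(grid, `[[`, numeric(1),
                                       "theta_stim1") - theta))]]
    cond$durations <- sample_period_durations(spec, dt_ms, fixed = TRUE)
    b <- make_batch(task, 1L, conditions = list(cond), noise_on = FALSE,
                    dt_ms = dt_ms)
    traj <- run_batch(params, b, noise_on = FALSE)
    pb <- b$period_bounds[[1]]
    t0 <- pb$end[pb$period == "context"]
    list(h_end = traj$states[t0, 1, ],
         update = traj$states[t0 + 1, 1, ] - traj$states[t0, 1, ])
  }
  thetas <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  dists <- numeric(n_angles); cosv <- numeric(n_angles)
  for (j in seq_along(thetas)) {
    ia <- onset_info(task_a, thetas[j])
    ib <- onset_info(task_b, thetas[j])
    dists[j] <- sqrt(sum((ia$h_end - ib$h_end)^2))
    na_ <- sqrt(sum(ia$update^2)); nb_ <- sqrt(sum(ib$update^2))
    cosv[j] <- if (na_ == 0 || nb_ == 0) NA
               else sum(ia$update * ib$update) / (na_ * nb_)
  }
  list(distance = mean(dists), cosine = mean(cosv, na.rm = TRUE),
       per_theta = data.frame(theta = thetas, distance = dists,
                              cosine = cosv))
}

#' Effective input response at a context fixed point
#'
#' Magnitude of the first-order state response to an input change `delta_u`
#' applied at a fixed point: `|| dF/du (h*, u*) . delta_u ||_2` with
#' `dF/du = gamma diag(sigma'(i*)) W_in`. Used to quantify contextual
#' amplification of stimulus inputs.
#'
#' @param params `network_params`.
#' @param h_context Fixed-point state under the context input.
#' @param u_context Context-period input vector.
#' @param delta_u Input perturbation (e.g. `u_stimulus - u_context`).
#' @param q_tol Warn if `h_context` is not a fixed point at this tolerance.
#' @return Scalar response norm.
#' @export
effective_input_response <- function(params, h_context, u_context, delta_u,
                                     q_tol = 1e-3) {
  q <- fp_residual(params, h_context, u_context)
  if (q > q_tol)
    warning(sprintf("h_context is not a fixed point at tolerance %g (q=%.3g)",
                    q_tol, q))
  i <- drop(params$W_rec %*% h_context + params$W_in %*% u_context +
              params$b_in)
  dphi <- activation_fn(params$activation, i, deriv = TRUE)
  sqrt(sum((params$gamma * dphi * drop(params$W_in %*% delta_u))^2))
}
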