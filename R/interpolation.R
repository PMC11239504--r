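# Input interpolation: track the task-relevant fixed point along a convex
# sweep between two input conditions and decide whether the underlying
# dynamical motif is shared or bifurcates.

#' Evenly spaced convex combinations of two inputs
#'
#' @param u1,u2 Input vectors of equal length.
#' @param n Number of grid points including both endpoints (default 21,
#'   i.e. alpha steps of 0.05).
#' @return Matrix \[length(u) x n\]; column j is `(1-alpha_j) u1 + alpha_j u2`.
#' @export
interpolate_inputs <- function(u1, u2, n = 21) {
  if (length(u1) != length(u2)) stop("u1 and u2 must have the same length")
  if (n < 2) stop("need at least the two endpoints")
  alpha <- seq(0, 1, length.out = n)
  vapply(alpha, function(a) (1 - a) * u1 + a * u2, numeric(length(u1)))
}

#' Track the relevant fixed point across interpolated inputs
#'
#' For each alpha on the grid, freezes the interpolated input, solves for
#' fixed points (seeded from a noise-free trajectory run from the start of
#' the context period under that same interpolated rule input), and selects
#' the fixed point nearest (Euclidean) to the network state at the end of
#' the period of interest -- or the nearest unstable one when
#' `selection_mode = "closest_unstable"`. Consecutive distances between
#' relevant fixed points and each point's maximum real Jacobian eigenvalue
#' are recorded, then [detect_bifurcation()] issues the verdict.
#'
#' @param params `network_params`.
#' @param task_a,task_b The two task names whose rule inputs are swept.
#' @param period Period of interest (must exist in both tasks).
#' @param selection_mode `"closest"` or `"closest_unstable"`.
#' @param n_alpha Grid size including endpoints.
#' @param condition Reference `trial_condition` (defaults to the first
#'   condition-grid entry of `task_a`).
#' @param tol_q,n_seeds Fixed-point solver settings.
#' @param jump_factor Passed to [detect_bifurcation()].
#' @param dt_ms Timestep in ms.
#' @return An `interpolation_result` with `alpha_grid`, `relevant_fps`,
#'   `consecutive_distances`, `max_re_per_alpha`, `stability_per_alpha`,
#'   `verdict` and `verdict_evidence`.
#' @export
track_relevant_fp <- function(params, task_a, task_b, period,
                              selection_mode = c("closest",
                                                 "closest_unstable"),
                              n_alpha = 21, condition = NULL,
                              tol_q = 1e-3, n_seeds = 48, jump_factor = 10,
                              dt_ms = 20) {
  selection_mode <- match.arg(selection_mode)
  spec_a <- get_task(task_a); spec_b <- get_task(task_b)
  stopifnot(period %in% spec_a$period_sequence,
            period %in% spec_b$period_sequence)
  if (is.null(condition)) condition <- condition_grid(task_a, 8)[[1]]
  u1 <- period_input(task_a, period, condition)
  u2 <- period_input(task_b, period, condition)
  ugrid <- interpolate_inputs(u1, u2, n_alpha)
  alpha <- seq(0, 1, length.out = n_alpha)

  # template trial of task_a with deterministic durations; its input array is
  # re-written with the interpolated rule mixture at every alpha
  cn <- condition
  cn$durations <- sample_period_durations(spec_a, dt_ms, fixed = TRUE)
  base <- make_batch(task_a, 1L, conditions = list(cn), noise_on = FALSE,
                     dt_ms = dt_ms)
  pb <- base$period_bounds[[1]]
  pe <- pb$end[pb$period == period]
  rule_mix_a <- ugrid[CH_RULE, , drop = FALSE]

  fps <- vector("list", n_alpha)
  incomplete <- FALSE
  for (j in seq_len(n_alpha)) {
    bj <- base
    bj$inputs[, 1, CH_RULE] <-
      matrix(rule_mix_a[, j], nrow(bj$inputs), N_RULE, byrow = TRUE)
    traj <- run_batch(params, bj, noise_on = FALSE)
    h_end <- traj$states[pe, 1, ]
    idx <- round(seq(1, pe, length.out = min(n_seeds - 1, pe)))
    seeds <- cbind(t(traj$states[idx, 1, , drop = TRUE]), h_end)
    cand <- suppressWarnings(
      find_fixed_points(params, ugrid[, j], seeds, tol_q = tol_q))
    if (!length(cand)) { incomplete <- TRUE; fps[j] <- list(NULL); next }
    pool <- if (selection_mode == "closest_unstable") {
      un <- Filter(function(f) f$stability == "unstable", cand)
      if (length(un)) un else cand
    } else cand
    d2 <- vapply(pool, function(f) sum((f$h_star - h_end)^2), numeric(1))
    fps[[j]] <- pool[[which.min(d2)]]
  }

  dists <- rep(NA_real_, n_alpha - 1)
  for (j in seq_len(n_alpha - 1)) {
    if (!is.null(fps[[j]]) && !is.null(fps[[j + 1]]))
      dists[j] <- sqrt(sum((fps[[j]]$h_star - fps[[j + 1]]$h_star)^2))
  }
  res <- structure(
    list(alpha_grid = alpha, u_endpoints = list(u1 = u1, u2 = u2),
         relevant_fps = fps, consecutive_distances = dists,
         max_re_per_alpha = vapply(fps, function(f)
           if (is.null(f)) NA_real_ else f$max_re, numeric(1)),
         stability_per_alpha = vapply(fps, function(f)
           if (is.null(f)) NA_character_ else f$stability, character(1)),
         selection_mode = selection_mode,
         task_pair = c(get_task(task_a)$name, get_task(task_b)$name),
         period = period, incomplete = incomplete,
         verdict = NA_character_, verdict_evidence = NULL),
    class = "interpolation_result")
  detect_bifurcation(res, jump_factor = jump_factor)
}

#' Decide shared motif versus bifurcation
#'
#' Verdict is `"bifurcation"` iff the largest consecutive distance between
#' relevant fixed points exceeds `jump_factor` times the median consecutive
#' distance, or the stability class of the relevant point changes anywhere
#' along the grid; otherwise `"shared"`.
#'
#' @param result An `interpolation_result`.
#' @param jump_factor Distance-jump multiplier (default 10).
#' @return The result with `verdict` and `verdict_evidence` filled.
#' @export
detect_bifurcation <- function(result, jump_factor = 10) {
  stopifnot(inherits(result, "interpolation_result"))
  if (length(result$alpha_grid) < 3) stop("degenerate interpolation grid")
  d <- result$consecutive_distances
  st <- result$stability_per_alpha
  d_ok <- d[!is.na(d)]
  med <- stats::median(d_ok)
  jump <- length(d_ok) > 0 && max(d_ok) > jump_factor * max(med, 1e-12)
  st_ok <- st[!is.na(st)]
  st_change <- length(unique(st_ok)) > 1
  result$verdict <- if (jump || st_change) "bifurcation" else "shared"
  result$verdict_evidence <- list(max_jump = if (length(d_ok)) max(d_ok) else NA,
                                  median_distance = med,
                                  jump_factor = jump_factor,
                                  distance_jump = jump,
                                  stability_change = st_change,
                                  stability_classes = unique(st_ok))
  result
}

#' @export
print.interpolation_result <- function(x, ...) {
  cat(sprintf(
    "<interpolation_result> %s <-> %s (%s, %s): %s (max jump %.3g, med %.3g)\n",
    x$task_pair[1], x$task_pair[2], x$period, x$selection_mode, x$verdict,
    x$verdict_evidence$max_jump, x$verdict_evidence$median_distance))
  invisible(x)
}

#' Track fixed points along an explicit input sweep
#'
#' Lower-level variant of [track_relevant_fp()] for arbitrary (not task-
#' derived) systems: takes precomputed input columns and seed states and
#' selects at each input the fixed point nearest `ref_state`.
#'
#' @param params `network_params`.
#' @param ugrid Matrix of inputs, one column per interpolation step.
#' @param seed_states Seed matrix passed to every solve.
#' @param ref_state State used for the relevance (nearest) selection.
#' @param tol_q Solver tolerance.
#' @param jump_factor Passed to [detect_bifurcation()].
#' @return An `interpolation_result`.
#' @export
track_fp_over_inputs <- function(params, ugrid, seed_states, ref_state,
                                 tol_q = 1e-6, jump_factor = 10) {
  n <- ncol(ugrid)
  fps <- vector("list", n)
  incomplete <- FALSE
  for (j in seq_len(n)) {
    cand <- suppressWarnings(
      find_fixed_points(params, ugrid[, j], seed_states, tol_q = tol_q))
    if (!length(cand)) { incomplete <- TRUE; fps[j] <- list(NULL); next }
    d2 <- vapply(cand, function(f) sum((f$h_star - ref_state)^2), numeric(1))
    fps[[j]] <- cand[[which.min(d2)]]
  }
  dists <- rep(NA_real_, n - 1)
  for (j in seq_len(n - 1))
    if (!is.null(fps[[j]]) && !is.null(fps[[j + 1]]))
      dists[j] <- sqrt(sum((fps[[j]]$h_star - fps[[j + 1]]$h_star)^2))
  res <- structure(
    list(alpha_grid = seq(0, 1, length.out = n),
         u_endpoints = list(u1 = ugrid[, 1], u2 = ugrid[, n]),
         relevant_fps = fps, consecutive_distances = dists,
         max_re_per_alpha = vapply(fps, function(f)
           if (is.null(f)) NA_real_ else f$max_re, numeric(1)),
         stability_per_alpha = vapply(fps, function(f)
           if (is.null(f)) NA_character_ else f$stability, character(1)),
         selection_mode = "closest", task_pair = c(NA, NA), period = NA,
         incomplete = incomplete, verdict = NA_character_,
         verdict_evidence = NULL),
    class = "interpolation_result")
  detect_bifurcation(res, jump_factor = jump_factor)
}
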