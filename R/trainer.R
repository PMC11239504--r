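# Masked squared-error training of the leaky RNN with Adam over randomly
# interleaved task batches.

L2_DEFAULT <- 1e-6

#' Training configuration
#'
#' Defaults follow the study protocol: Adam with beta1 = 0.9, beta2 = 0.999,
#' learning rate 1e-3 (1e-4 for tanh networks), mini-batches of 64 trials all
#' drawn from one task, L2 weight and activity regularization both 1e-6, and
#' five-fold oversampling of the two contextual-integration tasks. Training
#' stops when the smoothed loss plateaus (no new best, by a relative margin,
#' for `patience` consecutive steps) or at `max_steps`.
#'
#' @param learning_rate Adam step size.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param batch_size Trials per mini-batch.
#' @param l2_weight,l2_activity L2 regularization strengths.
#' @param max_steps Hard cap on training steps.
#' @param min_steps Steps before the plateau rule may fire.
#' @param patience Steps without improvement that terminate training.
#' @param plateau_rel_tol Relative improvement required to count as a new
#'   best smoothed loss.
#' @param smooth_window Smoothing window (steps) for the plateau rule.
#' @param eval_every Evaluate per-task performance every this many steps
#'   (0 = never during training).
#' @param n_eval Trials per task for in-training evaluation.
#' @param dt_ms Trial timestep in ms.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, batch_size = 64,
                         l2_weight = L2_DEFAULT, l2_activity = L2_DEFAULT,
                         max_steps = 20000, min_steps = 1000,
                         patience = 2000, plateau_rel_tol = 0.005,
                         smooth_window = 100,
                         eval_every = 0, n_eval = 128, dt_ms = 20) {
  stopifnot(learning_rate >= 0, batch_size >= 1, max_steps >= 1)
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, batch_size = as.integer(batch_size),
                 l2_weight = l2_weight, l2_activity = l2_activity,
                 max_steps = as.integer(max_steps),
                 min_steps = as.integer(min_steps),
                 patience = as.integer(patience),
                 plateau_rel_tol = plateau_rel_tol,
                 smooth_window = as.integer(smooth_window),
                 eval_every = as.integer(eval_every),
                 n_eval = as.integer(n_eval), dt_ms = dt_ms),
            class = "train_config")
}

#' Loss mask for a trial batch
#'
#' Mask values: 0 during the first 100 ms of the context and response periods
#' (grace), 5 during the rest of the response period, 1 elsewhere, and 0
#' beyond each trial's end. The fixation-output row is twice the direction
#' rows, giving entries in \{0, 1, 2, 5, 10\}.
#'
#' @param batch A `trial_batch`.
#' @return Array \[T x trial x 3\].
#' @export
build_mask <- function(batch) {
  dims <- dim(batch$inputs)
  T_max <- dims[1]; n_trials <- dims[2]
  grace <- max(1L, as.integer(round(GRACE_MS / batch$dt_ms)))
  mask <- array(0, c(T_max, n_trials, N_OUT))
  for (b in seq_len(n_trials)) {
    pb <- batch$period_bounds[[b]]
    Tb <- batch$seq_len[b]
    m <- rep(1, Tb)
    for (k in seq_len(nrow(pb))) {
      p <- pb$period[k]; s <- pb$start[k]; e <- pb$end[k]
      if (is_response_period(p)) {
        m[s:e] <- 5
        m[s:min(e, s + grace - 1L)] <- 0
      } else if (p == "context") {
        m[s:min(e, s + grace - 1L)] <- 0
      }
    }
    mask[seq_len(Tb), b, 1] <- 2 * m
    mask[seq_len(Tb), b, 2] <- m
    mask[seq_len(Tb), b, 3] <- m
  }
  mask
}

#' Masked squared-error loss (with L2 regularization)
#'
#' Mean over output units, timesteps and trials of `m * (z - zhat)^2`, plus
#' `l2_activity * mean(h^2)` over running steps and `l2_weight` times the
#' summed squared entries of the three weight matrices. Noise is off; the
#' loss is deterministic given `h0`.
#'
#' @param params `network_params`.
#' @param batch A `trial_batch`.
#' @param h0 Initial states (default [make_h0()]).
#' @param l2_weight,l2_activity Regularization strengths.
#' @param want_grad Also return analytic gradients for all parameters.
#' @return List with `loss`, `loss_mse`, `loss_act`, `loss_w` and optionally
#'   `grad` (list of arrays matching `W_in`, `W_rec`, `W_out`, `b_in`,
#'   `b_out`).
#' @export
masked_loss <- function(params, batch, h0 = NULL,
                        l2_weight = L2_DEFAULT, l2_activity = L2_DEFAULT,
                        want_grad = FALSE) {
  check_params(params)
  n_trials <- dim(batch$inputs)[2]
  if (is.null(h0)) h0 <- make_h0(params, n_trials)
  res <- rnn_loss_grad_cpp(h0, aperm(batch$inputs, c(3, 2, 1)),
                           aperm(batch$targets, c(3, 2, 1)),
                           aperm(batch$mask, c(3, 2, 1)),
                           params$W_rec, params$W_in, params$b_in,
                           params$W_out, params$b_out,
                           act_code(params$activation), params$gamma,
                           alive_matrix(batch), 0, 0L,
                           l2_weight, l2_activity, want_grad)
  res
}

# ---- Adam -----------------------------------------------------------------

LEARNED <- c("W_in", "W_rec", "b_in", "W_out", "b_out")

adam_init <- function(params) {
  st <- list(t = 0L)
  for (nm in LEARNED) {
    st[[paste0("m_", nm)]] <- params[[nm]] * 0
    st[[paste0("v_", nm)]] <- params[[nm]] * 0
  }
  st
}

adam_update <- function(params, grad, state, config, plastic = NULL) {
  state$t <- state$t + 1L
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  lr <- config$learning_rate
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in LEARNED) {
    g <- grad[[nm]]
    if (!is.matrix(params[[nm]])) g <- as.numeric(g)
    if (!is.null(plastic)) g <- g * plastic[[nm]]
    m <- state[[paste0("m_", nm)]] <- b1 * state[[paste0("m_", nm)]] +
      (1 - b1) * g
    v <- state[[paste0("v_", nm)]] <- b2 * state[[paste0("v_", nm)]] +
      (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (m / corr1) / (sqrt(v / corr2) + 1e-8)
  }
  list(params = params, state = state)
}

# ---- training loop --------------------------------------------------------

#' Train a network on interleaved task batches
#'
#' Each step samples one task (proportional to oversampling weights), builds
#' a fresh noisy batch, and applies one Adam update of the masked loss.
#' Training stops when the smoothed loss stops decreasing (no new best for
#' `patience` steps) or at `max_steps`.
#'
#' @param params Initial `network_params`.
#' @param tasks Character vector of task names to interleave.
#' @param config A [train_config()].
#' @param plastic Optional list of 0/1 arrays (same shapes as the learned
#'   parameters) selecting which entries may change; used for rule-column
#'   transfer learning.
#' @param verbose Print progress lines.
#' @return List with trained `params`, `loss_curve` (per-step total loss),
#'   `log` (data.frame of step/task/loss and any in-training evaluations),
#'   and `steps_run`.
#' @export
train <- function(params, tasks, config = train_config(), plastic = NULL,
                  verbose = FALSE) {
  check_params(params)
  stopifnot(length(tasks) >= 1)
  reg <- task_registry()
  stopifnot(all(tasks %in% names(reg)))
  w <- vapply(tasks, function(t) reg[[t]]$oversampling_weight, numeric(1))
  st <- adam_init(params)
  losses <- numeric(config$max_steps)
  h0 <- make_h0(params, config$batch_size)
  best <- Inf; best_step <- 0L
  log_rows <- list()
  win <- config$smooth_window
  for (step in seq_len(config$max_steps)) {
    task <- if (length(tasks) == 1) tasks else sample(tasks, 1, prob = w)
    batch <- make_batch(task, config$batch_size, noise_on = TRUE,
                        dt_ms = config$dt_ms)
    res <- rnn_loss_grad_cpp(h0[, seq_len(config$batch_size), drop = FALSE],
                             aperm(batch$inputs, c(3, 2, 1)),
                             aperm(batch$targets, c(3, 2, 1)),
                             aperm(batch$mask, c(3, 2, 1)),
                             params$W_rec, params$W_in, params$b_in,
                             params$W_out, params$b_out,
                             act_code(params$activation), params$gamma,
                             alive_matrix(batch), params$private_noise_sd,
                             new_noise_seed(), config$l2_weight,
                             config$l2_activity, TRUE)
    losses[step] <- res$loss
    upd <- adam_update(params, res$grad, st, config, plastic)
    params <- upd$params; st <- upd$state
    if (step >= win) {
      smoothed <- mean(losses[(step - win + 1L):step])
      if (smoothed < best * (1 - config$plateau_rel_tol)) {
        best <- smoothed; best_step <- step
      }
      if (step >= config$min_steps &&
          step - max(best_step, win) >= config$patience) {
        losses <- losses[seq_len(step)]
        break
      }
    }
    if (config$eval_every > 0 && step %% config$eval_every == 0) {
      perf <- vapply(tasks, function(t)
        evaluate_performance(params, t, config$n_eval,
                             dt_ms = config$dt_ms)$fraction_correct,
        numeric(1))
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(step = step, loss = losses[step],
                   t(perf), check.names = FALSE)
      if (verbose)
        message(sprintf("step %d loss %.4f perf %s", step, losses[step],
                        paste(sprintf("%s=%.2f", tasks, perf),
                              collapse = " ")))
    }
  }
  list(params = params, loss_curve = losses,
       log = if (length(log_rows)) do.call(rbind, log_rows) else NULL,
       steps_run = length(losses))
}

# ---- evaluation -----------------------------------------------------------

#' Evaluate trial-level performance on one task
#'
#' Runs noisy trials and scores each one: the trial is correct iff the
#' fixation output never falls below 0.5 before the response window
#' (fixation break), and -- for respond trials -- the fixation output drops
#' below 0.5 during the response window and the decoded response angle
#' (atan2 of the window-mean sine/cosine outputs) is within pi/10 of the
#' target. Withhold trials are correct iff fixation is never broken. The
#' response window excludes the 100 ms grace at the start of the response
#' period, and the fixation-break check starts after the 100 ms context
#' grace (the network needs a few steps to move from its random initial
#' state to the fixating posture).
#'
#' @param params `network_params`.
#' @param task Task name.
#' @param n_trials Number of evaluation trials.
#' @param noise_on Evaluate with input and private noise (default TRUE).
#' @param dt_ms Timestep in ms.
#' @return A `performance_report`: `fraction_correct`, `n`, and counts of
#'   the failure modes (`fixation_break`, `wrong_angle`, `no_response`).
#' @export
evaluate_performance <- function(params, task, n_trials = 512,
                                 noise_on = TRUE, dt_ms = 20) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  batch <- make_batch(task, n_trials, noise_on = noise_on, dt_ms = dt_ms)
  traj <- run_batch(params, batch, noise_on = noise_on)
  score_trajectory(traj)
}

# scoring separated so oracle outputs can be scored in tests
score_trajectory <- function(traj) {
  batch <- traj$source_batch
  n_trials <- dim(batch$inputs)[2]
  grace <- max(1L, as.integer(round(GRACE_MS / batch$dt_ms)))
  n_break <- 0L; n_wrong <- 0L; n_noresp <- 0L; n_ok <- 0L
  for (b in seq_len(n_trials)) {
    pb <- batch$period_bounds[[b]]
    resp_row <- nrow(pb)
    rs <- pb$start[resp_row]; re <- pb$end[resp_row]
    win <- min(rs + grace, re):re
    fix <- traj$outputs[, b, 1]
    pre <- if (rs - 1L >= grace + 1L) (grace + 1L):(rs - 1L) else integer(0)
    broke_early <- any(fix[pre] < 0.5)
    cn <- batch$conditions[[b]]
    if (cn$withhold) {
      ok <- !broke_early && all(fix[win] >= 0.5)
      if (ok) n_ok <- n_ok + 1L else n_break <- n_break + 1L
    } else {
      if (broke_early) { n_break <- n_break + 1L; next }
      responded <- any(fix[win] < 0.5)
      if (!responded) { n_noresp <- n_noresp + 1L; next }
      phi_hat <- atan2(mean(traj$outputs[win, b, 2]),
                       mean(traj$outputs[win, b, 3]))
      if (circ_dist(phi_hat, cn$phi_target) < pi / 10) n_ok <- n_ok + 1L
      else n_wrong <- n_wrong + 1L
    }
  }
  structure(list(fraction_correct = n_ok / n_trials, n = n_trials,
                 fixation_break = n_break, wrong_angle = n_wrong,
                 no_response = n_noresp),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(paste0("<performance_report> %.1f%% correct (n=%d; break=%d ",
                     "wrong=%d noresp=%d)\n"),
              100 * x$fraction_correct, x$n, x$fixation_break,
              x$wrong_angle, x$no_response))
  invisible(x)
}
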