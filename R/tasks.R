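#' @useDynLib dynmotifs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var cor prcomp cutree hclust dist optim
#' @importFrom utils head tail write.csv
NULL

# ---- channel layout -------------------------------------------------------
# input u (20): [fixation(1), mod1 sin, mod1 cos, mod2 sin, mod2 cos, rule(15)]
# output z (3): [fixation, sin(phi), cos(phi)]
N_IN <- 20L
N_OUT <- 3L
N_RULE <- 15L
CH_FIX <- 1L
CH_MOD1 <- c(2L, 3L)
CH_MOD2 <- c(4L, 5L)
CH_RULE <- 6L:20L
FIX_TARGET <- 0.8
INPUT_NOISE_SD <- sqrt(0.1)
GRACE_MS <- 100

#' Canonical names of the 15 cognitive tasks
#'
#' The order defines the rule-input channel assignment: task k activates rule
#' channel k of the 15-dimensional one-hot rule block.
#'
#' @return Character vector of length 15.
#' @export
task_names <- function() {
  c("DelayPro", "DelayAnti", "MemoryPro", "MemoryAnti",
    "ReactPro", "ReactAnti",
    "IntegrationModality1", "IntegrationModality2",
    "ContextIntModality1", "ContextIntModality2", "IntegrationMultimodal",
    "ReactMatch2Sample", "ReactNonMatch2Sample",
    "ReactCategoryPro", "ReactCategoryAnti")
}

new_task_spec <- function(name, periods, durations, response_rule,
                          stimulus_schedule, modality_scheme,
                          fixation_off_in_response, oversampling_weight = 1) {
  stopifnot(periods[1] == "context",
            grepl("response", periods[length(periods)]),
            all(vapply(durations, function(d) d[1] > 0 && d[1] <= d[2],
                       logical(1))))
  structure(list(name = name, period_sequence = periods,
                 duration_distributions = durations,
                 response_rule = response_rule,
                 stimulus_schedule = stimulus_schedule,
                 modality_scheme = modality_scheme,
                 fixation_off_in_response = fixation_off_in_response,
                 oversampling_weight = oversampling_weight),
            class = "task_spec")
}

#' The task registry
#'
#' Builds the full registry of 15 task specifications: period sequences,
#' per-period uniform duration bounds (ms), stimulus schedules (which stimulus
#' event appears in which period), response rules, and oversampling weights
#' (the two contextual-integration tasks are sampled five times more often
#' during training).
#'
#' @return Named list of `task_spec` objects, one per task, in canonical
#'   rule-channel order.
#' @export
task_registry <- function() {
  delay_dur <- list(context = c(300, 700), stim1 = c(200, 1500),
                    response = c(300, 700))
  mem_dur <- list(context = c(300, 700), stim1 = c(200, 1600),
                  memory1 = c(200, 1600), response = c(300, 700))
  react_dur <- list(context = c(500, 2500), stim1_response = c(300, 1700))
  dm_dur <- list(context = c(200, 600), stim1 = c(200, 1600),
                 memory1 = c(200, 1600), stim2 = c(200, 1600),
                 memory2 = c(100, 300), response = c(300, 700))
  match_dur <- list(context = c(200, 600), stim1 = c(200, 1600),
                    memory1 = c(200, 1600), stim2_response = c(300, 700))

  reg <- list(
    new_task_spec("DelayPro", c("context", "stim1", "response"), delay_dur,
                  "pro", list(stim1 = 1L, response = 1L), "random_single", TRUE),
    new_task_spec("DelayAnti", c("context", "stim1", "response"), delay_dur,
                  "anti", list(stim1 = 1L, response = 1L), "random_single", TRUE),
    new_task_spec("MemoryPro", c("context", "stim1", "memory1", "response"),
                  mem_dur, "pro", list(stim1 = 1L), "random_single", TRUE),
    new_task_spec("MemoryAnti", c("context", "stim1", "memory1", "response"),
                  mem_dur, "anti", list(stim1 = 1L), "random_single", TRUE),
    new_task_spec("ReactPro", c("context", "stim1_response"), react_dur,
                  "pro", list(stim1_response = 1L), "random_single", FALSE),
    new_task_spec("ReactAnti", c("context", "stim1_response"), react_dur,
                  "anti", list(stim1_response = 1L), "random_single", FALSE),
    new_task_spec("IntegrationModality1",
                  c("context", "stim1", "memory1", "stim2", "memory2",
                    "response"), dm_dur, "decision",
                  list(stim1 = 1L, stim2 = 2L), "mod1_only", TRUE),
    new_task_spec("IntegrationModality2",
                  c("context", "stim1", "memory1", "stim2", "memory2",
                    "response"), dm_dur, "decision",
                  list(stim1 = 1L, stim2 = 2L), "mod2_only", TRUE),
    new_task_spec("ContextIntModality1",
                  c("context", "stim1", "memory1", "stim2", "memory2",
                    "response"), dm_dur, "decision",
                  list(stim1 = 1L, stim2 = 2L), "both_attend1", TRUE,
                  oversampling_weight = 5),
    new_task_spec("ContextIntModality2",
                  c("context", "stim1", "memory1", "stim2", "memory2",
                    "response"), dm_dur, "decision",
                  list(stim1 = 1L, stim2 = 2L), "both_attend2", TRUE,
                  oversampling_weight = 5),
    new_task_spec("IntegrationMultimodal",
                  c("context", "stim1", "memory1", "stim2", "memory2",
                    "response"), dm_dur, "decision",
                  list(stim1 = 1L, stim2 = 2L), "both_attend_both", TRUE),
    new_task_spec("ReactMatch2Sample",
                  c("context", "stim1", "memory1", "stim2_response"),
                  match_dur, "match_angle",
                  list(stim1 = 1L, stim2_response = 2L), "random_single", FALSE),
    new_task_spec("ReactNonMatch2Sample",
                  c("context", "stim1", "memory1", "stim2_response"),
                  match_dur, "nonmatch_angle",
                  list(stim1 = 1L, stim2_response = 2L), "random_single", FALSE),
    new_task_spec("ReactCategoryPro",
                  c("context", "stim1", "memory1", "stim2_response"),
                  match_dur, "category_pro",
                  list(stim1 = 1L, stim2_response = 2L), "random_single", FALSE),
    new_task_spec("ReactCategoryAnti",
                  c("context", "stim1", "memory1", "stim2_response"),
                  match_dur, "category_anti",
                  list(stim1 = 1L, stim2_response = 2L), "random_single", FALSE))
  names(reg) <- vapply(reg, `[[`, character(1), "name")
  stopifnot(identical(names(reg), task_names()))
  reg
}

get_task <- function(task) {
  if (inherits(task, "task_spec")) return(task)
  reg <- task_registry()
  if (!task %in% names(reg)) stop("unknown task: ", task)
  reg[[task]]
}

rule_channel <- function(task_name) {
  idx <- match(task_name, task_names())
  if (is.na(idx)) stop("unknown task: ", task_name)
  CH_RULE[idx]
}

is_response_period <- function(period) grepl("response", period)

circ_wrap <- function(x) x %% (2 * pi)

#' Circular distance between angles
#' @param a,b Angles in radians.
#' @return Absolute circular distance in \[0, pi\].
#' @export
circ_dist <- function(a, b) {
  d <- abs(circ_wrap(a) - circ_wrap(b))
  pmin(d, 2 * pi - d)
}

category_of <- function(theta) as.integer(circ_wrap(theta) < pi)

# ---- period durations -----------------------------------------------------

#' Sample per-period durations for a task
#'
#' Each period duration is drawn uniformly between its lower and upper bound
#' (in ms) and rounded to the nearest timestep, with a floor of one step.
#' With `fixed = TRUE` the midpoint of each bound is used instead (the
#' deterministic durations used for all noise-free analyses).
#'
#' @param task Task name or `task_spec`.
#' @param dt_ms Timestep in ms (default 20).
#' @param fixed Use deterministic midpoint durations.
#' @return Named integer vector of step counts per period.
#' @export
sample_period_durations <- function(task, dt_ms = 20, fixed = FALSE) {
  spec <- get_task(task)
  dur <- spec$duration_distributions
  if (!all(spec$period_sequence %in% names(dur)))
    stop("duration bounds missing for some period of ", spec$name)
  steps <- vapply(spec$period_sequence, function(p) {
    b <- dur[[p]]
    ms <- if (fixed) mean(b) else runif(1, b[1], b[2])
    max(1L, as.integer(round(ms / dt_ms)))
  }, integer(1))
  names(steps) <- spec$period_sequence
  steps
}

# ---- trial conditions -----------------------------------------------------

new_trial_condition <- function(theta_stim1, theta_stim2 = NA_real_,
                                modality = 1L,
                                amp_mod1_stim1 = 0, amp_mod2_stim1 = 0,
                                amp_mod1_stim2 = 0, amp_mod2_stim2 = 0,
                                phi_target = NA_real_, withhold = FALSE,
                                durations = NULL) {
  structure(list(theta_stim1 = circ_wrap(theta_stim1),
                 theta_stim2 = if (is.na(theta_stim2)) NA_real_
                               else circ_wrap(theta_stim2),
                 modality = modality,
                 amp_mod1_stim1 = amp_mod1_stim1,
                 amp_mod2_stim1 = amp_mod2_stim1,
                 amp_mod1_stim2 = amp_mod1_stim2,
                 amp_mod2_stim2 = amp_mod2_stim2,
                 phi_target = if (withhold) NA_real_ else circ_wrap(phi_target),
                 withhold = withhold, durations = durations),
            class = "trial_condition")
}

# amplitudes for one modality of a decision trial: the stronger event gets
# 1 + c/2, the weaker 1 - c/2 (coherence c = amplitude difference)
decision_amps <- function(coherence, stronger_event) {
  a <- c(1 - coherence / 2, 1 - coherence / 2)
  a[stronger_event] <- 1 + coherence / 2
  a
}

sample_condition <- function(spec, coherence_range = c(0.005, 0.2)) {
  th1 <- runif(1, 0, 2 * pi)
  rule <- spec$response_rule
  if (rule %in% c("pro", "anti")) {
    modality <- sample(1:2, 1)
    phi <- if (rule == "pro") th1 else th1 + pi
    amps <- c(0, 0, 0, 0)
    amps[modality] <- 1
    return(new_trial_condition(th1, NA, modality,
                               amp_mod1_stim1 = amps[1],
                               amp_mod2_stim1 = amps[2],
                               phi_target = phi))
  }
  if (rule == "decision") {
    th2 <- runif(1, 0, 2 * pi)
    coh1 <- runif(1, coherence_range[1], coherence_range[2])
    coh2 <- runif(1, coherence_range[1], coherence_range[2])
    s1 <- sample(1:2, 1)
    s2 <- sample(1:2, 1)
    m1 <- spec$modality_scheme %in% c("mod1_only", "both_attend1",
                                      "both_attend2", "both_attend_both")
    m2 <- spec$modality_scheme %in% c("mod2_only", "both_attend1",
                                      "both_attend2", "both_attend_both")
    a1 <- if (m1) decision_amps(coh1, s1) else c(0, 0)
    a2 <- if (m2) decision_amps(coh2, s2) else c(0, 0)
    ev <- switch(spec$modality_scheme,
                 mod1_only = , both_attend1 = which.max(a1),
                 mod2_only = , both_attend2 = which.max(a2),
                 both_attend_both = which.max(a1 + a2))
    phi <- if (ev == 1L) th1 else th2
    return(new_trial_condition(th1, th2, 0L,
                               amp_mod1_stim1 = a1[1], amp_mod1_stim2 = a1[2],
                               amp_mod2_stim1 = a2[1], amp_mod2_stim2 = a2[2],
                               phi_target = phi))
  }
  # delay-match family: one modality for both events, 50% respond trials
  modality <- sample(1:2, 1)
  respond <- runif(1) < 0.5
  match_angle <- switch(rule,
                        match_angle = th1,
                        nonmatch_angle = th1 + pi,
                        category_pro = NA,
                        category_anti = NA)
  if (rule %in% c("match_angle", "nonmatch_angle")) {
    th2 <- if (respond) match_angle
           else match_angle + pi / 2 + runif(1, 0, pi)
  } else {
    th2 <- runif(1, 0, 2 * pi)
    same <- category_of(th1) == category_of(th2)
    respond <- if (rule == "category_pro") same else !same
  }
  amps1 <- c(0, 0); amps1[modality] <- 1
  new_trial_condition(th1, th2, modality,
                      amp_mod1_stim1 = amps1[1], amp_mod2_stim1 = amps1[2],
                      amp_mod1_stim2 = amps1[1], amp_mod2_stim2 = amps1[2],
                      phi_target = if (respond) circ_wrap(th2) else NA,
                      withhold = !respond)
}

# amplitude of (modality m, stimulus event e) for a condition
cond_amp <- function(cond, m, e) {
  cond[[sprintf("amp_mod%d_stim%d", m, e)]]
}

#' Deterministic condition grid for analysis trials
#'
#' Evenly spaced stimulus angles on \[0, 2pi); decision tasks cross the angle
#' grid with each coherence value (stimulus event 1 stronger, event 2 at the
#' opposite angle); for other tasks `coherence_list` is ignored. Match-family
#' tasks pair each grid angle with its respond partner angle.
#'
#' @param task Task name or spec.
#' @param n_angles Number of evenly spaced angles (>= 2).
#' @param coherence_list Coherence values for decision tasks.
#' @return List of `trial_condition` objects.
#' @export
condition_grid <- function(task, n_angles = 8, coherence_list = c(0.005, 0.2)) {
  spec <- get_task(task)
  if (n_angles < 2) stop("condition grid needs at least 2 angles")
  angles <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  rule <- spec$response_rule
  if (rule %in% c("pro", "anti")) {
    return(lapply(angles, function(th) {
      new_trial_condition(th, NA, 1L, amp_mod1_stim1 = 1,
                          phi_target = if (rule == "pro") th else th + pi)
    }))
  }
  if (rule == "decision") {
    if (length(coherence_list) < 1) stop("empty coherence list")
    out <- list()
    for (coh in coherence_list) for (th in angles) {
      a <- decision_amps(coh, 1L)
      m1 <- spec$modality_scheme %in% c("mod1_only", "both_attend1",
                                        "both_attend2", "both_attend_both")
      m2 <- spec$modality_scheme %in% c("mod2_only", "both_attend1",
                                        "both_attend2", "both_attend_both")
      out[[length(out) + 1L]] <- new_trial_condition(
        th, th + pi, 0L,
        amp_mod1_stim1 = if (m1) a[1] else 0,
        amp_mod1_stim2 = if (m1) a[2] else 0,
        amp_mod2_stim1 = if (m2) a[1] else 0,
        amp_mod2_stim2 = if (m2) a[2] else 0,
        phi_target = th)
    }
    return(out)
  }
  # match family: respond-partner second angle
  lapply(angles, function(th) {
    th2 <- if (rule %in% c("match_angle", "category_pro")) th else th + pi
    new_trial_condition(th, th2, 1L,
                        amp_mod1_stim1 = 1, amp_mod1_stim2 = 1,
                        phi_target = th2)
  })
}

# ---- trial batches --------------------------------------------------------

#' Generate a batch of trials for one task
#'
#' Builds time-major input, target, and loss-mask arrays for `n_trials`
#' independently sampled trials of a single task, padded to the longest trial.
#' Inputs carry `A sin(theta)`, `A cos(theta)` in the scheduled modality
#' channels during stimulus periods, a fixation channel (1 until the response
#' period for tasks with a go cue; held at 1 throughout for reaction-timed and
#' match tasks), and the one-hot rule block. When `noise_on`, i.i.d. Gaussian
#' noise of standard deviation sqrt(0.1) is added to every input channel and
#' step.
#'
#' @param task Task name or `task_spec`.
#' @param n_trials Number of trials (>= 1).
#' @param conditions Optional list of `trial_condition`s (recycled/truncated
#'   to `n_trials`); by default conditions are sampled randomly.
#' @param noise_on Add input noise.
#' @param dt_ms Timestep in ms.
#' @param fixed_durations Use deterministic midpoint period durations.
#' @param shared_durations Draw one random duration set for the whole batch
#'   instead of per trial (used during training: durations still vary across
#'   batches, but trials within a batch align, which removes padding).
#' @return A `trial_batch`: list with `inputs` \[T x trial x 20\], `targets`
#'   \[T x trial x 3\], `mask` \[T x trial x 3\], `seq_len`, `period_bounds`
#'   (per-trial data.frame of 1-based inclusive step ranges), `conditions`,
#'   `task_name`, `dt_ms`.
#' @export
make_batch <- function(task, n_trials = 64, conditions = NULL,
                       noise_on = TRUE, dt_ms = 20, fixed_durations = FALSE,
                       shared_durations = FALSE) {
  spec <- get_task(task)
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (is.null(conditions)) {
    conditions <- replicate(n_trials, sample_condition(spec), simplify = FALSE)
  } else {
    if (inherits(conditions, "trial_condition")) conditions <- list(conditions)
    conditions <- rep(conditions, length.out = n_trials)
  }
  shared <- if (shared_durations)
    sample_period_durations(spec, dt_ms, fixed = fixed_durations)
  for (b in seq_len(n_trials)) {
    if (is.null(conditions[[b]]$durations))
      conditions[[b]]$durations <- if (shared_durations) shared
        else sample_period_durations(spec, dt_ms, fixed = fixed_durations)
  }
  seq_len_b <- vapply(conditions, function(cn) sum(cn$durations), numeric(1))
  T_max <- as.integer(max(seq_len_b))

  inputs <- array(0, c(T_max, n_trials, N_IN))
  targets <- array(0, c(T_max, n_trials, N_OUT))
  bounds <- vector("list", n_trials)
  rch <- rule_channel(spec$name)

  for (b in seq_len(n_trials)) {
    cn <- conditions[[b]]
    dur <- cn$durations
    ends <- cumsum(dur)
    starts <- ends - dur + 1L
    bounds[[b]] <- structure(list(period = names(dur),
                                  start = unname(starts), end = unname(ends)),
                             class = "data.frame",
                             row.names = seq_along(dur))
    Tb <- ends[length(ends)]
    alive <- seq_len(Tb)
    inputs[alive, b, rch] <- 1
    inputs[alive, b, CH_FIX] <- 1
    resp_p <- names(dur)[length(dur)]
    rsteps <- starts[resp_p]:ends[resp_p]
    if (spec$fixation_off_in_response)
      inputs[rsteps, b, CH_FIX] <- 0
    # stimulus channels
    for (p in names(spec$stimulus_schedule)) {
      ev <- spec$stimulus_schedule[[p]]
      ps <- starts[p]:ends[p]
      th <- if (ev == 1L) cn$theta_stim1 else cn$theta_stim2
      for (m in 1:2) {
        A <- cond_amp(cn, m, ev)
        if (A > 0) {
          ch <- if (m == 1) CH_MOD1 else CH_MOD2
          inputs[ps, b, ch[1]] <- A * sin(th)
          inputs[ps, b, ch[2]] <- A * cos(th)
        }
      }
    }
    # targets: fixation 0.8 -> 0 at response (withhold trials keep fixating)
    targets[alive, b, 1] <- FIX_TARGET
    if (!cn$withhold) {
      targets[rsteps, b, 1] <- 0
      targets[rsteps, b, 2] <- sin(cn$phi_target)
      targets[rsteps, b, 3] <- cos(cn$phi_target)
    }
  }
  if (noise_on) {
    running <- outer(seq_len(T_max), seq_len_b, `<=`) # [T x trial]
    inputs <- inputs + INPUT_NOISE_SD * rnorm(length(inputs)) *
      as.numeric(running)
  }

  batch <- structure(list(inputs = inputs, targets = targets, mask = NULL,
                          seq_len = as.integer(seq_len_b),
                          period_bounds = bounds, conditions = conditions,
                          task_name = spec$name, dt_ms = dt_ms),
                     class = "trial_batch")
  batch$mask <- build_mask(batch)
  batch
}

#' Generate a single trial
#'
#' Convenience wrapper around [make_batch()] with one trial.
#'
#' @inheritParams make_batch
#' @param condition A `trial_condition`, or `NULL` for a random condition.
#' @export
make_trial <- function(task, condition = NULL, noise_on = TRUE, dt_ms = 20,
                       fixed_durations = FALSE) {
  make_batch(task, 1L, conditions = condition, noise_on = noise_on,
             dt_ms = dt_ms, fixed_durations = fixed_durations)
}

#' @export
print.trial_batch <- function(x, ...) {
  cat(sprintf("<trial_batch> task=%s trials=%d steps=%d dt=%gms\n",
              x$task_name, dim(x$inputs)[2], dim(x$inputs)[1], x$dt_ms))
  invisible(x)
}

# constant (noise-free) input vector during one period of a task, for a
# given condition: the frozen u* defining that period's dynamical landscape
period_input <- function(task, period, condition) {
  spec <- get_task(task)
  if (!period %in% spec$period_sequence)
    stop("task ", spec$name, " has no period ", period)
  u <- numeric(N_IN)
  u[rule_channel(spec$name)] <- 1
  u[CH_FIX] <- if (is_response_period(period) && spec$fixation_off_in_response)
    0 else 1
  ev <- spec$stimulus_schedule[[period]]
  if (!is.null(ev)) {
    th <- if (ev == 1L) condition$theta_stim1 else condition$theta_stim2
    for (m in 1:2) {
      A <- cond_amp(condition, m, ev)
      if (A > 0) {
        ch <- if (m == 1) CH_MOD1 else CH_MOD2
        u[ch] <- A * c(sin(th), cos(th))
      }
    }
  }
  u
}

#' Export the task registry to YAML
#'
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_task_registry <- function(path) {
  reg <- task_registry()
  yaml::write_yaml(lapply(reg, unclass), path)
  invisible(path)
}

#' Write/read a trial batch to/from an RDS container
#'
#' @param batch A `trial_batch`.
#' @param path File path.
#' @export
write_batch <- function(batch, path) {
  stopifnot(inherits(batch, "trial_batch"))
  saveRDS(batch, path)
  invisible(path)
}

#' @rdname write_batch
#' @export
read_batch <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "trial_batch")) stop("not a trial_batch file: ", path)
  b
}
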