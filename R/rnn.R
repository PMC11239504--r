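# Leaky continuous-time RNN, Euler-discretized:
#   h_{t+1} = (1 - gamma) h_t + gamma * sigma(W_rec h_t + W_in u_t + b_in + xi)
#   z_t     = W_out h_t + b_out
# gamma = dt/tau (0.2 at dt = 20 ms, tau = 100 ms); xi is per-unit Gaussian
# white noise with sd 0.158 when enabled.

PRIVATE_NOISE_SD <- 0.158

#' Pointwise activation functions
#'
#' `softplus` = ln(1 + e^x), `tanh`, and `retanh` = max(tanh(x), 0).
#' Numerically stable over the full double range (softplus switches to its
#' asymptotes beyond |x| = 30).
#'
#' @param kind One of `"softplus"`, `"tanh"`, `"retanh"`.
#' @param x Numeric array.
#' @param deriv Return the derivative instead of the value.
#' @return Array of the same shape as `x`.
#' @export
activation_fn <- function(kind, x, deriv = FALSE) {
  switch(kind,
    softplus = if (deriv) stats::plogis(x)
               else ifelse(x > 30, x, log1p(exp(pmin(x, 30)))),
    tanh = if (deriv) 1 - tanh(x)^2 else tanh(x),
    retanh = if (deriv) ifelse(x > 0, 1 - tanh(x)^2, 0) else pmax(tanh(x), 0),
    stop("unknown activation kind: ", kind))
}

act_code <- function(kind) {
  switch(kind, softplus = 0L, tanh = 1L, retanh = 2L,
         stop("unknown activation kind: ", kind))
}

#' Initialize network parameters
#'
#' The recurrent matrix starts from a scaled identity (`diagonal`) or from
#' i.i.d. Gaussian entries with standard deviation `g / sqrt(n_rec)`
#' (`random_gaussian`). The gain defaults to 0.8, except tanh networks which
#' use 1 (lower gains quench tanh activity during training). Input and output
#' weights start as small Gaussians (sd `1/sqrt(n_in)` and `1/sqrt(n_rec)`);
#' biases start at zero.
#'
#' @param n_rec Number of recurrent units.
#' @param activation `"softplus"`, `"tanh"` or `"retanh"`.
#' @param init `"diagonal"` or `"random_gaussian"`.
#' @param gain Initial recurrent gain g; default 0.8 (1 for tanh).
#' @param gamma Leak factor dt/tau in (0, 1].
#' @param private_noise_sd Per-unit white-noise sd inside the activation
#'   argument (0.158).
#' @param h0_seed Seed for the per-network random trial initial states.
#' @return A `network_params` object.
#' @export
init_params <- function(n_rec = 128, activation = "softplus",
                        init = c("diagonal", "random_gaussian"),
                        gain = NULL, gamma = 0.2,
                        private_noise_sd = PRIVATE_NOISE_SD,
                        h0_seed = NULL) {
  if (n_rec < 1) stop("n_rec must be positive")
  init <- match.arg(init)
  act_code(activation) # validate
  if (is.null(gain)) gain <- if (activation == "tanh") 1 else 0.8
  stopifnot(gamma > 0, gamma <= 1)
  W_rec <- if (init == "diagonal") diag(gain, n_rec)
           else matrix(rnorm(n_rec^2, sd = gain / sqrt(n_rec)), n_rec)
  W_in <- matrix(rnorm(n_rec * N_IN, sd = 1 / sqrt(N_IN)), n_rec)
  W_out <- matrix(rnorm(N_OUT * n_rec, sd = 1 / sqrt(n_rec)), N_OUT)
  if (is.null(h0_seed)) h0_seed <- sample.int(.Machine$integer.max, 1)
  structure(list(W_in = W_in, W_rec = W_rec, W_out = W_out,
                 b_in = numeric(n_rec), b_out = numeric(N_OUT),
                 activation = activation, gamma = gamma,
                 private_noise_sd = private_noise_sd,
                 init_kind = init, init_gain = gain, n_rec = as.integer(n_rec),
                 h0_seed = as.integer(h0_seed)),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(paste0("<network_params> n_rec=%d activation=%s gamma=%g ",
                     "init=%s(g=%g)\n"),
              x$n_rec, x$activation, x$gamma, x$init_kind, x$init_gain))
  invisible(x)
}

check_params <- function(params) {
  stopifnot(inherits(params, "network_params"),
            nrow(params$W_rec) == params$n_rec,
            ncol(params$W_in) == N_IN, nrow(params$W_out) == N_OUT,
            all(is.finite(params$W_rec)), all(is.finite(params$W_in)),
            all(is.finite(params$W_out)))
  invisible(params)
}

#' Per-network trial initial states
#'
#' Initial conditions are drawn once per network from a zero-mean Gaussian of
#' sd 0.1, from the network's own `h0_seed`, so the same trial slots get
#' identical initial states across tasks (and across calls).
#'
#' @param params `network_params`.
#' @param n_trials Number of columns.
#' @return Matrix \[n_rec x n_trials\].
#' @export
make_h0 <- function(params, n_trials) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$h0_seed)
  matrix(rnorm(params$n_rec * n_trials, sd = 0.1), params$n_rec)
}

#' One Euler step of the leaky RNN
#'
#' @param h State vector (or matrix \[n_rec x trials\]).
#' @param u Input vector (or matrix \[20 x trials\]).
#' @param params `network_params`.
#' @param noise_on Inject private noise into the activation argument.
#' @return Next state, same shape as `h`.
#' @export
rnn_step <- function(h, u, params, noise_on = FALSE) {
  h <- as.matrix(h); u <- as.matrix(u)
  i <- params$W_rec %*% h + params$W_in %*% u + params$b_in
  if (noise_on)
    i <- i + matrix(rnorm(length(i), sd = params$private_noise_sd), nrow(i))
  if (any(!is.finite(i))) stop("non-finite network state in rnn_step")
  (1 - params$gamma) * h + params$gamma * activation_fn(params$activation, i)
}

# the noise-free discrete update map F(h, u); h may be a matrix of columns
update_map <- function(h, u, params) {
  rnn_step(h, u, params, noise_on = FALSE)
}

# alive matrix [trials x T]: 1 while the trial is still running
alive_matrix <- function(batch) {
  T_max <- dim(batch$inputs)[1]
  t(vapply(batch$seq_len, function(L) as.numeric(seq_len(T_max) <= L),
           numeric(T_max)))
}

new_noise_seed <- function() sample.int(.Machine$integer.max - 1L, 1)

#' Run the network over a trial batch
#'
#' Applies the Euler update for every timestep of every trial (frozen after a
#' trial's end) and records states and linear readouts.
#'
#' @param params `network_params`.
#' @param batch A `trial_batch`.
#' @param h0 Initial states \[n_rec x trials\]; default from [make_h0()].
#' @param noise_on Inject private recurrent noise (input noise is a property
#'   of the batch).
#' @return A `trajectory`: list with `states` \[T x trial x n_rec\],
#'   `outputs` \[T x trial x 3\], `h0`, and the source batch.
#' @export
run_batch <- function(params, batch, h0 = NULL, noise_on = FALSE) {
  check_params(params)
  n_trials <- dim(batch$inputs)[2]
  if (is.null(h0)) h0 <- make_h0(params, n_trials)
  U <- aperm(batch$inputs, c(3, 2, 1))
  res <- rnn_forward_cpp(h0, U, params$W_rec, params$W_in, params$b_in,
                         params$W_out, params$b_out,
                         act_code(params$activation), params$gamma,
                         alive_matrix(batch),
                         if (noise_on) params$private_noise_sd else 0,
                         if (noise_on) new_noise_seed() else 0L)
  structure(list(states = aperm(res$H, c(3, 2, 1)),
                 outputs = aperm(res$Z, c(3, 2, 1)),
                 h0 = h0, source_batch = batch),
            class = "trajectory")
}

#' @rdname run_batch
#' @param ... Passed to [run_batch()].
#' @export
run_trial <- function(params, batch, ...) run_batch(params, batch, ...)
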