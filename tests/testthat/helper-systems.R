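# Hand-built small networks used as analytic benchmarks, plus a cache for
# expensive trained networks shared across test files.

# n-unit network with explicit weights; inputs keep the 20-channel layout
toy_params <- function(W_rec, activation = "tanh", gamma = 0.2,
                       W_in = NULL, b_in = NULL, W_out = NULL, b_out = NULL) {
  n <- nrow(W_rec)
  p <- structure(list(
    W_in = if (is.null(W_in)) matrix(0, n, 20) else W_in,
    W_rec = W_rec,
    W_out = if (is.null(W_out)) matrix(0, 3, n) else W_out,
    b_in = if (is.null(b_in)) numeric(n) else b_in,
    b_out = if (is.null(b_out)) numeric(3) else b_out,
    activation = activation, gamma = gamma, private_noise_sd = 0.158,
    init_kind = "manual", init_gain = NA_real_, n_rec = as.integer(n),
    h0_seed = 1L), class = "network_params")
  p
}

# bisection for roots of g on [lo, hi]
bisect <- function(g, lo, hi, tol = 1e-12) {
  stopifnot(sign(g(lo)) != sign(g(hi)))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(g(mid)) == sign(g(lo))) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# all fixed points of the scalar map h -> (1-g) h + g act(w h + b) found by
# dense sign-change scan (independent oracle for the solver)
scalar_fp_oracle <- function(w, b, activation = "tanh", lo = -5, hi = 5,
                             n_grid = 20001) {
  act <- function(x) dynmotifs::activation_fn(activation, x)
  g <- function(h) act(w * h + b) - h
  hs <- seq(lo, hi, length.out = n_grid)
  vals <- g(hs)
  roots <- c()
  for (i in seq_len(n_grid - 1)) {
    if (vals[i] == 0) roots <- c(roots, hs[i])
    else if (sign(vals[i]) != sign(vals[i + 1]))
      roots <- c(roots, bisect(g, hs[i], hs[i + 1]))
  }
  unique(round(roots, 9))
}

# ---- shared trained-network cache ----------------------------------------
# Expensive fixtures are trained once per test run and reused across files.
.dynmotifs_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .dynmotifs_cache)) {
    assign(key, force(expr), .dynmotifs_cache)
  }
  get(key, .dynmotifs_cache)
}

# the two-task memory network used by the training/fixed-point/ring/lesion/
# interpolation acceptance checks
memory_network <- function() {
  cached("memory_network", {
    set.seed(0)
    p <- init_params(128, "softplus", h0_seed = sample.int(2^31 - 1, 1))
    tr <- train(p, c("MemoryPro", "MemoryAnti"), train_config(max_steps = 6000))
    tr$params
  })
}

memory_ring <- function() {
  cached("memory_ring", {
    set.seed(101)
    ring_analysis(memory_network())
  })
}

memory_fps <- function() memory_ring()$all_fps

# small (64-unit) networks trained on the two memory tasks, one per seed,
# used by the cross-network and transfer orderings
small_trained_network <- function(seed) {
  cached(paste0("small_net_", seed), {
    set.seed(seed)
    p <- init_params(64, "softplus", h0_seed = sample.int(2^31 - 1, 1))
    train(p, c("MemoryPro", "MemoryAnti"),
          train_config(max_steps = 1200))$params
  })
}

# stage-1 networks for the transfer ordering (held-out task: MemoryAnti)
pretrained_network <- function(tasks, seed) {
  cached(paste0("pre_", paste(substr(tasks, 1, 4), collapse = ""), "_", seed), {
    set.seed(2000 + seed)
    p <- init_params(64, "softplus", h0_seed = sample.int(2^31 - 1, 1))
    train(p, tasks, train_config(max_steps = 1200))$params
  })
}

# ring points of a memory network: the accepted fixed points that are
# "relevant" (nearest to the end-of-memory state) for at least one remembered
# angle, with their projections onto the top-2 PCs of the memory-period
# trajectories
ring_analysis <- function(params, task = "MemoryPro", period = "memory1",
                          n_angles = 24, n_seeds = 128) {
  fps <- task_fixed_points(params, task, period, tol_q = 1e-3,
                           n_seeds = n_seeds, n_angles = n_angles)
  grid <- condition_grid(task, n_angles)
  b <- make_batch(task, length(grid), conditions = grid, noise_on = FALSE,
                  fixed_durations = TRUE)
  traj <- run_batch(params, b, noise_on = FALSE)
  pb <- b$period_bounds[[1]]
  ps <- pb$start[pb$period == period]; pe <- pb$end[pb$period == period]
  ends <- traj$states[pe, , ] # [cond x unit]
  H <- t(vapply(fps, `[[`, numeric(params$n_rec), "h_star"))
  relevant <- unique(vapply(seq_len(nrow(ends)), function(cnd)
    which.min(colSums((t(H) - ends[cnd, ])^2)), integer(1)))
  ring <- fps[relevant]
  S <- matrix(traj$states[ps:pe, , ], ncol = params$n_rec)
  ctr <- colMeans(S)
  pcs <- svd(sweep(S, 2, ctr), nu = 0, nv = 2)$v
  proj <- sweep(H[relevant, , drop = FALSE], 2, ctr) %*% pcs
  radii <- sqrt(rowSums(proj^2))
  list(fps = ring, radii = radii, radial_cv = sd(radii) / mean(radii),
       all_fps = fps)
}
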