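test_that("registry holds 15 well-formed task specs", {
  reg <- task_registry()
  expect_length(reg, 15)
  for (spec in reg) {
    expect_s3_class(spec, "task_spec")
    expect_identical(spec$period_sequence[1], "context")
    expect_true(grepl("response",
                      spec$period_sequence[length(spec$period_sequence)]))
    for (b in spec$duration_distributions) {
      expect_gt(b[1], 0)
      expect_lte(b[1], b[2])
    }
  }
  expect_error(make_batch("NoSuchTask", 2), "unknown task")
})

test_that("period durations are uniform draws in the stated bounds", {
  set.seed(11)
  draws <- replicate(2000, sample_period_durations("MemoryPro", dt_ms = 20))
  ctx_ms <- draws["context", ] * 20
  expect_gte(min(ctx_ms), 300 - 10) # rounding to nearest step
  expect_lte(max(ctx_ms), 700 + 10)
  stim_ms <- draws["stim1", ] * 20
  expect_gte(min(stim_ms), 200 - 10)
  expect_lte(max(stim_ms), 1600 + 10)
  expect_equal(mean(stim_ms), 900, tolerance = 0.03)
  # degenerate uniform: fixed (midpoint) durations are deterministic
  d1 <- sample_period_durations("MemoryPro", 20, fixed = TRUE)
  d2 <- sample_period_durations("MemoryPro", 20, fixed = TRUE)
  expect_identical(d1, d2)
  expect_equal(unname(d1["context"]), 25) # 500 ms at 20 ms steps
})

test_that("trial arrays have the stated channel layout and rule one-hot", {
  set.seed(12)
  for (task in task_names()) {
    b <- make_batch(task, 3, noise_on = FALSE)
    expect_equal(dim(b$inputs)[3], 20)
    expect_equal(dim(b$targets)[3], 3)
    # pre-noise rule block is one-hot and constant while the trial runs
    for (tr in 1:3) {
      alive <- seq_len(b$seq_len[tr])
      rule <- b$inputs[alive, tr, 6:20, drop = FALSE]
      expect_equal(rowSums(rule[, 1, ]), rep(1, length(alive)))
      expect_true(all(rule %in% c(0, 1)))
      expect_equal(unique(which(rule[1, 1, ] == 1)),
                   match(task, task_names()))
    }
  }
})

test_that("stimulus channels carry A sin/cos theta during scheduled periods", {
  cn <- dynmotifs:::new_trial_condition(
    theta_stim1 = 0, modality = 1L, amp_mod1_stim1 = 1, phi_target = 0)
  b <- make_trial("MemoryPro", cn, noise_on = FALSE, fixed_durations = TRUE)
  pb <- b$period_bounds[[1]]
  stim <- pb$start[pb$period == "stim1"]:pb$end[pb$period == "stim1"]
  mem <- pb$start[pb$period == "memory1"]:pb$end[pb$period == "memory1"]
  expect_equal(unique(b$inputs[stim, 1, 2]), sin(0)) # mod1 sin = 0
  expect_equal(unique(b$inputs[stim, 1, 3]), cos(0)) # mod1 cos = 1
  expect_true(all(b$inputs[mem, 1, 2:5] == 0))      # stimulus off in memory
  expect_true(all(b$inputs[stim, 1, 4:5] == 0))      # modality 2 silent
  # fixation input: 1 until response, 0 during it (go-cue task)
  resp <- pb$start[pb$period == "response"]:pb$end[pb$period == "response"]
  expect_true(all(b$inputs[setdiff(seq_len(b$seq_len), resp), 1, 1] == 1))
  expect_true(all(b$inputs[resp, 1, 1] == 0))
  # fixation target 0.8 before response and 0 during it
  expect_true(all(b$targets[setdiff(seq_len(b$seq_len), resp), 1, 1] == 0.8))
  expect_true(all(b$targets[resp, 1, 1] == 0))
  expect_equal(unique(b$targets[resp, 1, 2]), sin(0))
  expect_equal(unique(b$targets[resp, 1, 3]), cos(0))
})

test_that("reaction-timed and match tasks never receive a go cue", {
  set.seed(13)
  for (task in c("ReactPro", "ReactAnti", "ReactMatch2Sample",
                 "ReactCategoryAnti")) {
    b <- make_batch(task, 2, noise_on = FALSE)
    for (tr in 1:2)
      expect_true(all(b$inputs[seq_len(b$seq_len[tr]), tr, 1] == 1),
                  label = paste(task, "fixation input"))
  }
})

test_that("response rules give the stated target angles", {
  set.seed(14)
  thetas <- 2 * pi * (0:63) / 64
  for (task in c("MemoryPro", "DelayPro", "ReactPro")) {
    g <- condition_grid(task, 64)
    phi <- vapply(g, `[[`, numeric(1), "phi_target")
    expect_equal(phi, thetas, tolerance = 1e-12, label = task)
  }
  for (task in c("MemoryAnti", "DelayAnti", "ReactAnti")) {
    g <- condition_grid(task, 64)
    phi <- vapply(g, `[[`, numeric(1), "phi_target")
    expect_equal(phi, (thetas + pi) %% (2 * pi), tolerance = 1e-12,
                 label = task)
  }
  # MemoryAnti theta = pi/2 -> target 3pi/2
  cn <- dynmotifs:::sample_condition(dynmotifs:::get_task("MemoryAnti"))
  cn2 <- replicate(50, dynmotifs:::sample_condition(
    dynmotifs:::get_task("MemoryAnti")), simplify = FALSE)
  for (c0 in cn2)
    expect_equal(circ_dist(c0$phi_target, c0$theta_stim1 + pi), 0,
                 tolerance = 1e-12)
})

test_that("match-family rules decide respond versus withhold correctly", {
  # same-category pair below pi: match for CategoryPro, respond at theta2
  g <- condition_grid("ReactCategoryPro", 8)
  expect_true(all(!vapply(g, `[[`, logical(1), "withhold")))
  expect_equal(vapply(g, `[[`, numeric(1), "phi_target"),
               vapply(g, `[[`, numeric(1), "theta_stim2"))
  set.seed(15)
  for (i in 1:200) {
    cn <- dynmotifs:::sample_condition(
      dynmotifs:::get_task("ReactCategoryPro"))
    same <- (cn$theta_stim1 < pi) == (cn$theta_stim2 < pi)
    expect_identical(cn$withhold, !same)
    if (!cn$withhold)
      expect_equal(cn$phi_target, cn$theta_stim2, tolerance = 1e-12)
    cn <- dynmotifs:::sample_condition(
      dynmotifs:::get_task("ReactCategoryAnti"))
    same <- (cn$theta_stim1 < pi) == (cn$theta_stim2 < pi)
    expect_identical(cn$withhold, same)
  }
})

test_that("decision conditions respond toward the stronger stimulus", {
  set.seed(16)
  for (i in 1:200) {
    cn <- dynmotifs:::sample_condition(
      dynmotifs:::get_task("ContextIntModality1"))
    # attended modality 1 decides regardless of modality 2
    win <- if (cn$amp_mod1_stim1 > cn$amp_mod1_stim2) cn$theta_stim1
           else cn$theta_stim2
    expect_equal(cn$phi_target, win, tolerance = 1e-12)
    expect_true(all(c(cn$amp_mod1_stim1, cn$amp_mod1_stim2,
                      cn$amp_mod2_stim1, cn$amp_mod2_stim2) >= 0))
    cm <- dynmotifs:::sample_condition(
      dynmotifs:::get_task("IntegrationMultimodal"))
    win <- if (cm$amp_mod1_stim1 + cm$amp_mod2_stim1 >
               cm$amp_mod1_stim2 + cm$amp_mod2_stim2) cm$theta_stim1
           else cm$theta_stim2
    expect_equal(cm$phi_target, win, tolerance = 1e-12)
  }
})

test_that("condition grids have the documented sizes", {
  expect_length(condition_grid("DelayPro", 8), 8)
  expect_length(condition_grid("IntegrationModality1", 8,
                               coherence_list = c(0.005, 0.2)), 16)
  expect_error(condition_grid("DelayPro", 1), "at least 2")
  expect_error(condition_grid("IntegrationModality1", 8,
                              coherence_list = numeric(0)), "empty")
})

test_that("batches pad with zero mask and freeze bookkeeping beyond trial end", {
  set.seed(17)
  b <- make_batch("MemoryPro", 16, noise_on = TRUE)
  T_max <- dim(b$inputs)[1]
  expect_equal(max(b$seq_len), T_max)
  for (tr in 1:16) {
    if (b$seq_len[tr] < T_max) {
      pad <- (b$seq_len[tr] + 1):T_max
      expect_true(all(b$mask[pad, tr, ] == 0))
      expect_true(all(b$inputs[pad, tr, ] == 0))
    }
    pb <- b$period_bounds[[tr]]
    # periods tile the trial without gaps or overlaps
    expect_equal(pb$start[1], 1)
    expect_equal(pb$end[nrow(pb)], b$seq_len[tr])
    if (nrow(pb) > 1)
      expect_equal(pb$start[-1], pb$end[-nrow(pb)] + 1)
  }
})

test_that("generation is deterministic under a fixed seed", {
  set.seed(99); b1 <- make_batch("ContextIntModality2", 8, noise_on = TRUE)
  set.seed(99); b2 <- make_batch("ContextIntModality2", 8, noise_on = TRUE)
  expect_identical(b1, b2)
})

test_that("registry and batch round-trip through their file formats", {
  tf <- tempfile(fileext = ".yaml")
  write_task_registry(tf)
  y <- yaml::read_yaml(tf)
  expect_length(y, 15)
  expect_equal(y$MemoryPro$duration_distributions$stim1, c(200, 1600))
  bf <- tempfile(fileext = ".rds")
  set.seed(3)
  b <- make_batch("DelayPro", 4)
  write_batch(b, bf)
  expect_identical(read_batch(bf), b)
})
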