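test_that("input-driven units produce the expected variance pattern", {
  # unit 1 reads the mod1-sine channel, unit 2 nothing: after normalization
  # unit 1 is maximal in the stimulus period and ~0 in the memory period
  Wi <- matrix(0, 2, 20); Wi[1, 2] <- 5
  p <- toy_params(matrix(0, 2, 2), "tanh", gamma = 0.5, W_in = Wi)
  p$n_rec <- 2L
  vm <- compute_variance_matrix(p, "MemoryPro", n_angles = 8)
  v <- vm$values
  expect_true(all(v >= 0))
  expect_equal(v["MemoryPro|stim1", "u1"], 1)
  # residual stimulus decay leaks a little variance into early memory steps
  expect_lt(v["MemoryPro|memory1", "u1"], 0.05)
  # unit 2 only carries its decayed initial transient: silent, left raw
  expect_equal(unname(vm$silent_units), 2L)
  expect_true(all(v[, "u2"] < 1e-12))
})

test_that("a constant-activity unit has zero variance everywhere", {
  p <- toy_params(matrix(0, 2, 2), "softplus", gamma = 0.5)
  p$n_rec <- 2L
  vm <- compute_variance_matrix(p, "MemoryPro", n_angles = 6,
                                normalize = FALSE)
  # softplus(0) drive converges to ln 2 for every condition -> variance ~ 0
  expect_true(all(vm$values < 1e-10))
})

test_that("sparsity counts entries below the threshold fraction", {
  vm <- structure(list(values = matrix(1, 4, 6), normalized = TRUE,
                       silent_units = integer(0)),
                  class = "variance_matrix")
  expect_equal(sparsity(vm), 0)
  vm$values[1:2, ] <- 0
  expect_equal(sparsity(vm), 0.5)
  expect_equal(sparsity(vm, threshold = 1.1), 1)
  vm$normalized <- FALSE
  expect_error(sparsity(vm), "normalized")
})

test_that("ward clustering recovers a planted two-block structure", {
  set.seed(51)
  # 2 unit blocks x 2 period blocks with small noise
  values <- rbind(cbind(matrix(1, 4, 10), matrix(0, 4, 10)),
                  cbind(matrix(0, 4, 10), matrix(1, 4, 10))) +
    matrix(rnorm(8 * 20, sd = 0.03), 8)
  rownames(values) <- paste0("t", 1:8)
  colnames(values) <- paste0("u", 1:20)
  vm <- structure(list(values = values, normalized = TRUE,
                       silent_units = integer(0)),
                  class = "variance_matrix")
  ca <- cluster_variance(vm, "units", k_range = 2:10)
  planted <- rep(1:2, each = 10)
  # exact recovery: two clusters, each pure
  expect_equal(ca$k, 2)
  for (cl in unique(ca$labels))
    expect_length(unique(planted[ca$labels == cl]), 1)
  # silhouette search range is 3..40 by default, truncated to item count
  ca2 <- cluster_variance(vm, "task_periods")
  expect_true(all(as.integer(names(ca2$silhouette_by_k)) <= 7))
  expect_gte(min(as.integer(names(ca2$silhouette_by_k))), 3)
})

test_that("well-separated blobs are still isolated at the forced minimum k", {
  set.seed(52)
  blob1 <- matrix(rnorm(60, mean = 0, sd = 0.1), 10)
  blob2 <- matrix(rnorm(60, mean = 4, sd = 0.1), 10)
  values <- t(rbind(blob1, blob2)) # 6 periods x 20 units
  rownames(values) <- paste0("t", 1:6)
  vm <- structure(list(values = values, normalized = TRUE,
                       silent_units = integer(0)),
                  class = "variance_matrix")
  ca <- cluster_variance(vm, "units", k_range = 3:10)
  # with k >= 3 one blob is split, but no cluster spans both blobs
  blob_id <- rep(1:2, each = 10)
  for (cl in unique(ca$labels))
    expect_length(unique(blob_id[ca$labels == cl]), 1)
})

test_that("variance matrix is invariant to unit permutation", {
  # two input-driven units with no recurrence: swapping them swaps columns
  # (the unpermuted random initial state decays away during the context
  # period, which the matrix excludes)
  Wi <- matrix(0, 2, 20); Wi[1, 2] <- 5; Wi[2, 3] <- 3
  p <- toy_params(matrix(0, 2, 2), "tanh", gamma = 0.5, W_in = Wi)
  p$n_rec <- 2L
  pp <- p
  pp$W_in <- p$W_in[2:1, ]
  vm <- compute_variance_matrix(p, "MemoryPro", n_angles = 8)
  vmp <- compute_variance_matrix(pp, "MemoryPro", n_angles = 8)
  expect_equal(unname(vmp$values), unname(vm$values[, 2:1]),
               tolerance = 1e-6)
})

test_that("normalization is idempotent", {
  set.seed(54)
  p <- init_params(10, "softplus", init = "random_gaussian")
  vm <- compute_variance_matrix(p, "DelayPro", n_angles = 6)
  mx <- apply(vm$values, 2, max)
  live <- mx > 0
  expect_true(all(abs(mx[live] - 1) < 1e-12))
  renorm <- sweep(vm$values[, live], 2, apply(vm$values[, live], 2, max), "/")
  expect_equal(renorm, vm$values[, live], tolerance = 1e-12)
})

test_that("cross-network similarity behaves at its fixed points", {
  set.seed(55)
  mk <- function(values) structure(
    list(values = values, normalized = TRUE, silent_units = integer(0)),
    class = "variance_matrix")
  v <- matrix(runif(6 * 15), 6,
              dimnames = list(paste0("t", 1:6), paste0("u", 1:15)))
  cmp <- compare_networks(list(a = mk(v), b = mk(v)))
  expect_equal(cmp$similarity["a", "b"], 1, tolerance = 1e-12)
  # independent random matrices decorrelate
  sims <- replicate(20, {
    v1 <- matrix(runif(16 * 40), 16,
                 dimnames = list(paste0("t", 1:16), NULL))
    v2 <- matrix(runif(16 * 40), 16,
                 dimnames = list(paste0("t", 1:16), NULL))
    compare_networks(list(mk(v1), mk(v2)))$similarity[1, 2]
  })
  expect_lt(abs(mean(sims)), 0.1)
  # mismatched row sets refuse to compare
  v3 <- v; rownames(v3) <- paste0("x", 1:6)
  expect_error(compare_networks(list(mk(v), mk(v3))), "different task-period")
})

test_that("variance matrix export includes labels and cluster row", {
  set.seed(56)
  p <- init_params(8, "softplus", init = "random_gaussian")
  vm <- compute_variance_matrix(p, c("MemoryPro", "MemoryAnti"), n_angles = 6)
  tf <- tempfile(fileext = ".csv")
  ca <- cluster_variance(vm, "units", k_range = 3:6)
  write_variance_matrix(vm, tf, ca)
  back <- read.csv(tf, row.names = 1)
  expect_equal(nrow(back), nrow(vm$values) + 1)
  expect_true("MemoryPro.stim1" %in% rownames(back) ||
              "MemoryPro|stim1" %in% rownames(back))
})
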