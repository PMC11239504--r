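# Pipeline glue: validated run configuration, checkpoint persistence, and an
# end-to-end driver (train -> variance -> clusters -> optional fixed points /
# interpolation / lesions).

CHECKPOINT_VERSION <- 1L

#' Assemble and validate a pipeline configuration
#'
#' All defaults follow the study protocol where one is stated (gamma 0.2,
#' noise levels, Adam settings, batch 64, L2 1e-6); the remaining knobs are
#' desk-scale analysis sizes.
#'
#' @param seed Master seed; all stage randomness derives from it.
#' @param tasks Task names to train on.
#' @param n_rec,activation,init Network architecture settings.
#' @param train Named list overriding [train_config()] fields.
#' @param analysis Named list: `n_angles`, `coherence_list`, `tol_q`,
#'   `n_seeds`, `n_alpha`, `k_range`, `n_eval`.
#' @param dt_ms Timestep in ms.
#' @return A validated `run_config`.
#' @export
run_config <- function(seed = 1, tasks = c("MemoryPro", "MemoryAnti"),
                       n_rec = 128, activation = "softplus",
                       init = "diagonal", train = list(),
                       analysis = list(), dt_ms = 20) {
  stopifnot(all(tasks %in% task_names()), length(seed) == 1)
  tc <- do.call(train_config, c(train, list(dt_ms = dt_ms)))
  an <- utils::modifyList(
    list(n_angles = 16, coherence_list = c(0.005, 0.05, 0.2), tol_q = 1e-3,
         n_seeds = 128, n_alpha = 21, k_range = 3:40, n_eval = 512),
    analysis)
  structure(list(seed = as.integer(seed), tasks = tasks, n_rec = n_rec,
                 activation = activation, init = init, train = tc,
                 analysis = an, dt_ms = dt_ms),
            class = "run_config")
}

# derive a named substream seed (kept below 2^31) from the master seed
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 977)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647) + 1L
}

#' Save / load a network checkpoint
#'
#' Checkpoints hold all parameters plus the configuration that produced them
#' and round-trip bit-exactly.
#'
#' @param params `network_params`.
#' @param config The `run_config` (or any list) that produced the network.
#' @param path File path.
#' @return `save_checkpoint`: invisibly, the path. `load_checkpoint`: list
#'   with `params` and `config`.
#' @export
save_checkpoint <- function(params, config, path) {
  check_params(params)
  saveRDS(list(version = CHECKPOINT_VERSION, params = params,
               config = config), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt checkpoint: ", path,
                                           " (", conditionMessage(e), ")"))
  if (!is.list(obj) || is.null(obj$version))
    stop("corrupt checkpoint: ", path)
  if (obj$version != CHECKPOINT_VERSION)
    stop(sprintf("checkpoint version mismatch: file has %s, package expects %d",
                 obj$version, CHECKPOINT_VERSION))
  obj[c("params", "config")]
}

#' Run the full pipeline
#'
#' Initializes a network from the config seed, trains it on the configured
#' tasks (0 training steps yields the untrained control), computes the
#' variance matrix and unit clusters, evaluates per-task performance, and
#' optionally runs fixed-point, interpolation, and lesion stages. All
#' artifacts are written under `out_dir` (checkpoint, variance CSV,
#' performance CSV, config JSON).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param stages Character subset of `c("fixed_points", "interpolation",
#'   "lesion")` to run beyond the core train/variance/cluster stages.
#' @return Invisibly, a list with `params`, `performance`, `vm`, `clusters`,
#'   and any optional stage outputs.
#' @export
run_pipeline <- function(config, out_dir, stages = character(0)) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  an <- config$analysis

  set.seed(substream_seed(config$seed, "init"))
  params <- init_params(config$n_rec, config$activation, config$init)

  set.seed(substream_seed(config$seed, "train"))
  trained <- if (config$train$max_steps > 0)
    train(params, config$tasks, config$train)
  else list(params = params, loss_curve = numeric(0), steps_run = 0L)
  params <- trained$params
  save_checkpoint(params, config, file.path(out_dir, "checkpoint.rds"))
  if (length(trained$loss_curve))
    write.csv(data.frame(step = seq_along(trained$loss_curve),
                         loss = trained$loss_curve),
              file.path(out_dir, "loss_curve.csv"), row.names = FALSE)

  set.seed(substream_seed(config$seed, "eval"))
  performance <- vapply(config$tasks, function(t)
    evaluate_performance(params, t, an$n_eval,
                         dt_ms = config$dt_ms)$fraction_correct, numeric(1))
  write.csv(data.frame(task = config$tasks, fraction_correct = performance),
            file.path(out_dir, "performance.csv"), row.names = FALSE)

  vm <- compute_variance_matrix(params, config$tasks, n_angles = an$n_angles,
                                coherence_list = an$coherence_list,
                                dt_ms = config$dt_ms)
  clusters <- cluster_variance(vm, "units", k_range = an$k_range)
  write_variance_matrix(vm, file.path(out_dir, "variance_matrix.csv"),
                        clusters)

  out <- list(params = params, performance = performance, vm = vm,
              clusters = clusters, steps_run = trained$steps_run)

  if ("fixed_points" %in% stages) {
    set.seed(substream_seed(config$seed, "fps"))
    task <- config$tasks[1]
    spec <- get_task(task)
    period <- if ("memory1" %in% spec$period_sequence) "memory1"
              else spec$period_sequence[2]
    out$fixed_points <- task_fixed_points(params, task, period,
                                          tol_q = an$tol_q,
                                          n_seeds = an$n_seeds,
                                          dt_ms = config$dt_ms)
  }
  if ("interpolation" %in% stages && length(config$tasks) >= 2) {
    set.seed(substream_seed(config$seed, "interp"))
    sa <- get_task(config$tasks[1]); sb <- get_task(config$tasks[2])
    shared_p <- intersect(sa$period_sequence, sb$period_sequence)
    shared_p <- shared_p[shared_p != "context"][1]
    out$interpolation <- track_relevant_fp(params, config$tasks[1],
                                           config$tasks[2], shared_p,
                                           n_alpha = an$n_alpha,
                                           tol_q = an$tol_q,
                                           dt_ms = config$dt_ms)
  }
  if ("lesion" %in% stages) {
    set.seed(substream_seed(config$seed, "lesion"))
    out$lesion <- lesion_report(params, clusters, config$tasks,
                                n_eval = min(an$n_eval, 128),
                                seed = substream_seed(config$seed, "lesion"),
                                dt_ms = config$dt_ms)
    jsonlite::write_json(out$lesion$results,
                         file.path(out_dir, "lesion_report.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  jsonlite::write_json(
    list(seed = config$seed, tasks = config$tasks, n_rec = config$n_rec,
         activation = config$activation, steps_run = out$steps_run,
         performance = as.list(performance)),
    file.path(out_dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}
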