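# Cluster lesions: zero the outgoing projections of a unit set and compare
# per-task performance against the unlesioned baseline under paired seeds.

#' Lesion a set of units
#'
#' Sets the lesioned units' projection weights to zero: the corresponding
#' columns of `W_rec` (their input to every recurrent unit) and of `W_out`
#' (their input to the readout). Incoming weights are untouched, so the
#' lesioned units still receive input; their output simply no longer reaches
#' the rest of the network. Lesions apply for the entire trial.
#'
#' @param params `network_params`.
#' @param unit_ids Integer unit indices in 1..n_rec.
#' @return Lesioned `network_params` (all other entries bit-identical).
#' @export
lesion_units <- function(params, unit_ids) {
  check_params(params)
  unit_ids <- as.integer(unit_ids)
  if (length(unit_ids) &&
      (min(unit_ids) < 1 || max(unit_ids) > params$n_rec))
    stop("unit index out of range")
  params$W_rec[, unit_ids] <- 0
  params$W_out[, unit_ids] <- 0
  params
}

#' Evaluate the behavioral effect of cluster lesions
#'
#' For each requested cluster, evaluates every task before and after
#' lesioning the cluster's units, with identical trial seeds for the
#' baseline and lesioned runs (paired evaluation), and reports the
#' fractional performance change per task.
#'
#' @param params `network_params`.
#' @param clusters A `cluster_assignment` on units, or a named list of unit
#'   index vectors.
#' @param tasks Task names to evaluate.
#' @param n_eval Trials per task per evaluation.
#' @param cluster_ids Which clusters to lesion (default: all).
#' @param seed Seed for the paired evaluations.
#' @param dt_ms Timestep in ms.
#' @return A `lesion_report`: per-cluster data.frame of task, baseline,
#'   lesioned, and fraction_change (`(lesioned - baseline)/baseline`,
#'   NA where baseline is 0).
#' @export
lesion_report <- function(params, clusters, tasks = task_names(),
                          n_eval = 128, cluster_ids = NULL, seed = 1,
                          dt_ms = 20) {
  units_by_cluster <- if (inherits(clusters, "cluster_assignment")) {
    stopifnot(clusters$axis == "units")
    split(seq_along(clusters$labels), clusters$labels)
  } else clusters
  if (is.null(cluster_ids)) cluster_ids <- names(units_by_cluster)
  eval_all <- function(p) {
    set.seed(seed)
    vapply(tasks, function(t)
      evaluate_performance(p, t, n_eval, dt_ms = dt_ms)$fraction_correct,
      numeric(1))
  }
  baseline <- eval_all(params)
  out <- lapply(cluster_ids, function(cid) {
    lp <- lesion_units(params, units_by_cluster[[cid]])
    les <- eval_all(lp)
    data.frame(cluster = cid, task = tasks, baseline = baseline,
               lesioned = les,
               fraction_change = ifelse(baseline > 0,
                                        (les - baseline) / baseline, NA),
               row.names = NULL)
  })
  structure(list(results = do.call(rbind, out),
                 lesioned_units = units_by_cluster[cluster_ids],
                 n_eval = n_eval, seed = seed),
            class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf("<lesion_report> %d cluster(s), n_eval=%d\n",
              length(x$lesioned_units), x$n_eval))
  print(x$results)
  invisible(x)
}

#' Fixed points under a cluster lesion
#'
#' @param params `network_params`.
#' @param unit_ids Units to lesion.
#' @param task,period Task period whose frozen input is analyzed.
#' @param ... Passed to [task_fixed_points()].
#' @return List of `fixed_point`s of the lesioned network.
#' @export
lesioned_fixed_points <- function(params, unit_ids, task, period, ...) {
  task_fixed_points(lesion_units(params, unit_ids), task, period, ...)
}
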