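# Task-variance analysis: per-(task, period) stimulus-condition variance of
# every unit, unit-normalized; sparsity; Ward clustering with silhouette-
# selected k; and cross-network correlation comparisons.

#' Task-variance matrix of a network
#'
#' For every task and every post-context period, runs the network noise-free
#' over the task's condition grid (deterministic durations) and computes each
#' unit's activity variance across (condition x within-period timepoint)
#' samples. The context (pure fixation) period is excluded. Columns (units)
#' are then normalized by their maximum over task periods.
#'
#' @param params `network_params`.
#' @param tasks Task names (default all 15).
#' @param n_angles Condition-grid angles per task.
#' @param coherence_list Coherences for decision-task grids.
#' @param variance_over `"joint"` (variance across conditions and timepoints
#'   pooled; the default, treating time as part of the dynamical signature)
#'   or `"time_mean"` (variance across conditions at each timepoint, then
#'   averaged over the period).
#' @param normalize Normalize each unit column by its max over rows.
#' @param silent_tol Units whose maximum variance does not exceed this are
#'   flagged silent and left unnormalized.
#' @param dt_ms Timestep in ms.
#' @return A `variance_matrix`: `values` \[task_periods x units\] with
#'   row labels `"task|period"`, plus `normalized` flag and `silent_units`.
#' @export
compute_variance_matrix <- function(params, tasks = task_names(),
                                    n_angles = 16,
                                    coherence_list = c(0.005, 0.05, 0.2),
                                    variance_over = c("joint", "time_mean"),
                                    normalize = TRUE, silent_tol = 1e-12,
                                    dt_ms = 20) {
  check_params(params)
  variance_over <- match.arg(variance_over)
  rows <- list()
  labels <- character(0)
  for (task in tasks) {
    spec <- get_task(task)
    grid <- condition_grid(task, n_angles, coherence_list)
    batch <- make_batch(task, length(grid), conditions = grid,
                        noise_on = FALSE, dt_ms = dt_ms,
                        fixed_durations = TRUE)
    traj <- run_batch(params, batch, noise_on = FALSE)
    pb <- batch$period_bounds[[1]]
    for (k in seq_len(nrow(pb))) {
      period <- pb$period[k]
      if (period == "context") next
      sl <- traj$states[pb$start[k]:pb$end[k], , , drop = FALSE]
      v <- if (variance_over == "joint") {
        apply(matrix(sl, ncol = params$n_rec), 2, var)
      } else {
        # variance across conditions at each timepoint, averaged over time
        colMeans(apply(sl, 1, function(m) apply(m, 2, var)) |> t())
      }
      rows[[length(rows) + 1L]] <- v
      labels <- c(labels, paste0(spec$name, "|", period))
    }
  }
  values <- do.call(rbind, rows)
  rownames(values) <- labels
  colnames(values) <- paste0("u", seq_len(ncol(values)))
  mx <- apply(values, 2, max)
  silent <- which(mx <= silent_tol) # numerically dead units stay raw
  if (normalize) {
    scale_by <- ifelse(mx > silent_tol, mx, 1)
    values <- sweep(values, 2, scale_by, "/")
  }
  structure(list(values = values, normalized = normalize,
                 silent_units = silent, variance_over = variance_over),
            class = "variance_matrix")
}

#' @export
print.variance_matrix <- function(x, ...) {
  cat(sprintf("<variance_matrix> %d task periods x %d units (%s%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw",
              if (length(x$silent_units))
                sprintf(", %d silent units", length(x$silent_units)) else ""))
  invisible(x)
}

#' Sparsity of a normalized variance matrix
#'
#' Fraction of entries strictly below `threshold` (default 0.15, i.e. 15% of
#' each unit's maximum task-period variance).
#'
#' @param vm A normalized `variance_matrix`.
#' @param threshold Sparsity threshold.
#' @return Fraction in \[0, 1\].
#' @export
sparsity <- function(vm, threshold = 0.15) {
  stopifnot(inherits(vm, "variance_matrix"))
  if (!vm$normalized) stop("sparsity is defined on the normalized matrix")
  mean(vm$values < threshold)
}

#' Ward hierarchical clustering with silhouette-selected k
#'
#' Clusters units (columns) or task periods (rows) of the variance matrix by
#' Ward's variance-minimization linkage on Euclidean distances, computes the
#' mean silhouette score for every candidate cluster count, and returns the
#' cut at the k with the highest score.
#'
#' @param vm A `variance_matrix`.
#' @param axis `"units"` or `"task_periods"`.
#' @param k_range Candidate cluster counts (default 3:40, truncated to the
#'   number of items minus one).
#' @return A `cluster_assignment`: `labels` (named integer partition), `k`,
#'   `silhouette_by_k`, `linkage` (hclust object), `axis`.
#' @export
cluster_variance <- function(vm, axis = c("units", "task_periods"),
                             k_range = 3:40) {
  stopifnot(inherits(vm, "variance_matrix"))
  axis <- match.arg(axis)
  x <- if (axis == "units") t(vm$values) else vm$values
  if (nrow(x) < 4) stop("need at least 4 items to cluster")
  k_range <- k_range[k_range < nrow(x)]
  if (!length(k_range)) stop("k_range exceeds the number of items")
  d <- dist(x)
  hc <- hclust(d, method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    ct <- cutree(hc, k = k)
    mean(cluster::silhouette(ct, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range
  k_best <- k_range[which.max(sil)]
  structure(list(axis = axis, labels = cutree(hc, k = k_best), k = k_best,
                 silhouette_by_k = sil, linkage = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %s: k=%d (best silhouette %.3f)\n",
              x$axis, x$k, max(x$silhouette_by_k)))
  invisible(x)
}

#' Cross-network similarity of variance structure
#'
#' For each network's variance matrix (rows sorted to a common reference
#' order), computes the Pearson correlation matrix between task-period rows,
#' flattens its upper triangle, and correlates these vectors across networks.
#'
#' @param vms List of `variance_matrix` objects with identical row sets.
#' @param reference Index of the reference network for row ordering.
#' @return List with `similarity` (network x network Pearson matrix) and
#'   `row_correlations` (per-network row-correlation matrices).
#' @export
compare_networks <- function(vms, reference = 1) {
  stopifnot(length(vms) >= 2)
  ref_rows <- rownames(vms[[reference]]$values)
  cors <- lapply(vms, function(vm) {
    v <- vm$values
    if (!setequal(rownames(v), ref_rows))
      stop("variance matrices have different task-period row sets")
    cor(t(v[ref_rows, , drop = FALSE]))
  })
  ut <- upper.tri(cors[[1]])
  flat <- vapply(cors, function(cm) cm[ut], numeric(sum(ut)))
  sim <- cor(flat)
  dimnames(sim) <- list(names(vms), names(vms))
  list(similarity = sim, row_correlations = cors)
}

#' Average row-correlation matrix across networks
#'
#' @param vms List of `variance_matrix` objects.
#' @param reference Reference network index for row ordering.
#' @return Matrix of mean Pearson correlations between task-period rows.
#' @export
average_row_correlation <- function(vms, reference = 1) {
  cors <- compare_networks(vms, reference)$row_correlations
  Reduce(`+`, cors) / length(cors)
}

#' Write a variance matrix (and optional cluster labels) to CSV
#'
#' @param vm A `variance_matrix`.
#' @param path Output CSV path.
#' @param clusters Optional `cluster_assignment` on units; appended as a row.
#' @export
write_variance_matrix <- function(vm, path, clusters = NULL) {
  out <- as.data.frame(vm$values)
  if (!is.null(clusters) && clusters$axis == "units")
    out <- rbind(out, cluster = clusters$labels)
  write.csv(out, path)
  invisible(path)
}
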