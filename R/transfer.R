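# Transfer learning: pre-train on a task subset with everything plastic,
# then learn a held-out task through its rule-input column alone, with the
# rest of the network frozen.

#' Rule-column transfer training
#'
#' Stage-2 learning of a held-out task: every connection is frozen except the
#' held-out task's rule-input column of `W_in` (an `n_rec`-vector). The
#' column is re-initialized to small random values, then trained with the
#' same Adam configuration as stage 1, recording the held-out task's
#' performance along the way.
#'
#' @param params Pre-trained `network_params` (stage 1 must not have included
#'   `heldout_task`; pass `pretrain_tasks` to enforce this).
#' @param heldout_task Task name to learn via its rule column.
#' @param config A [train_config()]; `eval_every`/`n_eval` control the
#'   learning curve resolution.
#' @param pretrain_tasks Optional character vector of stage-1 tasks, checked
#'   against the held-out task.
#' @param reinit_sd Scale of the random re-initialization of the rule column.
#' @return A `transfer_result`: trained `params`, `curve` (data.frame of
#'   step and heldout performance), `auc` (mean performance over curve
#'   checkpoints), `heldout_task`.
#' @export
transfer_train <- function(params, heldout_task, config = train_config(),
                           pretrain_tasks = NULL, reinit_sd = 0.01) {
  check_params(params)
  if (!is.null(pretrain_tasks) && heldout_task %in% pretrain_tasks)
    stop("held-out task was part of the pre-training set")
  rch <- rule_channel(get_task(heldout_task)$name)
  plastic <- list(W_in = matrix(0, params$n_rec, N_IN),
                  W_rec = matrix(0, params$n_rec, params$n_rec),
                  b_in = numeric(params$n_rec),
                  W_out = matrix(0, N_OUT, params$n_rec),
                  b_out = numeric(N_OUT))
  plastic$W_in[, rch] <- 1
  params$W_in[, rch] <- rnorm(params$n_rec, sd = reinit_sd)
  if (config$eval_every <= 0) config$eval_every <- 200L
  tr <- train(params, heldout_task, config, plastic = plastic)
  curve <- if (is.null(tr$log)) {
    data.frame(step = tr$steps_run,
               performance = evaluate_performance(
                 tr$params, heldout_task, config$n_eval)$fraction_correct)
  } else {
    data.frame(step = tr$log$step, performance = tr$log[[heldout_task]])
  }
  structure(list(params = tr$params, heldout_task = heldout_task,
                 curve = curve, auc = mean(curve$performance),
                 steps_run = tr$steps_run, loss_curve = tr$loss_curve),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> heldout=%s steps=%d AUC=%.3f final=%.3f\n",
              x$heldout_task, x$steps_run, x$auc,
              utils::tail(x$curve$performance, 1)))
  invisible(x)
}

#' Motif-uniqueness score of a task
#'
#' From an averaged task-period row-correlation matrix (see
#' [average_row_correlation()]): for each period of the task, the maximum
#' correlation to any period of a different task; the task's score is the
#' minimum of these maxima. Low scores mark tasks whose dynamics have no
#' counterpart in other tasks (unique motifs).
#'
#' @param avg_corr Square correlation matrix with `"task|period"` dimnames.
#' @param task Task name.
#' @return Scalar uniqueness score.
#' @export
motif_uniqueness <- function(avg_corr, task) {
  rows <- rownames(avg_corr)
  row_task <- sub("\\|.*$", "", rows)
  own <- which(row_task == task)
  if (!length(own)) stop("task ", task, " not present in correlation matrix")
  other <- which(row_task != task)
  maxima <- vapply(own, function(i) max(avg_corr[i, other]), numeric(1))
  min(maxima)
}
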