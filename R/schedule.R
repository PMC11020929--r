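#' Define a training schedule (curriculum)
#'
#' A schedule fixes the curriculum regime and its bookkeeping: slice size,
#' epochs per slice, batch size, the amount of pre-training `n_pretrain`
#' (number of supporting-task slices) and the number of main-task slices
#' `n_main`.  Regimes: `static` pools the pre-training budget into one
#' subset; `continual` presents disjoint slices sequentially (exemplar
#' incremental); `reversed` runs the main task before the supporting task;
#' `class_incremental` stages the pre-training slices so each stage
#' introduces previously unseen digit classes.
#'
#' @param regime one of "static", "continual", "reversed", "class_incremental"
#' @param n_pretrain number of supporting-task slices (0..24)
#' @param n_main number of main-task slices (default 8)
#' @param slice_size exemplars per slice (default 400; 1250 at full scale)
#' @param epochs_per_slice epochs per slice (default 3)
#' @param batch_size minibatch size (default 32)
#' @param eval_size held-out evaluation set size recorded with the schedule
#' @param record_fi record Fisher Information for both task losses after
#'   every slice (default FALSE; costs one forward+backward per exemplar of
#'   the probe slice per loss)
#' @param seed integer seed driving slicing, shuffling and initial weights
#' @return an object of class `schedule`
#' @export
schedule <- function(regime = c("static", "continual", "reversed", "class_incremental"),
                     n_pretrain = 0L, n_main = 8L, slice_size = 400L,
                     epochs_per_slice = 3L, batch_size = 32L, eval_size = 1000L,
                     record_fi = FALSE, seed = 1L) {
  regime <- match.arg(regime)
  if (n_pretrain < 0 || n_pretrain > 24) stop("n_pretrain must be in 0..24")
  if (n_main < 1) stop("n_main must be >= 1")
  if (slice_size < 1 || epochs_per_slice < 1 || batch_size < 1) stop("sizes must be >= 1")
  structure(
    list(regime = regime, n_pretrain = as.integer(n_pretrain),
         n_main = as.integer(n_main), slice_size = as.integer(slice_size),
         epochs_per_slice = as.integer(epochs_per_slice),
         batch_size = as.integer(batch_size), eval_size = as.integer(eval_size),
         record_fi = isTRUE(record_fi), seed = as.integer(seed)),
    class = "schedule"
  )
}

pool_size_of <- function(data) {
  if (inherits(data, "glyph_corpus")) length(data$labels)
  else if (inherits(data, "scene_dataset")) n_scenes(data)
  else if (is.numeric(data) && length(data) == 1) as.integer(data)
  else stop("data must be a corpus, a scene dataset, or a pool size")
}

first_class_of <- function(data) {
  if (inherits(data, "glyph_corpus")) data$labels
  else if (inherits(data, "scene_dataset")) data$component_digits[, 1]
  else stop("class-incremental slicing needs labelled data")
}

#' Sample curriculum slices
#'
#' Samples exemplar indices without replacement from a pool.  `static`
#' returns a single pooled subset of `n * slice_size` items; `continual`
#' and `reversed` return `n` pairwise-disjoint slices of `slice_size`;
#' `class_incremental` also returns `n` disjoint slices, but partitions the
#' ten digit classes into five stages of two previously unseen classes and
#' draws each slice only from its stage's classes.
#'
#' @param data a `glyph_corpus`, `scene_dataset`, or a plain pool size
#' @param regime slicing regime (see [schedule()])
#' @param n number of slices
#' @param slice_size exemplars per slice
#' @param seed integer seed; NULL uses the current RNG stream
#' @return list of integer index vectors
#' @export
make_slices <- function(data, regime, n, slice_size = 400L, seed = NULL) {
  pool <- pool_size_of(data)
  n <- as.integer(n); slice_size <- as.integer(slice_size)
  if (n * slice_size > pool)
    stop(sprintf("budget exceeded: %d slices of %d need %d exemplars but the pool has %d",
                 n, slice_size, n * slice_size, pool))
  run <- function() {
    if (n == 0L) return(list())
    if (regime == "static") {
      list(sample.int(pool, n * slice_size))
    } else if (regime %in% c("continual", "reversed")) {
      idx <- sample.int(pool, n * slice_size)
      split(idx, rep(seq_len(n), each = slice_size))
    } else if (regime == "class_incremental") {
      cls <- first_class_of(data)
      stage_of_slice <- floor((seq_len(n) - 1L) * 5L / n) + 1L
      used <- rep(FALSE, pool)
      lapply(seq_len(n), function(s) {
        stage_classes <- c(2L * stage_of_slice[s] - 2L, 2L * stage_of_slice[s] - 1L)
        avail <- which(!used & cls %in% stage_classes)
        if (length(avail) < slice_size)
          stop(sprintf("stage %d (classes %s) has only %d unused exemplars, needs %d",
                       stage_of_slice[s], paste(stage_classes, collapse = ","),
                       length(avail), slice_size))
        take <- sample(avail, slice_size)
        used[take] <<- TRUE
        take
      })
    } else stop(sprintf("unknown regime '%s'", regime))
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# Three epochs (by default) of minibatch Adam on one slice, reshuffling each
# epoch.  Uses the caller's RNG stream.
train_slice <- function(state, ds, idx, sched, head) {
  for (e in seq_len(sched$epochs_per_slice)) {
    ord <- sample(idx)
    starts <- seq(1L, length(ord), by = sched$batch_size)
    for (s in starts) {
      b <- ord[s:min(s + sched$batch_size - 1L, length(ord))]
      train_batch(state, ds$images[b, , , drop = FALSE],
                  ds$labels[b, , drop = FALSE], head)
    }
  }
  invisible(state)
}

slice_perf <- function(state, ds, idx) {
  unname(evaluate_model(state, subset_scenes(ds, idx)))
}

record_fi_pair <- function(state, fi_ctx) {
  if (is.null(fi_ctx)) return(c(NA_real_, NA_real_))
  f1 <- if (!is.null(fi_ctx$task1)) {
    fisher_information(state, fi_ctx$task1$images, "single_digit")$value
  } else NA_real_
  f2 <- if (!is.null(fi_ctx$task2)) {
    fisher_information(state, fi_ctx$task2$images, head_for(fi_ctx$task2$task_kind))$value
  } else NA_real_
  c(f1, f2)
}

trace_row <- function(phase, slice, stage, train_perf, holdout_perf, fi) {
  data.frame(phase = phase, slice = slice, stage = stage,
             train_perf = train_perf, holdout_perf = holdout_perf,
             fi_task1 = fi[1], fi_task2 = fi[2])
}

#' Run the pre-training (supporting task) phase
#'
#' Trains the single-digit head on the given slices in order, three epochs
#' per slice in shuffled minibatches.  After each slice the trace records
#' the slice's training accuracy, held-out accuracy on `eval_set`, and
#' (when the schedule asks for it) Fisher Information under both task
#' losses, probed on the upcoming slice of each task.
#'
#' @param state a `model_state` (mutated in place)
#' @param task1_data a single-digit `scene_dataset` pool
#' @param slices list of index vectors from [make_slices()]
#' @param sched a `schedule`
#' @param eval_set held-out single-digit `scene_dataset` (or NULL)
#' @param task2_probe main-task `scene_dataset` slice used as the Fisher
#'   probe for the task-2 loss (or NULL)
#' @return a trace data.frame, one row per slice
#' @export
run_pretraining <- function(state, task1_data, slices, sched,
                            eval_set = NULL, task2_probe = NULL) {
  if (length(slices) == 0) return(NULL)
  rows <- list()
  for (s in seq_along(slices)) {
    train_slice(state, task1_data, slices[[s]], sched, "single_digit")
    fi <- if (sched$record_fi) {
      probe1 <- slices[[min(s + 1L, length(slices))]]
      record_fi_pair(state, list(task1 = subset_scenes(task1_data, probe1),
                                 task2 = task2_probe))
    } else c(NA_real_, NA_real_)
    rows[[s]] <- trace_row(
      "task1", s, "pretrain",
      slice_perf(state, task1_data, slices[[s]]),
      if (is.null(eval_set)) NA_real_ else unname(evaluate_model(state, eval_set)),
      fi)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the main-task phase
#'
#' Trains the main-task head slice by slice and evaluates held-out
#' performance after every slice.
#'
#' @param state a `model_state` (mutated in place)
#' @param task2_data main-task `scene_dataset` pool
#' @param slices list of index vectors
#' @param sched a `schedule`
#' @param testset held-out main-task `scene_dataset`
#' @param task1_probe single-digit `scene_dataset` used as the Fisher probe
#'   for the task-1 loss (or NULL)
#' @return a trace data.frame, one row per slice
#' @export
run_main_training <- function(state, task2_data, slices, sched, testset,
                              task1_probe = NULL) {
  if (length(slices) == 0) return(NULL)
  head <- head_for(task2_data$task_kind)
  rows <- list()
  for (s in seq_along(slices)) {
    train_slice(state, task2_data, slices[[s]], sched, head)
    fi <- if (sched$record_fi) {
      probe2 <- slices[[min(s + 1L, length(slices))]]
      record_fi_pair(state, list(task1 = task1_probe,
                                 task2 = subset_scenes(task2_data, probe2)))
    } else c(NA_real_, NA_real_)
    rows[[s]] <- trace_row(
      "task2", s, "main",
      slice_perf(state, task2_data, slices[[s]]),
      unname(evaluate_model(state, testset)),
      fi)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Execute one complete curriculum run
#'
#' Builds the network, samples the slices for both phases, runs the
#' pre-training and main phases in the order the regime dictates
#' (`reversed` trains the main task first and re-evaluates it once the
#' supporting task has been learned), and returns the full record.
#' Everything is a pure function of `sched$seed` and the data.
#'
#' @param spec a `model_spec`
#' @param sched a `schedule` (its `n_pretrain`/`n_main` set the slice counts)
#' @param data list with `task1_pool`, `task2_pool` (scene datasets),
#'   `task1_eval`, `task2_eval` (held-out scene datasets; `task1_eval` may
#'   be NULL)
#' @return an object of class `run_record`: list with `seed`, `regime`,
#'   `n_pretrain`, `schedule`, `trace`, `final_performance`
#' @export
run_curriculum <- function(spec, sched, data) {
  withr::with_seed(sched$seed, {
    state <- build_network(spec, seed = sample.int(.Machine$integer.max, 1))
    slicing_regime <- if (sched$regime == "static") "static" else sched$regime
    t1_slices <- if (sched$n_pretrain > 0)
      make_slices(data$task1_pool, slicing_regime, sched$n_pretrain, sched$slice_size)
    else list()
    # the main task is always presented as disjoint consecutive slices
    t2_slices <- make_slices(data$task2_pool, "continual", sched$n_main, sched$slice_size)
    fi_probe2 <- if (sched$record_fi) subset_scenes(data$task2_pool, t2_slices[[1]]) else NULL
    fi_probe1 <- if (sched$record_fi && sched$n_pretrain > 0)
      subset_scenes(data$task1_pool, t1_slices[[length(t1_slices)]]) else NULL

    if (sched$regime == "reversed") {
      tr2 <- run_main_training(state, data$task2_pool, t2_slices, sched,
                               data$task2_eval, task1_probe = fi_probe1)
      tr1 <- if (length(t1_slices))
        run_pretraining(state, data$task1_pool, t1_slices, sched,
                        eval_set = data$task1_eval, task2_probe = fi_probe2)
      else NULL
      final_row <- trace_row("task2", sched$n_main, "final", NA_real_,
                             unname(evaluate_model(state, data$task2_eval)),
                             c(NA_real_, NA_real_))
      trace <- rbind(tr2, tr1, final_row)
    } else {
      tr1 <- if (length(t1_slices))
        run_pretraining(state, data$task1_pool, t1_slices, sched,
                        eval_set = data$task1_eval, task2_probe = fi_probe2)
      else NULL
      tr2 <- run_main_training(state, data$task2_pool, t2_slices, sched,
                               data$task2_eval, task1_probe = fi_probe1)
      trace <- rbind(tr1, tr2)
    }
    rownames(trace) <- NULL
    t2rows <- trace[trace$phase == "task2", ]
    structure(
      list(seed = sched$seed, regime = sched$regime,
           n_pretrain = sched$n_pretrain, schedule = sched, trace = trace,
           final_performance = t2rows$holdout_perf[nrow(t2rows)],
           steps = step_count(state), state = state),
      class = "run_record"
    )
  })
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> regime %s, n_pretrain %d, seed %d, final task-2 %.4f\n",
              x$regime, x$n_pretrain, x$seed, x$final_performance))
  invisible(x)
}

#' Run a replicated curriculum grid
#'
#' One run per (regime, n_pretrain, replicate).  Replicate k uses seed
#' `base_seed + k * 10007`, so replicates are deterministic and paired
#' across grid cells.
#'
#' @param spec a `model_spec`
#' @param data experiment data as for [run_curriculum()]
#' @param n_values integer vector of pre-training amounts
#' @param regimes character vector of regimes
#' @param replicates replicate runs per cell
#' @param base_seed integer base seed
#' @param ... further arguments passed to [schedule()] (slice_size, n_main,
#'   record_fi, ...)
#' @return an object of class `run_records` (list of `run_record`)
#' @export
run_grid <- function(spec, data, n_values, regimes = "continual",
                     replicates = 4L, base_seed = 1L, ...) {
  records <- list()
  for (regime in regimes)
    for (n in n_values)
      for (k in seq_len(replicates)) {
        sched <- schedule(regime = regime, n_pretrain = n,
                          seed = as.integer(base_seed + k * 10007L), ...)
        records[[length(records) + 1L]] <- run_curriculum(spec, sched, data)
      }
  structure(records, class = "run_records")
}

#' Mean/sd of final main-task performance per pre-training amount
#'
#' @param records a `run_records`
#' @return data.frame with columns `regime`, `n_pretrain`, `mean`, `sd`, `n`
#' @export
final_performance_by_n <- function(records) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(regime = r$regime, n_pretrain = r$n_pretrain,
               final = r$final_performance)))
  out <- do.call(rbind, lapply(split(df, list(df$regime, df$n_pretrain), drop = TRUE),
    function(g) data.frame(regime = g$regime[1], n_pretrain = g$n_pretrain[1],
                           mean = mean(g$final), sd = stats::sd(g$final),
                           n = nrow(g))))
  out <- out[order(out$regime, out$n_pretrain), ]
  rownames(out) <- NULL
  out
}
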