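#' Optimal switching window from a performance grid
#'
#' The optimal switching window is the set of pre-training amounts whose
#' mean final main-task performance reaches the top decile of the means
#' observed over all regimes of training, i.e. is at least the 90th
#' percentile (linear interpolation) of those means.  The smallest element
#' is the optimal switching moment.  The window always contains the argmax
#' and is invariant to monotone relabelling of the pre-training amounts.
#'
#' @param means named numeric vector: names are pre-training amounts `n`,
#'   values are mean final performances
#' @return list with `window` (numeric vector of n), `moment` (smallest n in
#'   the window) and `threshold`
#' @export
optimal_switch_window <- function(means) {
  if (length(means) == 0) stop("empty grid")
  if (is.null(names(means))) names(means) <- seq_along(means) - 1L
  thr <- unname(stats::quantile(means, 0.9, type = 7))
  window <- as.numeric(names(means)[means >= thr - 1e-12])
  list(window = sort(window), moment = min(window), threshold = thr)
}

task2_rows <- function(trace) trace[trace$phase == "task2" & trace$stage != "final", ]

#' Initial competence on the main task
#'
#' Held-out main-task performance after its first training slice.
#'
#' @param trace a trace data.frame from a curriculum run
#' @return scalar performance
#' @export
initial_competence <- function(trace) {
  t2 <- task2_rows(trace)
  if (nrow(t2) == 0) stop("trace has no main-task entries")
  t2$holdout_perf[1]
}

#' Prediction gain (learning progress) at a step
#'
#' The change in held-out performance across one training slice: the gain at
#' step `i` is `performance[i + 1] - performance[i]` over the phase's
#' per-slice performances, so step 1 is the first transition and valid steps
#' run 1..(number of slices - 1).
#'
#' @param trace a trace data.frame
#' @param phase "task1" or "task2"
#' @param step_index transition index in 1..(n slices - 1)
#' @return scalar gain
#' @export
prediction_gain <- function(trace, phase = c("task2", "task1"), step_index) {
  phase <- match.arg(phase)
  p <- trace[trace$phase == phase & trace$stage != "final", "holdout_perf"]
  if (step_index < 1 || step_index > length(p) - 1)
    stop(sprintf("step_index must be in 1..%d", length(p) - 1))
  p[step_index + 1] - p[step_index]
}

#' Diagonal empirical Fisher Information of the weights
#'
#' For every example, a label is sampled from the model's own predictive
#' distribution (categorical for the softmax heads; 20 independent
#' Bernoullis for the magnitude head) and the gradient of the log-likelihood
#' of that label is computed for every weight receiving gradient under the
#' chosen loss.  The per-weight mean squared gradient over the sample is
#' averaged over weights to give a single non-negative value, invariant to
#' sample order, batch partitioning and weight relabelling.
#'
#' @param state a `model_state` (or a [logistic_unit()] reference model)
#' @param sample an n x H x W image array or dataset (for the logistic
#'   model, a numeric input vector)
#' @param head loss to differentiate: "single_digit", "parity_sum" or
#'   "magnitude_sum" (ignored for the logistic model)
#' @return an object of class `fi_estimate`: list with `value`, `head`,
#'   `n_examples`, `n_weights`
#' @export
fisher_information <- function(state, sample, head) UseMethod("fisher_information")

#' @export
fisher_information.model_state <- function(state, sample, head) {
  imgs <- as_image_array(sample)
  n <- dim(imgs)[1]
  if (n < 1) stop("Fisher Information needs a non-empty sample")
  k <- if (head == "magnitude_sum") 20L else 1L
  u <- runif(n * k)
  est <- cn_fisher(state$ptr, imgs, head, u)
  structure(list(value = est$value, head = head,
                 n_examples = est$n_examples, n_weights = est$n_weights),
            class = "fi_estimate")
}

#' @export
print.fi_estimate <- function(x, ...) {
  cat(sprintf("<fi_estimate> %.6g (head %s, %d examples, %d weights)\n",
              x$value, x$head, x$n_examples, x$n_weights))
  invisible(x)
}

#' A one-weight Bernoulli-logistic reference model
#'
#' A minimal model -- P(y = 1 | x) = logistic(w x) with a single weight --
#' whose Fisher Information has the closed form E\[p(1-p)x^2\].  Used to
#' validate the empirical Fisher estimator against an analytic target.
#'
#' @param w the weight
#' @return an object of class `logistic_unit`
#' @export
logistic_unit <- function(w) structure(list(w = w), class = "logistic_unit")

#' @export
fisher_information.logistic_unit <- function(state, sample, head = NULL) {
  x <- as.numeric(sample)
  if (length(x) < 1) stop("Fisher Information needs a non-empty sample")
  p <- 1 / (1 + exp(-state$w * x))
  y <- as.numeric(runif(length(x)) < p)
  g2 <- ((y - p) * x)^2        # squared gradient of the Bernoulli log-likelihood
  structure(list(value = mean(g2), head = "logistic", n_examples = length(x),
                 n_weights = 1L),
            class = "fi_estimate")
}

fi_at_switch <- function(record) {
  t1 <- record$trace[record$trace$phase == "task1", ]
  if (nrow(t1) == 0) return(NA_real_)
  t1$fi_task1[nrow(t1)]
}

#' Correlation between Fisher Information at switching and final performance
#'
#' Pools (FI-at-switch, final main-task performance) pairs across runs and
#' computes the Pearson correlation with a two-sided p-value.  FI at
#' switching is the task-1 Fisher Information recorded on the last
#' pre-training slice before the first main-task slice.
#'
#' @param records a `run_records` (runs must have been traced with
#'   `record_fi = TRUE` and `n_pretrain >= 1`), or a data.frame with columns
#'   `fi` and `final`
#' @return list with `r`, `p_value`, `n`
#' @export
fi_performance_correlation <- function(records) {
  df <- if (is.data.frame(records)) records else {
    do.call(rbind, lapply(records, function(r)
      data.frame(fi = fi_at_switch(r), final = r$final_performance)))
  }
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 3) stop("need at least 3 runs with FI at switching")
  if (stats::sd(df$fi) == 0 || stats::sd(df$final) == 0)
    stop("degenerate input: zero variance in FI or in final performance")
  ct <- stats::cor.test(df$fi, df$final, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(df))
}

#' Fisher Information for the two candidate next steps
#'
#' After some amount of pre-training, compares the information gain from
#' the two possible continuations: one more supporting-task slice versus
#' the first main-task slice.  Both estimates are computed on deep copies,
#' so the run state is not mutated.
#'
#' @param state a `model_state`
#' @param next_task1_slice single-digit `scene_dataset` slice
#' @param first_task2_slice main-task `scene_dataset` slice
#' @return list with `fi_task1`, `fi_task2` (both `fi_estimate`)
#' @export
fi_next_step_comparison <- function(state, next_task1_slice, first_task2_slice) {
  s1 <- clone_model(state)
  s2 <- clone_model(state)
  list(fi_task1 = fisher_information(s1, next_task1_slice, "single_digit"),
       fi_task2 = fisher_information(s2, first_task2_slice,
                                     head_for(first_task2_slice$task_kind)))
}

#' Supporting-task performance thresholds as switching rules
#'
#' For each threshold, the first pre-training slice at which held-out
#' supporting-task performance reaches it; thresholds never crossed are
#' flagged `reached = FALSE` rather than raising an error.
#'
#' @param trace a trace data.frame (its "task1" rows are scanned)
#' @param thresholds numeric vector of performance thresholds
#' @return data.frame with columns `threshold`, `slice`, `reached`
#' @export
performance_threshold_probe <- function(trace, thresholds) {
  p <- trace[trace$phase == "task1", "holdout_perf"]
  out <- lapply(thresholds, function(th) {
    hit <- which(p >= th)
    data.frame(threshold = th,
               slice = if (length(hit)) hit[1] else NA_integer_,
               reached = length(hit) > 0)
  })
  do.call(rbind, out)
}

#' Pairwise comparison of Fisher Information across pre-training amounts
#'
#' Summarises FI samples per group (mean, StDev) and runs Welch two-sample
#' t-tests on every pair of groups, with raw (uncorrected) p-values.
#'
#' @param groups named list of numeric FI samples, one per pre-training
#'   amount
#' @return list with `summary` (group, n, mean, sd) and `pairwise`
#'   (group1, group2, statistic, p_value)
#' @export
fi_group_difference <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs at least 2 values")
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  summary <- data.frame(group = nm,
                        n = vapply(groups, length, 1L),
                        mean = vapply(groups, mean, 1.0),
                        sd = vapply(groups, stats::sd, 1.0),
                        row.names = NULL)
  pairs <- utils::combn(seq_along(groups), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (stats::sd(groups[[i1]]) == 0 && stats::sd(groups[[i2]]) == 0) {
      # identical constant groups are maximally indistinguishable
      if (isTRUE(all.equal(mean(groups[[i1]]), mean(groups[[i2]]))))
        return(data.frame(group1 = nm[i1], group2 = nm[i2], statistic = 0, p_value = 1))
      stop(sprintf("degenerate groups '%s' and '%s' (zero variance, different means)",
                   nm[i1], nm[i2]))
    }
    tt <- stats::t.test(groups[[i1]], groups[[i2]], var.equal = FALSE)
    data.frame(group1 = nm[i1], group2 = nm[i2],
               statistic = unname(tt$statistic), p_value = tt$p.value)
  }))
  list(summary = summary, pairwise = pairwise)
}
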