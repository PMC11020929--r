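#' Scaled-down scenario fixtures for the studied phenomena
#'
#' Each scenario packages a synthetic glyph corpus, the task datasets, the
#' model specification and the schedule grid that together embody one of
#' the studied training phenomena at desk scale, with the qualitative
#' outcome it is expected to show.  Two scales are provided: `"small"`
#' (slice 150, 6 main-task slices, 300-scene evaluation set; sized so a
#' whole scenario grid trains in a few minutes on one CPU) and `"standard"`
#' (the schedule defaults: slice 400, 8 main-task slices, 1000-scene
#' evaluation set).
#'
#' Scenarios:
#' \describe{
#'   \item{no_pretrain_chance}{zero supporting-task pre-training; parity
#'     performance is expected to stay at chance.}
#'   \item{curriculum_benefit}{moderate pre-training (4 slices); parity
#'     performance is expected to rise well above chance.}
#'   \item{reversed_order}{main task first, supporting task afterwards;
#'     expected to stay at chance.}
#'   \item{overtraining_detriment}{grid over 0/4/12 continual pre-training
#'     slices; the largest amount is expected to underperform the best
#'     intermediate amount.}
#'   \item{magnitude_no_pretrain}{magnitude-encoded sum task under static
#'     pre-training amounts full/half/zero; expected learnable without
#'     pre-training, with differences within run-to-run spread.}
#'   \item{class_incremental_forgetting}{pre-training slices introduce two
#'     unseen digit classes per stage; single-digit representations never
#'     stabilise and parity performance is expected to stay near chance.}
#' }
#'
#' @param name scenario name (see above)
#' @param seed integer seed; datasets and run seeds derive from it
#' @param scale "small" or "standard"
#' @return an object of class `scenario`: list with `spec`, `data`,
#'   `n_values`, `regimes`, `replicates`, `schedule_args`, `expected`, and
#'   a `config` block recording the sizes
#' @export
make_scenario <- function(name = c("no_pretrain_chance", "curriculum_benefit",
                                   "reversed_order", "overtraining_detriment",
                                   "magnitude_no_pretrain",
                                   "class_incremental_forgetting"),
                          seed = 1L, scale = c("small", "standard")) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  seed <- as.integer(seed)
  sc <- if (scale == "small") {
    list(n_per_class = 500L, n_writers = 25L, slice = 150L, n_main = 6L,
         eval2 = 300L, eval1 = 150L, replicates = 4L)
  } else {
    list(n_per_class = 1300L, n_writers = 50L, slice = 400L, n_main = 8L,
         eval2 = 1000L, eval1 = 400L, replicates = 4L)
  }

  task <- if (name == "magnitude_no_pretrain") "magnitude_sum" else "parity_sum"
  regime <- switch(name,
    reversed_order = "reversed",
    magnitude_no_pretrain = "static",
    class_incremental_forgetting = "class_incremental",
    "continual")
  n_values <- switch(name,
    no_pretrain_chance = 0L,
    curriculum_benefit = 4L,
    reversed_order = 4L,
    overtraining_detriment = c(0L, 4L, 12L),
    magnitude_no_pretrain = if (scale == "small") c(0L, 3L, 6L) else c(0L, 4L, 8L),
    class_incremental_forgetting = 5L)
  expected <- switch(name,
    no_pretrain_chance = "held-out parity accuracy stays at chance (0.5)",
    curriculum_benefit = "final parity accuracy clearly exceeds the no-pretraining level",
    reversed_order = "final parity accuracy stays within a few points of chance",
    overtraining_detriment = "the largest pre-training amount underperforms the best intermediate amount",
    magnitude_no_pretrain = "final sum-prediction error differs across pre-training amounts by less than the run-to-run spread",
    class_incremental_forgetting = "parity accuracy stays near chance; staged classes are forgotten")

  corpus <- make_glyph_corpus(sc$n_per_class, sc$n_writers, seed = seed)
  parts <- split_corpus(corpus, 0.2, seed = seed + 1L)
  max_n <- max(n_values)
  task1_pool <- if (max_n > 0)
    build_task_dataset(parts$train, "single_digit", max_n * sc$slice, seed = seed + 2L)
  else NULL
  task2_pool <- build_task_dataset(parts$train, task, sc$n_main * sc$slice, seed = seed + 3L)
  task1_eval <- if (max_n > 0)
    build_task_dataset(parts$holdout, "single_digit", sc$eval1, seed = seed + 4L)
  else NULL
  task2_eval <- build_task_dataset(parts$holdout, task, sc$eval2, seed = seed + 5L,
                                   pair_sampling = "digit_uniform")

  spec <- model_spec(n_conv = 2L, head = task)
  steps_per_run <- (n_values + sc$n_main) * 3L * ceiling(sc$slice / 32)
  budget <- sum(steps_per_run) * sc$replicates
  stopifnot(budget <= 60000)   # desk-scale ceiling on total gradient steps

  structure(
    list(name = name, scale = scale, seed = seed, spec = spec,
         data = list(task1_pool = task1_pool, task2_pool = task2_pool,
                     task1_eval = task1_eval, task2_eval = task2_eval),
         n_values = n_values, regimes = regime, replicates = sc$replicates,
         schedule_args = list(slice_size = sc$slice, n_main = sc$n_main,
                              epochs_per_slice = 3L, batch_size = 32L,
                              eval_size = sc$eval2),
         expected = expected,
         config = c(sc, list(corpus_size = 10L * sc$n_per_class,
                             gradient_step_budget = budget))),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s (%s scale): regime %s, n in {%s}, %d replicates\n",
              x$name, x$scale, x$regimes, paste(x$n_values, collapse = ", "),
              x$replicates))
  cat("  expectation:", x$expected, "\n")
  invisible(x)
}

#' Run a scenario grid end to end
#'
#' @param scn a `scenario` from [make_scenario()]
#' @param replicates override the scenario's replicate count
#' @param record_fi record Fisher Information traces (default FALSE)
#' @return a `run_records`
#' @export
run_scenario <- function(scn, replicates = NULL, record_fi = FALSE) {
  if (!inherits(scn, "scenario")) stop("scn must be a scenario")
  do.call(run_grid, c(
    list(spec = scn$spec, data = scn$data, n_values = scn$n_values,
         regimes = scn$regimes,
         replicates = if (is.null(replicates)) scn$replicates else replicates,
         base_seed = scn$seed, record_fi = record_fi),
    scn$schedule_args))
}
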