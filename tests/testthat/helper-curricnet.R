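# Shared fixtures.  Expensive objects are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

tiny_corpus <- function() cached("tiny_corpus", make_glyph_corpus(30, 5, seed = 11))

# A small-input, few-filter network spec for structural/bookkeeping tests.
tiny_spec <- function(head = "parity_sum", n_conv = 2L)
  model_spec(n_conv = n_conv, head = head, conv_filters = c(4L, 3L, 3L)[seq_len(n_conv)],
             input_size = 28L)

# A synthetic 28x28 "scene" dataset (random images, valid labels) for
# schedule bookkeeping tests where image content is irrelevant.
fake_scenes <- function(n, task_kind = "parity_sum", seed = 5, size = 28L) {
  withr::with_seed(seed, {
    d1 <- sample(0:9, n, replace = TRUE)
    d2 <- sample(0:9, n, replace = TRUE)
    labels <- switch(task_kind,
      single_digit = { m <- matrix(0, n, 10); m[cbind(seq_len(n), d1 + 1)] <- 1; m },
      parity_sum = { odd <- (d1 + d2) %% 2; cbind(even = 1 - odd, odd = odd) },
      magnitude_sum = outer(d1 + d2, 1:20, ">=") * 1)
    structure(
      list(images = array(runif(n * size * size), dim = c(n, size, size)),
           task_kind = task_kind, labels = labels,
           component_digits = cbind(d1 = d1, d2 = if (task_kind == "single_digit") NA else d2),
           placements = NULL),
      class = "scene_dataset")
  })
}

# Scenario fixtures and grids shared across test files (each grid trains
# for minutes; computed on first use, then reused).
scenario_of <- function(name) cached(paste0("scn_", name),
  make_scenario(name, seed = 101))

chance_runs <- function() cached("chance_runs",
  run_scenario(scenario_of("no_pretrain_chance")))

benefit_runs <- function() cached("benefit_runs",
  run_scenario(scenario_of("curriculum_benefit"), replicates = 3))

reversed_runs <- function() cached("reversed_runs",
  run_scenario(scenario_of("reversed_order"), replicates = 2))

magnitude_runs <- function() cached("magnitude_runs", {
  scn <- scenario_of("magnitude_no_pretrain")
  # zero- and full-pretraining arms
  run_grid(scn$spec, scn$data, n_values = range(scn$n_values),
           regimes = scn$regimes, replicates = 3L,
           base_seed = scn$seed,
           slice_size = scn$schedule_args$slice_size,
           n_main = scn$schedule_args$n_main,
           eval_size = scn$schedule_args$eval_size)
})

final_means <- function(records) {
  agg <- final_performance_by_n(records)
  stats::setNames(agg$mean, agg$n_pretrain)
}
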