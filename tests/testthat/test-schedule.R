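test_that("continual slices are disjoint, sized, and exhaust the budget", {
  sl <- make_slices(1000, "continual", 4, slice_size = 250, seed = 1)
  expect_length(sl, 4)
  expect_true(all(lengths(sl) == 250))
  all_idx <- unlist(sl)
  expect_false(any(duplicated(all_idx)))        # sampling without replacement
  expect_setequal(all_idx, 1:1000)              # 4 x 250 covers the pool
  # pairwise intersections are empty
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(sl[[i]], sl[[j]]), 0)
  expect_identical(sl, make_slices(1000, "continual", 4, slice_size = 250, seed = 1))
})

test_that("static slicing pools the budget into one subset", {
  sl <- make_slices(1000, "static", 2, slice_size = 100, seed = 2)
  expect_length(sl, 1)
  expect_length(sl[[1]], 200)
  expect_false(any(duplicated(sl[[1]])))
})

test_that("slice budgets are enforced", {
  expect_error(make_slices(100, "continual", 2, slice_size = 60), "budget exceeded")
  expect_error(schedule("continual", n_pretrain = 30), "0..24")
})

test_that("class-incremental slices introduce classes stage by stage", {
  co <- tiny_corpus()   # 30 per class
  sl <- make_slices(co, "class_incremental", 5, slice_size = 40, seed = 3)
  expect_length(sl, 5)
  seen <- integer(0)
  for (s in 1:5) {
    cls <- sort(unique(co$labels[sl[[s]]]))
    expect_equal(cls, c(2 * s - 2, 2 * s - 1))  # exactly the two new classes
    expect_length(intersect(cls, seen), 0)
    seen <- c(seen, cls)
  }
  expect_setequal(seen, 0:9)
})

test_that("training bookkeeping matches the closed-form gradient-step count", {
  spec <- tiny_spec()
  pool <- fake_scenes(300, "single_digit")
  st <- build_network(spec, seed = 1)
  sched <- schedule("continual", n_pretrain = 2, slice_size = 100,
                    batch_size = 32, seed = 1)
  sl <- make_slices(300, "continual", 2, slice_size = 100, seed = 1)
  tr <- withr::with_seed(2, run_pretraining(st, pool, sl, sched))
  expect_equal(nrow(tr), 2)                     # one record per slice
  expect_equal(tr$phase, rep("task1", 2))
  # n * epochs * ceil(slice/batch) optimizer steps
  expect_equal(step_count(st), 2 * 3 * ceiling(100 / 32))

  # n_pretrain = 0: state untouched, empty trace
  st0 <- build_network(spec, seed = 1)
  tr0 <- run_pretraining(st0, pool, list(), sched)
  expect_null(tr0)
  expect_equal(step_count(st0), 0)
})

test_that("a full curriculum run records both phases and its final performance", {
  spec <- tiny_spec()
  data <- list(task1_pool = fake_scenes(120, "single_digit", seed = 1),
               task2_pool = fake_scenes(120, "parity_sum", seed = 2),
               task1_eval = fake_scenes(40, "single_digit", seed = 3),
               task2_eval = fake_scenes(40, "parity_sum", seed = 4))
  sched <- schedule("continual", n_pretrain = 2, n_main = 3, slice_size = 40,
                    eval_size = 40, seed = 7)
  rec <- run_curriculum(spec, sched, data)
  expect_s3_class(rec, "run_record")
  expect_equal(sum(rec$trace$phase == "task1"), 2)
  expect_equal(sum(rec$trace$phase == "task2"), 3)
  t2 <- rec$trace[rec$trace$phase == "task2", ]
  expect_equal(rec$final_performance, t2$holdout_perf[nrow(t2)])
  expect_true(all(rec$trace$holdout_perf >= 0 & rec$trace$holdout_perf <= 1))
  # reproducible end to end
  rec2 <- run_curriculum(spec, sched, data)
  expect_identical(rec$trace, rec2$trace)
  expect_identical(rec$final_performance, rec2$final_performance)
})

test_that("weights keep changing during the main phase (never frozen)", {
  spec <- tiny_spec()
  data <- list(task1_pool = NULL,
               task2_pool = fake_scenes(80, "parity_sum", seed = 2),
               task1_eval = NULL,
               task2_eval = fake_scenes(40, "parity_sum", seed = 4))
  sched <- schedule("continual", n_pretrain = 0, n_main = 2, slice_size = 40, seed = 8)
  st <- build_network(spec, seed = 8)
  w <- get_weights(st)
  w$dense2_b[] <- 1   # bias the narrow rectified head into its active region
  set_weights(st, w)
  sl <- make_slices(80, "continual", 2, slice_size = 40, seed = 8)
  w0 <- get_weights(st)
  withr::with_seed(8, curricnet:::train_slice(st, data$task2_pool, sl[[1]], sched, "parity_sum"))
  w1 <- get_weights(st)
  withr::with_seed(9, curricnet:::train_slice(st, data$task2_pool, sl[[2]], sched, "parity_sum"))
  w2 <- get_weights(st)
  expect_false(identical(w0$conv1_W, w1$conv1_W))
  expect_false(identical(w1$conv1_W, w2$conv1_W))
  expect_false(identical(w1$out_W, w2$out_W))
})

test_that("the reversed regime trains the main task first and re-evaluates it last", {
  spec <- tiny_spec()
  data <- list(task1_pool = fake_scenes(80, "single_digit", seed = 1),
               task2_pool = fake_scenes(80, "parity_sum", seed = 2),
               task1_eval = fake_scenes(40, "single_digit", seed = 3),
               task2_eval = fake_scenes(40, "parity_sum", seed = 4))
  sched <- schedule("reversed", n_pretrain = 2, n_main = 2, slice_size = 40, seed = 9)
  rec <- run_curriculum(spec, sched, data)
  phases <- rec$trace$phase
  expect_equal(phases[1:2], rep("task2", 2))    # main task first
  expect_equal(phases[3:4], rep("task1", 2))
  expect_equal(rec$trace$stage[nrow(rec$trace)], "final")
  expect_equal(rec$final_performance, rec$trace$holdout_perf[nrow(rec$trace)])
})

test_that("run_grid produces one deterministic record per cell and replicate", {
  spec <- tiny_spec()
  data <- list(task1_pool = fake_scenes(120, "single_digit", seed = 1),
               task2_pool = fake_scenes(80, "parity_sum", seed = 2),
               task1_eval = NULL,
               task2_eval = fake_scenes(40, "parity_sum", seed = 4))
  recs <- run_grid(spec, data, n_values = c(0, 2), replicates = 2,
                   base_seed = 3, slice_size = 40, n_main = 2, eval_size = 40)
  expect_s3_class(recs, "run_records")
  expect_length(recs, 4)
  expect_equal(vapply(recs, function(r) r$seed, 1.0),
               c(3 + 10007, 3 + 2 * 10007, 3 + 10007, 3 + 2 * 10007))
  agg <- final_performance_by_n(recs)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$n, c(2L, 2L))
  # mean/sd match hand arithmetic
  f0 <- vapply(recs[1:2], function(r) r$final_performance, 1.0)
  expect_equal(agg$mean[agg$n_pretrain == 0], sum(f0) / 2)
  expect_equal(agg$sd[agg$n_pretrain == 0],
               sqrt(sum((f0 - mean(f0))^2) / 1))
})
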