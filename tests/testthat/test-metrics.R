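# Hand/oracle computations for the switching metrics.

test_that("the optimal switching window is the top decile of observed means", {
  means <- c("0" = 0.50, "4" = 0.60, "8" = 0.90, "12" = 0.91, "16" = 0.88)
  # hand oracle: sorted means .50 .60 .88 .90 .91; the 90th percentile by
  # linear interpolation is .90 + 0.6 * (.91 - .90) = 0.906
  res <- optimal_switch_window(means)
  expect_equal(res$threshold, 0.906)
  expect_equal(res$window, 12)
  expect_equal(res$moment, 12)

  allsame <- c("0" = 0.7, "4" = 0.7, "8" = 0.7)
  expect_equal(optimal_switch_window(allsame)$window, c(0, 4, 8))
  expect_equal(optimal_switch_window(c("6" = 0.4))$window, 6)
  expect_error(optimal_switch_window(numeric(0)), "empty")
})

test_that("the window contains the argmax and survives monotone relabelling", {
  withr::with_seed(10, {
    for (rep in 1:20) {
      n <- sample(3:12, 1)
      means <- stats::setNames(runif(n), sort(sample(0:24, n)))
      win <- optimal_switch_window(means)$window
      expect_true(as.numeric(names(which.max(means))) %in% win)
      relab <- means
      names(relab) <- as.numeric(names(means)) * 3 + 1   # monotone map
      win2 <- optimal_switch_window(relab)$window
      expect_equal(win2, sort(as.numeric(names(means))[
        as.numeric(names(means)) %in% win] * 3 + 1))
    }
  })
})

fake_trace <- function(t2_perf, t1_perf = numeric(0)) {
  empty <- data.frame(phase = character(0), slice = integer(0), stage = character(0),
                      train_perf = numeric(0), holdout_perf = numeric(0),
                      fi_task1 = numeric(0), fi_task2 = numeric(0))
  if (length(t2_perf) == 0 && length(t1_perf) == 0) return(empty)
  rbind(
    if (length(t1_perf))
      data.frame(phase = "task1", slice = seq_along(t1_perf), stage = "pretrain",
                 train_perf = NA, holdout_perf = t1_perf,
                 fi_task1 = NA, fi_task2 = NA),
    if (length(t2_perf))
      data.frame(phase = "task2", slice = seq_along(t2_perf), stage = "main",
                 train_perf = NA, holdout_perf = t2_perf,
                 fi_task1 = NA, fi_task2 = NA)
  )
}

test_that("initial competence reads the first main-task slice", {
  tr <- fake_trace(c(0.52, 0.70, 0.80))
  expect_equal(initial_competence(tr), 0.52)
  expect_equal(initial_competence(fake_trace(0.61)), 0.61)
  expect_error(initial_competence(fake_trace(numeric(0))), "no main-task")
})

test_that("prediction gain equals independent first differences", {
  tr <- fake_trace(c(0.5, 0.7))
  expect_equal(prediction_gain(tr, "task2", 1), 0.2)
  const <- fake_trace(rep(0.6, 5))
  for (i in 1:4) expect_equal(prediction_gain(const, "task2", i), 0)
  withr::with_seed(3, {
    p <- runif(8)
    tr <- fake_trace(p)
    # independent loop oracle
    for (i in 1:7) expect_equal(prediction_gain(tr, "task2", i), p[i + 1] - p[i])
  })
  expect_error(prediction_gain(tr, "task2", 0), "step_index")
  expect_error(prediction_gain(tr, "task2", 8), "step_index")
})

test_that("the FI estimator matches the closed-form logistic Fisher Information", {
  withr::with_seed(42, {
    x <- runif(1e4, -2, 2)
    m <- logistic_unit(0.7)
    est <- fisher_information(m, x)
    p <- 1 / (1 + exp(-0.7 * x))
    closed <- mean(p * (1 - p) * x^2)     # analytic Fisher of the model
    expect_equal(est$value, closed, tolerance = 0.02)
    expect_gte(est$value, 0)
  })
})

test_that("network FI equals a per-example looped oracle and is order invariant", {
  st <- build_network(tiny_spec(), seed = 2)
  ds <- fake_scenes(10, "parity_sum", seed = 3)
  u <- withr::with_seed(4, runif(10))
  batched <- curricnet:::cn_fisher(st$ptr, ds$images, "parity_sum", u)
  # brute force: one example at a time, averaging the per-example values
  looped <- vapply(1:10, function(i)
    curricnet:::cn_fisher(st$ptr, ds$images[i, , , drop = FALSE],
                          "parity_sum", u[i])$value, 1.0)
  expect_equal(batched$value, mean(looped), tolerance = 1e-6)
  # permutation of examples together with their label draws
  perm <- c(7, 2, 9, 1, 5, 10, 3, 4, 8, 6)
  permuted <- curricnet:::cn_fisher(st$ptr, ds$images[perm, , , drop = FALSE],
                                    "parity_sum", u[perm])
  expect_equal(permuted$value, batched$value, tolerance = 1e-6)
  # two-part partition recombines to the full estimate
  a <- curricnet:::cn_fisher(st$ptr, ds$images[1:4, , , drop = FALSE], "parity_sum", u[1:4])
  b <- curricnet:::cn_fisher(st$ptr, ds$images[5:10, , , drop = FALSE], "parity_sum", u[5:10])
  expect_equal((4 * a$value + 6 * b$value) / 10, batched$value, tolerance = 1e-6)
})

test_that("network FI matches finite-difference log-likelihood gradients", {
  # independent oracle: numerically differentiate the log-likelihood of the
  # sampled labels with respect to every weight of a tiny network
  spec <- model_spec(conv_filters = c(2L, 2L), input_size = 12L)
  st <- build_network(spec, seed = 5)
  ds <- fake_scenes(3, "parity_sum", seed = 6, size = 12L)
  u <- rep(0, 3)  # label = first class the cumulative softmax reaches
  est <- curricnet:::cn_fisher(st$ptr, ds$images, "parity_sum", u)
  y <- rep(1L, 3)   # u = 0 always samples the first class
  w <- get_weights(st)
  loglik <- function(weights) {
    set_weights(st, weights)
    pr <- forward_pass(st, ds$images, "parity_sum")
    vapply(1:3, function(i) log(pr[i, y[i]]), 1.0)
  }
  h <- 1e-3
  sumsq <- 0; nw <- 0
  for (tn in names(w)) {
    for (j in seq_along(w[[tn]])) {
      wp <- w; wp[[tn]][j] <- wp[[tn]][j] + h
      wm <- w; wm[[tn]][j] <- wm[[tn]][j] - h
      g <- (loglik(wp) - loglik(wm)) / (2 * h)   # per-example FD gradients
      sumsq <- sumsq + sum(g^2)
      nw <- nw + 1
    }
  }
  set_weights(st, w)
  expect_equal(est$value, sumsq / 3 / nw, tolerance = 5e-3)
  expect_equal(est$n_weights, nw)
})

test_that("FI is zero when the output does not depend on the weights", {
  # saturated rectifiers: all dense-10 activations are clamped at zero, so
  # the parity-head softmax is constant in the trunk weights
  st <- build_network(tiny_spec(), seed = 7)
  w <- get_weights(st)
  w$dense1_b[] <- -100           # rectifiers clamp the trunk to zero
  w$dense2_W[] <- 0; w$dense2_b[] <- 0
  w$out_W[] <- 0; w$out_b[] <- c(40, -40)  # output saturates at the sampled class
  set_weights(st, w)
  ds <- fake_scenes(5, "parity_sum", seed = 8)
  est <- fisher_information(st, ds$images, "parity_sum")
  expect_lt(est$value, 1e-12)
})

test_that("Pearson correlation matches the closed formula and flags degeneracy", {
  df <- data.frame(fi = c(1, 2, 3), final = c(2, 4, 5))
  res <- fi_performance_correlation(df)
  # closed-form oracle
  x <- df$fi; y <- df$final
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$n, 3)
  expect_equal(fi_performance_correlation(
    data.frame(fi = 1:5, final = 2 * (1:5) + 3))$r, 1)
  expect_equal(fi_performance_correlation(
    data.frame(fi = 1:5, final = -1 * (1:5)))$r, -1)
  expect_error(fi_performance_correlation(
    data.frame(fi = c(1, 1, 1), final = 1:3)), "degenerate")
  expect_error(fi_performance_correlation(df[1:2, ]), "at least 3")
})

test_that("next-step FI comparison composes from standalone estimates", {
  st <- build_network(tiny_spec(), seed = 9)
  t1 <- fake_scenes(6, "single_digit", seed = 10)
  t2 <- fake_scenes(6, "parity_sum", seed = 11)
  w0 <- get_weights(st)
  res <- withr::with_seed(12, fi_next_step_comparison(st, t1, t2))
  expect_gte(res$fi_task1$value, 0)
  expect_gte(res$fi_task2$value, 0)
  expect_identical(get_weights(st), w0)   # no mutation of the run state
  # identical slices and heads give equal estimates
  res2 <- withr::with_seed(12, fi_next_step_comparison(st, t1, t1))
  expect_equal(res2$fi_task1$value,
               withr::with_seed(12, {
                 a <- fisher_information(clone_model(st), t1, "single_digit")$value
                 a
               }))
  # each component equals a standalone call under the same draws
  cmp <- withr::with_seed(12, {
    a <- fisher_information(clone_model(st), t1, "single_digit")$value
    b <- fisher_information(clone_model(st), t2, "parity_sum")$value
    c(a, b)
  })
  expect_equal(c(res$fi_task1$value, res$fi_task2$value), cmp)
})

test_that("performance thresholds report the first crossing or not-reached", {
  tr <- fake_trace(c(0.5), t1_perf = c(0.3, 0.6, 0.9))
  probe <- performance_threshold_probe(tr, c(0.5, 0.95))
  expect_equal(probe$slice, c(2L, NA_integer_))
  expect_equal(probe$reached, c(TRUE, FALSE))
  # vectorised result equals a per-threshold scan
  ths <- seq(0, 1, by = 0.1)
  probe2 <- performance_threshold_probe(tr, ths)
  for (i in seq_along(ths)) {
    hit <- which(c(0.3, 0.6, 0.9) >= ths[i])
    expect_equal(probe2$slice[i], if (length(hit)) hit[1] else NA_integer_)
  }
})

test_that("FI group comparisons mirror hand arithmetic and Welch t-tests", {
  groups <- list("2500" = c(1, 2, 3, 4), "5000" = c(2, 3, 4, 9))
  res <- fi_group_difference(groups)
  expect_equal(res$summary$mean, c(2.5, 4.5))
  expect_equal(res$summary$sd,
               c(sqrt(sum((1:4 - 2.5)^2) / 3), sqrt(sum((c(2, 3, 4, 9) - 4.5)^2) / 3)))
  expect_equal(nrow(res$summary), 2)            # one row per pre-training amount
  tt <- t.test(groups[[1]], groups[[2]])
  expect_equal(res$pairwise$p_value, tt$p.value)
  # identical groups are maximally indistinguishable
  same <- fi_group_difference(list(a = c(1, 1), b = c(1, 1)))
  expect_equal(same$pairwise$p_value, 1)
  expect_error(fi_group_difference(list(a = 1:3)), "at least 2")
  expect_error(fi_group_difference(list(a = 1, b = 2)), "at least 2 values")
})
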