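test_that("the network has the specified layer stack and shapes", {
  st <- build_network(model_spec(n_conv = 2), seed = 1)
  w <- get_weights(st)
  expect_named(w, c("conv1_W", "conv1_b", "conv2_W", "conv2_b",
                    "dense1_W", "dense1_b", "dense2_W", "dense2_b",
                    "out_W", "out_b"))
  expect_equal(dim(w$conv1_W), c(9, 64))
  expect_equal(dim(w$conv2_W), c(9 * 64, 32))
  expect_equal(dim(w$dense1_W), c(21 * 21 * 32, 10))
  expect_equal(dim(w$dense2_W), c(10, 2))
  expect_equal(dim(w$out_W), c(2, 2))

  st3 <- build_network(model_spec(n_conv = 3), seed = 1)
  w3 <- get_weights(st3)
  expect_true("conv3_W" %in% names(w3))
  expect_equal(dim(w3$conv3_W), c(9 * 32, 32))
  expect_equal(dim(w3$dense1_W), c(10 * 10 * 32, 10))

  stm <- build_network(model_spec(head = "magnitude_sum"), seed = 1)
  wm <- get_weights(stm)
  expect_equal(dim(wm$mag_W), c(10, 20))
  expect_false("out_W" %in% names(wm))
})

test_that("initialisation is deterministic in the seed", {
  a <- get_weights(build_network(tiny_spec(), seed = 5))
  b <- get_weights(build_network(tiny_spec(), seed = 5))
  c <- get_weights(build_network(tiny_spec(), seed = 6))
  expect_identical(a, b)
  expect_false(identical(a$conv1_W, c$conv1_W))
})

test_that("head/label mismatches are rejected", {
  st <- build_network(tiny_spec(), seed = 1)
  ds <- fake_scenes(8, "parity_sum")
  expect_error(task_loss(st, ds$images, ds$labels, "magnitude_sum"), "magnitude")
  expect_error(task_loss(st, ds$images, matrix(0, 8, 10), "parity_sum"), "columns")
  expect_error(task_loss(st, ds$images, ds$labels[1:4, ], "parity_sum"), "rows")
  expect_error(task_loss(st, ds$images, ds$labels, "nonsense"), "unknown head")
})

test_that("losses reach their analytic limits and match hand arithmetic", {
  ds <- fake_scenes(6, "parity_sum", seed = 2)
  st <- build_network(tiny_spec(), seed = 3)
  # force the softmax onto the labelled class: cross-entropy -> 0
  w <- get_weights(st)
  lab1 <- matrix(rep(c(1, 0), each = 6), 6, 2)
  w$out_W[] <- 0; w$out_b[] <- c(40, -40)
  set_weights(st, w)
  expect_lt(task_loss(st, ds$images, lab1, "parity_sum"), 1e-6)
  # and a hand-computable cross-entropy: zeroed head gives uniform softmax
  w$out_b[] <- 0
  set_weights(st, w)
  expect_equal(task_loss(st, ds$images, lab1, "parity_sum"), log(2), tolerance = 1e-6)

  # magnitude head: all-zero labels with saturated-off outputs give MAE 0
  stm <- build_network(tiny_spec("magnitude_sum"), seed = 3)
  dsm <- fake_scenes(6, "magnitude_sum", seed = 2)
  zero_lab <- matrix(0, 6, 20)
  wm <- get_weights(stm)
  wm$mag_W[] <- 0; wm$mag_b[] <- -40
  set_weights(stm, wm)
  expect_lt(task_loss(stm, dsm$images, zero_lab, "magnitude_sum"), 1e-6)
  # MAE equals the average absolute difference computed in R on the outputs
  wm$mag_b[] <- stats::rnorm(20)
  set_weights(stm, wm)
  out <- forward_pass(stm, dsm$images, "magnitude_sum")
  expect_equal(task_loss(stm, dsm$images, dsm$labels, "magnitude_sum"),
               mean(abs(out - dsm$labels)), tolerance = 1e-6)
})

test_that("the forward pass is deterministic and evaluation counts correctly", {
  st <- build_network(tiny_spec(), seed = 4)
  ds <- fake_scenes(10, "parity_sum", seed = 7)
  p1 <- forward_pass(st, ds$images, "parity_sum")
  p2 <- forward_pass(st, ds$images, "parity_sum")
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 10), tolerance = 1e-5)
  # accuracy equals a hand count on the 10-item fixture
  pred <- apply(p1, 1, which.max)
  truth <- apply(ds$labels, 1, which.max)
  hand <- sum(pred == truth) / 10
  expect_equal(unname(evaluate_model(st, ds)), hand)
  expect_error(evaluate_model(st, curricnet:::subset_scenes(ds, integer(0))), "empty")
})

test_that("magnitude evaluation scores the predicted digit sum", {
  stm <- build_network(tiny_spec("magnitude_sum"), seed = 4)
  dsm <- fake_scenes(12, "magnitude_sum", seed = 8)
  out <- forward_pass(stm, dsm$images, "magnitude_sum")
  pred <- rowSums(out > 0.5)
  truth <- rowSums(dsm$labels)
  expect_equal(unname(evaluate_model(stm, dsm)), mean((pred - truth)^2))
})

test_that("training steps reduce the loss on a learnable toy problem", {
  st <- build_network(tiny_spec(), seed = 5)
  ds <- fake_scenes(64, "parity_sum", seed = 9)
  # learnable surrogate labels: driven by mean brightness, deliberately
  # unbalanced so the loss is reducible even from a one-sided start
  bright <- apply(ds$images, 1, mean)
  lab <- cbind(bright > stats::quantile(bright, 0.25),
               bright <= stats::quantile(bright, 0.25)) * 1
  before <- task_loss(st, ds$images, lab, "parity_sum")
  withr::with_seed(1, {
    for (i in 1:30) train_batch(st, ds$images, lab, "parity_sum")
  })
  after <- task_loss(st, ds$images, lab, "parity_sum")
  expect_lt(after, before)
  expect_equal(step_count(st), 30)
})

test_that("single-digit training leaves the upper head untouched", {
  st <- build_network(tiny_spec(), seed = 6)
  ds <- fake_scenes(32, "single_digit", seed = 10)
  before <- get_weights(st)
  train_batch(st, ds$images, ds$labels, "single_digit")
  after <- get_weights(st)
  expect_false(identical(before$conv1_W, after$conv1_W))
  expect_false(identical(before$dense1_W, after$dense1_W))
  expect_identical(before$dense2_W, after$dense2_W)  # loss attaches at dense-10
  expect_identical(before$out_W, after$out_W)
})

test_that("a balanced parity batch gives near-zero mean gradient per digit", {
  # The parity error signal is orthogonal to digit identity: over a batch
  # balanced across pair classes, the per-digit mean of the loss gradient at
  # the 10-node layer is compatible with a permutation null.
  co <- cached("pair_corpus", make_glyph_corpus(250, 10, seed = 31))
  ds <- build_task_dataset(co, "parity_sum", 550, seed = 12)
  st <- build_network(model_spec(), seed = 13)
  g <- cn_grad_z10(st$ptr, ds$images, ds$labels, "parity_sum")
  has <- sapply(0:9, function(d)
    ds$component_digits[, 1] == d | ds$component_digits[, 2] == d)
  stat <- function(gm) {
    vapply(1:10, function(j) sqrt(sum(colMeans(gm[has[, j], ])^2)), 1.0)
  }
  obs <- stat(g)
  null <- withr::with_seed(14, {
    replicate(100, {
      gp <- g[sample(nrow(g)), ]
      stat(gp)
    })
  })
  # observed per-digit gradient means sit inside the permutation null
  expect_lt(median(obs), stats::quantile(apply(null, 2, median), 0.99))
  expect_lt(max(obs / apply(null, 1, stats::quantile, 0.99)), 2)
})
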