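#' Specify the two-head convolutional network
#'
#' The trunk is two (or three) 3x3 "same"-padded convolutional layers with
#' rectifier activations and 2x2 average pooling (64 filters, then 32, then
#' optionally 32), followed by a densely connected layer of 10 nodes.  The
#' single-digit task loss is a softmax cross-entropy computed from that
#' 10-node layer.  The main-task head is stacked after it: for the parity
#' task, two dense layers of 2 nodes (rectifier, then softmax +
#' cross-entropy); for the magnitude task, one dense layer of 20 logistic
#' outputs trained with per-output mean absolute error and no softmax.
#' Optimisation is Adam at a constant learning rate with no regulariser in
#' any layer.
#'
#' @param n_conv 2 or 3 convolutional layers
#' @param head "parity_sum" or "magnitude_sum" main-task head
#' @param conv_filters filter counts per conv layer (default 64, 32, and 32
#'   for the third layer when present)
#' @param learning_rate Adam learning rate (default 1e-3; 5e-4 is the slower
#'   variant)
#' @param batch_size minibatch size (default 32)
#' @param input_size input image side (default 84)
#' @return an object of class `model_spec`
#' @export
model_spec <- function(n_conv = 2L, head = c("parity_sum", "magnitude_sum"),
                       conv_filters = NULL, learning_rate = 1e-3,
                       batch_size = 32L, input_size = 84L) {
  head <- match.arg(head)
  if (!n_conv %in% c(2L, 3L)) stop("n_conv must be 2 or 3")
  if (is.null(conv_filters)) conv_filters <- c(64L, 32L, 32L)[seq_len(n_conv)]
  if (length(conv_filters) != n_conv) stop("conv_filters must have one entry per conv layer")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1) stop("batch_size must be >= 1")
  sides <- input_size
  for (i in seq_len(n_conv)) sides <- c(sides, sides[length(sides)] %/% 2L)
  structure(
    list(n_conv = as.integer(n_conv), head = head,
         conv_filters = as.integer(conv_filters), kernel = 3L,
         activation = "relu", pooling = "average",
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         input_size = as.integer(input_size),
         flatten_dim = as.integer(sides[n_conv + 1L]^2 * conv_filters[n_conv])),
    class = "model_spec"
  )
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build and initialise the network
#'
#' Weights use Glorot-uniform initialisation, biases zero; initialisation is
#' a pure function of the seed.  Both heads always share the trunk and no
#' weights are ever frozen.
#'
#' @param spec a `model_spec`
#' @param seed integer seed for the initial weights
#' @return an object of class `model_state`
#' @export
build_network <- function(spec, seed = 1L) {
  if (!inherits(spec, "model_spec")) stop("spec must be a model_spec")
  f <- spec$conv_filters
  withr::with_seed(as.integer(seed), {
    w <- list()
    w$conv1_W <- glorot(9L, f[1], 9, 9 * f[1])
    w$conv1_b <- matrix(0, 1, f[1])
    w$conv2_W <- glorot(9L * f[1], f[2], 9 * f[1], 9 * f[2])
    w$conv2_b <- matrix(0, 1, f[2])
    if (spec$n_conv == 3L) {
      w$conv3_W <- glorot(9L * f[2], f[3], 9 * f[2], 9 * f[3])
      w$conv3_b <- matrix(0, 1, f[3])
    }
    D <- spec$flatten_dim
    w$dense1_W <- glorot(D, 10L, D, 10)
    w$dense1_b <- matrix(0, 1, 10L)
    if (spec$head == "parity_sum") {
      w$dense2_W <- glorot(10L, 2L, 10, 2)
      w$dense2_b <- matrix(0, 1, 2L)
      w$out_W <- glorot(2L, 2L, 2, 2)
      w$out_b <- matrix(0, 1, 2L)
    } else {
      w$mag_W <- glorot(10L, 20L, 10, 20)
      w$mag_b <- matrix(0, 1, 20L)
    }
    ptr <- cn_create(spec$n_conv, if (spec$head == "parity_sum") 0L else 1L,
                     spec$input_size, spec$learning_rate, w)
    structure(list(ptr = ptr, spec = spec, seed = as.integer(seed)),
              class = "model_state")
  })
}

#' @export
print.model_state <- function(x, ...) {
  f <- x$spec$conv_filters
  layers <- c(sprintf("conv%d(%d filters, 3x3, relu) + avgpool2", seq_along(f), f),
              "dense(10)",
              if (x$spec$head == "parity_sum") c("dense(2, relu)", "dense(2, softmax)")
              else "dense(20, logistic)")
  cat(sprintf("<model_state> input %dx%d, head %s, %.0f optimizer steps\n",
              x$spec$input_size, x$spec$input_size, x$spec$head,
              cn_step_count(x$ptr)))
  cat(paste0("  ", layers, collapse = "\n"), "\n")
  invisible(x)
}

#' Deep-copy a model (weights and optimizer state)
#' @param state a `model_state`
#' @export
clone_model <- function(state) {
  structure(list(ptr = cn_clone(state$ptr), spec = state$spec, seed = state$seed),
            class = "model_state")
}

#' Get / set network weights
#'
#' Weights are exposed as a named list of numeric matrices keyed by layer
#' name (`conv1_W`, `conv1_b`, ..., `dense1_W`, ...), suitable for
#' checkpointing.
#' @param state a `model_state`
#' @export
get_weights <- function(state) cn_get_weights(state$ptr)

#' @rdname get_weights
#' @param weights named list as returned by [get_weights()]
#' @export
set_weights <- function(state, weights) {
  cn_set_weights(state$ptr, weights)
  invisible(state)
}

#' Number of optimizer (gradient) steps taken so far
#' @param state a `model_state`
#' @export
step_count <- function(state) cn_step_count(state$ptr)

as_image_array <- function(x) {
  if (inherits(x, "scene_dataset") || inherits(x, "glyph_corpus")) x <- x$images
  if (length(dim(x)) == 2L) x <- array(x, dim = c(1L, dim(x)))
  if (length(dim(x)) != 3L) stop("images must be an n x H x W array")
  x
}

head_for <- function(task_kind) {
  switch(task_kind,
    single_digit = "single_digit",
    parity_sum = "parity_sum",
    magnitude_sum = "magnitude_sum",
    stop(sprintf("unknown task kind '%s'", task_kind)))
}

#' Task loss on a batch
#'
#' Softmax cross-entropy for the single-digit and parity heads; per-output
#' mean absolute error for the magnitude head.
#'
#' @param state a `model_state`
#' @param images n x H x W array (or a dataset/corpus)
#' @param labels label matrix matching the head encoding
#' @param head "single_digit", "parity_sum" or "magnitude_sum"
#' @return scalar loss
#' @export
task_loss <- function(state, images, labels, head) {
  cn_loss(state$ptr, as_image_array(images), as.matrix(labels), head)
}

#' One Adam step on a batch
#'
#' @inheritParams task_loss
#' @return the pre-update batch loss, invisibly
#' @export
train_batch <- function(state, images, labels, head) {
  invisible(cn_train_batch(state$ptr, as_image_array(images), as.matrix(labels), head))
}

#' Forward pass
#'
#' @inheritParams task_loss
#' @return matrix of head outputs: softmax probabilities for classification
#'   heads, logistic activations for the magnitude head
#' @export
forward_pass <- function(state, images, head) {
  cn_forward(state$ptr, as_image_array(images), head)
}

#' Evaluate held-out performance
#'
#' Classification heads return accuracy in \[0,1\] (argmax of the head
#' output against the argmax of the one-hot label).  The magnitude head
#' returns the mean squared error of the predicted digit sum, where the
#' predicted sum counts logistic outputs above 0.5.
#'
#' @param state a `model_state`
#' @param testset a `scene_dataset`
#' @return named scalar: accuracy or MSE depending on the task
#' @export
evaluate_model <- function(state, testset) {
  if (!inherits(testset, "scene_dataset")) stop("testset must be a scene_dataset")
  if (n_scenes(testset) == 0) stop("test set is empty")
  head <- head_for(testset$task_kind)
  out <- forward_pass(state, testset$images, head)
  if (testset$task_kind == "magnitude_sum") {
    pred <- rowSums(out > 0.5)
    truth <- rowSums(testset$labels)
    stats::setNames(mean((pred - truth)^2), "mse")
  } else {
    acc <- mean(max.col(out, ties.method = "first") ==
                max.col(testset$labels, ties.method = "first"))
    stats::setNames(acc, "accuracy")
  }
}

#' First-dense-layer activations
#'
#' The 10-node dense layer is linear: its outputs are the single-digit
#' logits, and the main-task head reads them directly.  `rectified = TRUE`
#' applies a rectifier on top, which is occasionally useful for
#' sparse-coding style summaries.
#'
#' @param state a `model_state`
#' @param images n x H x W array (or dataset)
#' @param rectified apply a rectifier to the activations (default FALSE)
#' @return n x 10 matrix
#' @export
dense_activations <- function(state, images, rectified = FALSE) {
  cn_dense_activations(state$ptr, as_image_array(images), rectified)
}
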