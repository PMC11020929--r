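#' Extract first-dense-layer activations for diagnostic classes
#'
#' Builds probe scenes for the requested diagnostic digit classes -- each
#' single digit and each unordered pair of them (e.g. 1, 3, 8 and 11, 13,
#' 18, 33, 38, 88) -- and returns the forward-pass activations of the ten
#' first-dense-layer units.  Extraction is read-only: no gradients, weights
#' untouched.
#'
#' @param state a `model_state`
#' @param corpus a `glyph_corpus` supplying the glyph exemplars
#' @param classes diagnostic single-digit classes (default c(1, 3, 8))
#' @param n_examples probe scenes per diagnostic class (default 100)
#' @param layer "dense1" (the linear 10-unit outputs, default) or
#'   "dense1_rect" (rectified)
#' @param seed integer seed for probe construction
#' @return matrix with `n_examples * n_classes` rows and 10 columns; row
#'   names give the diagnostic class ("1", "13", ...)
#' @export
extract_activations <- function(state, corpus, classes = c(1, 3, 8),
                                n_examples = 100L, layer = "dense1", seed = 1L) {
  if (!layer %in% c("dense1", "dense1_rect"))
    stop(sprintf("unknown layer '%s' (use 'dense1' or 'dense1_rect')", layer))
  classes <- sort(unique(as.integer(classes)))
  pairs <- expand.grid(d1 = classes, d2 = classes)
  pairs <- pairs[pairs$d1 <= pairs$d2, ]
  withr::with_seed(as.integer(seed), {
    probes <- list()
    for (d in classes) {
      idx <- sample(which(corpus$labels == d), n_examples, replace = TRUE)
      imgs <- array(0, dim = c(n_examples, 84L, 84L))
      for (i in seq_len(n_examples))
        imgs[i, , ] <- compose_scene(list(corpus$images[idx[i], , ]))$image
      probes[[as.character(d)]] <- imgs
    }
    for (j in seq_len(nrow(pairs))) {
      d1 <- pairs$d1[j]; d2 <- pairs$d2[j]
      i1 <- sample(which(corpus$labels == d1), n_examples, replace = TRUE)
      i2 <- sample(which(corpus$labels == d2), n_examples, replace = TRUE)
      imgs <- array(0, dim = c(n_examples, 84L, 84L))
      for (i in seq_len(n_examples))
        imgs[i, , ] <- compose_scene(list(corpus$images[i1[i], , ],
                                          corpus$images[i2[i], , ]))$image
      probes[[paste0(d1, d2)]] <- imgs
    }
    acts <- do.call(rbind, lapply(names(probes), function(nm)
      dense_activations(state, probes[[nm]], rectified = (layer == "dense1_rect"))))
    rownames(acts) <- rep(names(probes), each = n_examples)
    acts
  })
}

#' 2-D stochastic neighbour embedding of activation rows
#'
#' An exact (all-pairs) t-SNE for small activation matrices: Gaussian input
#' affinities calibrated per point to the target perplexity by bisection,
#' Student-t output kernel, gradient descent with momentum and early
#' exaggeration.  No prior dimensionality reduction is applied.  Defaults
#' match the analysis settings: 2 components, 300 iterations, perplexity 40.
#' The embedding is a deterministic function of (activations, parameters,
#' seed).
#'
#' @param acts numeric matrix (rows = stimuli); at least `3 * perplexity`
#'   rows are required
#' @param perplexity target perplexity (default 40)
#' @param n_iter gradient-descent iterations (default 300)
#' @param seed integer seed for the initial layout
#' @param eta learning rate (default 200)
#' @return matrix with `nrow(acts)` rows and 2 columns
#' @export
embed_2d <- function(acts, perplexity = 40, n_iter = 300L, seed = 1L, eta = 200) {
  acts <- as.matrix(acts)
  n <- nrow(acts)
  if (n < 3 * perplexity)
    stop(sprintf("need at least %d rows for perplexity %g, got %d",
                 ceiling(3 * perplexity), perplexity, n))
  D2 <- as.matrix(stats::dist(acts))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { w <- rep(1e-12, length(di)); sw <- sum(w) }
      pj <- w / sw
      H <- -sum(ifelse(pj > 0, pj * log(pj), 0))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / max(sum(w), .Machine$double.eps)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withr::with_seed(as.integer(seed), {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    G <- matrix(0, n, 2)   # momentum buffer
    gains <- matrix(1, n, 2)
    exag <- 4
    stop_exag <- min(100L, max(1L, n_iter %/% 3))
    for (iter in seq_len(n_iter)) {
      Pit <- if (iter <= stop_exag) P * exag else P
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pit - Q) * num
      grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
      mom <- if (iter < 250) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
      gains <- pmax(gains, 0.01)
      G <- mom * G - eta * gains * grad
      Y <- Y + G
      Y <- sweep(Y, 2, colMeans(Y))
    }
    rownames(Y) <- rownames(acts)
    Y
  })
}

#' Neuron-preference-ordered activation table
#'
#' Mean first-dense-layer activation per image class, with the ten units
#' permuted by "digit preference": a unit's preferred digit is the
#' single-digit class that maximises its mean activation, and units are
#' ordered by that digit (ties broken by unit index).
#'
#' @param state a `model_state`
#' @param corpus a `glyph_corpus`
#' @param classes image classes to display: single digits and/or two-digit
#'   strings (default all single digits)
#' @param n_examples probe scenes per class (default 10)
#' @param seed integer seed
#' @return list with `table` (class x unit mean activations, columns in
#'   preference order), `order` (unit permutation) and `preference`
#'   (preferred digit per unit, original order)
#' @export
neuron_preference_heatmap <- function(state, corpus, classes = 0:9,
                                      n_examples = 10L, seed = 1L) {
  if (n_examples < 1) stop("n_examples must be >= 1")
  classes <- as.character(classes)
  withr::with_seed(as.integer(seed), {
    mean_acts <- function(cls) {
      ds <- strsplit(cls, "")[[1]]
      glyph_of <- function(d) {
        i <- sample(which(corpus$labels == as.integer(d)), 1)
        corpus$images[i, , ]
      }
      imgs <- array(0, dim = c(n_examples, 84L, 84L))
      for (i in seq_len(n_examples)) {
        gl <- lapply(ds, glyph_of)
        imgs[i, , ] <- compose_scene(gl)$image
      }
      colMeans(dense_activations(state, imgs))
    }
    tab <- t(vapply(classes, mean_acts, numeric(10)))
    singles <- classes[nchar(classes) == 1]
    probe <- if (length(singles) == 10) tab[singles, , drop = FALSE] else {
      t(vapply(as.character(0:9), mean_acts, numeric(10)))
    }
    pref <- apply(probe, 2, which.max) - 1L      # preferred digit per unit
    ord <- order(pref, seq_along(pref))
    list(table = tab[, ord, drop = FALSE], order = ord, preference = pref)
  })
}
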