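#' Enumerate the unordered two-digit pair classes
#'
#' All unordered pairs of digits 0..9, including repeated digits, sorted by
#' (d1, d2) with d1 <= d2.  There are exactly 55 such classes.
#'
#' @return data.frame with integer columns `d1`, `d2`
#' @export
enumerate_pair_classes <- function() {
  out <- expand.grid(d2 = 0:9, d1 = 0:9)[, c("d1", "d2")]
  out <- out[out$d1 <= out$d2, ]
  out <- out[order(out$d1, out$d2), ]
  rownames(out) <- NULL
  out
}

check_digit <- function(d, name) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d != round(d) || d < 0 || d > 9)
    stop(sprintf("%s must be a single digit in 0..9", name))
  as.integer(d)
}

#' Encode the parity of a digit sum
#'
#' One-hot length-2 label over classes (even, odd): "even" iff
#' `(d1 + d2) %% 2 == 0`, equivalently the XOR of the component parities.
#'
#' @param d1,d2 digits in 0..9
#' @return numeric vector of length 2, names c("even","odd")
#' @export
encode_parity <- function(d1, d2) {
  d1 <- check_digit(d1, "d1"); d2 <- check_digit(d2, "d2")
  odd <- (d1 + d2) %% 2L
  stats::setNames(c(1 - odd, odd), c("even", "odd"))
}

#' Encode a digit sum as a magnitude label
#'
#' A binary vector over output positions i = 1..20 with bit i set iff
#' i <= X, where X = d1 + d2.  The vector is a prefix of ones of length X;
#' positions 19 and 20 are always 0 since X <= 18.
#'
#' @param d1,d2 digits in 0..9
#' @return integer vector of length 20
#' @export
encode_magnitude <- function(d1, d2) {
  d1 <- check_digit(d1, "d1"); d2 <- check_digit(d2, "d2")
  as.integer(seq_len(20L) <= d1 + d2)
}

#' Compose a scene from one or two glyphs
#'
#' Pastes 28x28 glyphs onto an 84x84 white canvas at uniformly drawn integer
#' offsets, with each glyph's bounding box fully inside the canvas.  For two
#' glyphs the boxes are kept disjoint by rejection sampling.  The paste
#' operator is a pixel-wise minimum with the canvas, so dark ink wins and
#' glyph pixels are reproduced exactly over the white background.  Glyphs are
#' padded, never resized.
#'
#' @param glyphs list of one or two 28x28 matrices
#' @param seed optional integer seed; if NULL the current RNG stream is used
#' @param canvas canvas side length (default 84)
#' @param max_attempts rejection-sampling cap for the second placement
#' @return list with `image` (canvas x canvas matrix) and `placements`
#'   (data.frame of 0-based `row`, `col` offsets and box size; boxes are
#'   half-open)
#' @export
compose_scene <- function(glyphs, seed = NULL, canvas = 84L, max_attempts = 1000L) {
  if (is.matrix(glyphs)) glyphs <- list(glyphs)
  if (length(glyphs) < 1 || length(glyphs) > 2) stop("compose_scene takes 1 or 2 glyphs")
  g <- 28L
  if (!all(vapply(glyphs, function(x) all(dim(x) == c(g, g)), logical(1))))
    stop("glyphs must be 28x28 matrices")
  run <- function() {
    lim <- canvas - g  # max 0-based offset (= 56 for 84x84)
    img <- matrix(1, canvas, canvas)
    rows <- integer(0); cols <- integer(0)
    for (k in seq_along(glyphs)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        r <- sample.int(lim + 1L, 1L) - 1L
        c <- sample.int(lim + 1L, 1L) - 1L
        if (k == 2L) {
          # axis-aligned half-open 28x28 boxes must not intersect
          overlap <- (abs(r - rows[1]) < g) && (abs(c - cols[1]) < g)
          if (overlap) next
        }
        rows[k] <- r; cols[k] <- c; placed <- TRUE; break
      }
      if (!placed) stop("could not place glyph without overlap within max_attempts")
      sel_r <- (r + 1L):(r + g); sel_c <- (c + 1L):(c + g)
      img[sel_r, sel_c] <- pmin(img[sel_r, sel_c], glyphs[[k]])
    }
    list(image = img,
         placements = data.frame(row = rows, col = cols, height = g, width = g))
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

task_label_matrix <- function(task_kind, d1, d2) {
  switch(task_kind,
    single_digit = {
      m <- matrix(0, length(d1), 10L)
      m[cbind(seq_along(d1), d1 + 1L)] <- 1
      m
    },
    parity_sum = {
      odd <- (d1 + d2) %% 2L
      cbind(even = 1 - odd, odd = odd)
    },
    magnitude_sum = {
      X <- d1 + d2
      outer(X, seq_len(20L), ">=") * 1
    },
    stop(sprintf("unknown task kind '%s'", task_kind))
  )
}

#' Build a task dataset of composed scenes
#'
#' For `single_digit`, each scene holds one glyph and a one-hot digit label.
#' For `parity_sum` and `magnitude_sum`, two-digit scenes are drawn under
#' one of two sampling designs and glyph exemplars are taken without
#' replacement from the per-class pools (exhaustion is an error):
#'
#' * `"class_balanced"` (the training design) cycles a shuffled list of the
#'   55 unordered pair classes, balancing the classes to within one cycle.
#'   Note its parity prior is 30/55 (even), not 1/2.
#' * `"digit_uniform"` (the evaluation design) draws the two digits
#'   independently and uniformly, so the parity classes are balanced at
#'   1/2 each in expectation and chance level on the parity task is 50%.
#'
#' @param corpus a `glyph_corpus`
#' @param task_kind "single_digit", "parity_sum" or "magnitude_sum"
#' @param n_scenes number of scenes (>= 1)
#' @param seed integer seed
#' @param pair_sampling "class_balanced" (default) or "digit_uniform"
#' @return an object of class `scene_dataset`: list with `images`
#'   (n x 84 x 84), `task_kind`, `labels` (matrix), `component_digits`
#'   (n x 2, second column NA for single-digit scenes), `placements`
#' @export
build_task_dataset <- function(corpus, task_kind, n_scenes, seed = 1L,
                               pair_sampling = c("class_balanced", "digit_uniform")) {
  task_kind <- match.arg(task_kind, c("single_digit", "parity_sum", "magnitude_sum"))
  pair_sampling <- match.arg(pair_sampling)
  if (!is.numeric(n_scenes) || n_scenes < 1) stop("n_scenes must be >= 1")
  n_scenes <- as.integer(n_scenes)
  if (length(corpus$labels) == 0) stop("corpus is empty")
  withr::with_seed(as.integer(seed), {
    pools <- lapply(0:9, function(d) sample(which(corpus$labels == d)))
    taken <- integer(10L)
    draw <- function(d) {
      taken[d + 1L] <<- taken[d + 1L] + 1L
      if (taken[d + 1L] > length(pools[[d + 1L]]))
        stop(sprintf("exemplar pool for digit %d exhausted after %d draws; reduce n_scenes or enlarge the corpus",
                     d, length(pools[[d + 1L]])))
      pools[[d + 1L]][taken[d + 1L]]
    }
    images <- array(0, dim = c(n_scenes, 84L, 84L))
    place_list <- vector("list", n_scenes)
    if (task_kind == "single_digit") {
      d1 <- rep_len(sample(0:9), n_scenes)
      d2 <- rep(NA_integer_, n_scenes)
      for (i in seq_len(n_scenes)) {
        sc <- compose_scene(list(corpus$images[draw(d1[i]), , ]))
        images[i, , ] <- sc$image
        place_list[[i]] <- cbind(scene = i, glyph = 1L, sc$placements)
      }
      labels <- task_label_matrix(task_kind, d1, NULL)
    } else {
      if (pair_sampling == "class_balanced") {
        pairs <- enumerate_pair_classes()
        ord <- unlist(lapply(seq_len(ceiling(n_scenes / 55)), function(i) sample.int(55L)))
        cls <- ord[seq_len(n_scenes)]
        d1 <- pairs$d1[cls]; d2 <- pairs$d2[cls]
      } else {
        d1 <- sample(0:9, n_scenes, replace = TRUE)
        d2 <- sample(0:9, n_scenes, replace = TRUE)
      }
      for (i in seq_len(n_scenes)) {
        g1 <- corpus$images[draw(d1[i]), , ]
        g2 <- corpus$images[draw(d2[i]), , ]
        sc <- compose_scene(list(g1, g2))
        images[i, , ] <- sc$image
        place_list[[i]] <- cbind(scene = i, glyph = 1:2, sc$placements)
      }
      labels <- task_label_matrix(task_kind, d1, d2)
    }
    structure(
      list(images = images, task_kind = task_kind, labels = labels,
           component_digits = cbind(d1 = d1, d2 = d2),
           placements = do.call(rbind, place_list)),
      class = "scene_dataset"
    )
  })
}

#' @export
print.scene_dataset <- function(x, ...) {
  cat(sprintf("<scene_dataset> %d scenes (84x84), task %s\n",
              dim(x$images)[1], x$task_kind))
  invisible(x)
}

# Index a scene dataset.
subset_scenes <- function(ds, idx) {
  structure(
    list(images = ds$images[idx, , , drop = FALSE],
         task_kind = ds$task_kind,
         labels = ds$labels[idx, , drop = FALSE],
         component_digits = ds$component_digits[idx, , drop = FALSE],
         placements = ds$placements[ds$placements$scene %in% idx, , drop = FALSE]),
    class = "scene_dataset"
  )
}

n_scenes <- function(ds) dim(ds$images)[1]
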