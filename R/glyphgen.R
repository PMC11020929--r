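#' @useDynLib curricnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm quantile sd cor aggregate t.test
#' @importFrom utils head write.csv read.csv
NULL

# Stroke templates for the ten glyph classes, as segment endpoints in unit
# coordinates (x right, y down).  Shapes follow handwritten digit forms --
# loops, arcs and diagonals rather than a shared bar alphabet -- so classes
# differ in locally discriminative features (curvature, stroke orientation),
# the property a translation-invariant recogniser relies on.
arc_segments <- function(cx, cy, rx, ry, from, to, n = 10) {
  th <- seq(from, to, length.out = n + 1) * pi / 180
  x <- cx + rx * cos(th)
  y <- cy - ry * sin(th)   # y grows downward
  cbind(x[-length(x)], y[-length(y)], x[-1], y[-1])
}

seg <- function(x1, y1, x2, y2) cbind(x1, y1, x2, y2)

glyph_segments <- function(digit) {
  segs <- switch(as.character(digit),
    "0" = arc_segments(0.50, 0.50, 0.20, 0.33, 0, 360, 14),
    "1" = rbind(seg(0.50, 0.16, 0.50, 0.84),
                seg(0.36, 0.32, 0.50, 0.16)),
    "2" = rbind(arc_segments(0.50, 0.33, 0.17, 0.16, 170, -20, 8),
                seg(0.66, 0.40, 0.31, 0.82),
                seg(0.31, 0.82, 0.72, 0.82)),
    "3" = rbind(arc_segments(0.47, 0.33, 0.17, 0.17, 150, -75, 8),
                arc_segments(0.47, 0.67, 0.19, 0.18, 105, -150, 9)),
    "4" = rbind(seg(0.60, 0.16, 0.27, 0.58),
                seg(0.27, 0.58, 0.76, 0.58),
                seg(0.62, 0.40, 0.62, 0.84)),
    "5" = rbind(seg(0.70, 0.16, 0.34, 0.16),
                seg(0.34, 0.16, 0.32, 0.46),
                arc_segments(0.49, 0.64, 0.20, 0.20, 120, -140, 9)),
    "6" = rbind(arc_segments(0.50, 0.63, 0.17, 0.20, 0, 360, 12),
                arc_segments(0.62, 0.42, 0.34, 0.52, 75, 135, 5)),
    "7" = rbind(seg(0.28, 0.17, 0.73, 0.17),
                seg(0.73, 0.17, 0.42, 0.84)),
    "8" = rbind(arc_segments(0.50, 0.32, 0.15, 0.15, 0, 360, 10),
                arc_segments(0.50, 0.66, 0.19, 0.19, 0, 360, 10)),
    "9" = rbind(arc_segments(0.50, 0.36, 0.16, 0.19, 0, 360, 10),
                seg(0.66, 0.40, 0.58, 0.84)),
    stop("digit must be in 0..9")
  )
  unname(segs)
}

# Rasterize segments at 28x28 after an affine style transform.
# Returns ink intensity in [0,1] (1 = full stroke).
rasterize_glyph <- function(segs, rot = 0, shear = 0, dx = 0, dy = 0,
                            radius = 0.065, size = 28L) {
  th <- rot * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, shear, 1), 2, 2)
  M <- R %*% S
  tf <- function(x, y) {
    p <- M %*% rbind(x - 0.5, y - 0.5)
    list(x = p[1, ] + 0.5 + dx, y = p[2, ] + 0.5 + dy)
  }
  p1 <- tf(segs[, 1], segs[, 2])
  p2 <- tf(segs[, 3], segs[, 4])
  g <- seq(0, 1, length.out = size)
  px <- rep(g, each = size)   # x varies slowly: column-major over (row=y, col=x)
  py <- rep(g, times = size)
  ink <- matrix(0, size, size)
  aa <- 1 / size              # ~1 px soft edge
  for (s in seq_len(nrow(segs))) {
    vx <- p2$x[s] - p1$x[s]; vy <- p2$y[s] - p1$y[s]
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - p1$x[s]) * vx + (py - p1$y[s]) * vy) / len2))
    d <- sqrt((px - p1$x[s] - t * vx)^2 + (py - p1$y[s] - t * vy)^2)
    ink <- pmax(ink, matrix(pmin(1, pmax(0, (radius - d) / aa + 0.5)), size, size))
  }
  ink
}

#' Generate a synthetic glyph corpus
#'
#' Builds a balanced corpus of ten 28x28 glyph classes that emulates the
#' statistical structure of a handwritten-digit pool: distinct stroke
#' templates per class, a fixed per-writer style (rotation up to +/-15
#' degrees, shear, translation up to +/-2 px, stroke-width scaling, and a
#' per-writer pixel-noise level), and per-image Gaussian pixel noise.
#' Glyphs are dark strokes on a white background; all pixel values lie in
#' \[0,1\].  Writers are assigned round-robin within each class so classes
#' and writers are sampled in a balanced way.
#'
#' @param n_per_class images per glyph class (>= 1)
#' @param n_writers number of writer styles (>= 1)
#' @param seed integer seed; the corpus is a pure function of the arguments
#' @return an object of class `glyph_corpus`: list with `images`
#'   (n x 28 x 28 array), `labels` (integer 0..9), `writer_ids` (integer),
#'   and `polarity` ("dark_on_light")
#' @export
make_glyph_corpus <- function(n_per_class, n_writers, seed = 1L) {
  if (!is.numeric(n_per_class) || n_per_class < 1) stop("n_per_class must be >= 1")
  if (!is.numeric(n_writers) || n_writers < 1) stop("n_writers must be >= 1")
  n_per_class <- as.integer(n_per_class); n_writers <- as.integer(n_writers)
  n <- 10L * n_per_class
  withr::with_seed(as.integer(seed), {
    style <- data.frame(
      rot    = runif(n_writers, -15, 15),
      shear  = runif(n_writers, -0.15, 0.15),
      dx     = runif(n_writers, -2, 2) / 27,
      dy     = runif(n_writers, -2, 2) / 27,
      radfac = runif(n_writers, 0.85, 1.25),
      sigma  = runif(n_writers, 0.03, 0.07)
    )
    images <- array(0, dim = c(n, 28L, 28L))
    labels <- rep(0:9, each = n_per_class)
    # round-robin writer assignment within each class
    writer_ids <- rep(rep_len(seq_len(n_writers), n_per_class), times = 10L)
    # rasterize each (class, writer) template once
    templates <- vector("list", 10L * n_writers)
    used <- unique(writer_ids)
    for (d in 0:9) {
      segs <- glyph_segments(d)
      for (w in used) {
        templates[[d * n_writers + w]] <- rasterize_glyph(
          segs, rot = style$rot[w], shear = style$shear[w],
          dx = style$dx[w], dy = style$dy[w],
          radius = 0.065 * style$radfac[w]
        )
      }
    }
    for (i in seq_len(n)) {
      tm <- templates[[labels[i] * n_writers + writer_ids[i]]]
      img <- 1 - tm + rnorm(784L, 0, style$sigma[writer_ids[i]])
      images[i, , ] <- pmin(1, pmax(0, img))
    }
    structure(
      list(images = images, labels = as.integer(labels),
           writer_ids = as.integer(writer_ids), polarity = "dark_on_light"),
      class = "glyph_corpus"
    )
  })
}

#' @export
print.glyph_corpus <- function(x, ...) {
  cat(sprintf("<glyph_corpus> %d images (28x28), %d classes, %d writers, polarity %s\n",
              length(x$labels), length(unique(x$labels)),
              length(unique(x$writer_ids)), x$polarity))
  invisible(x)
}

#' Number of images in a corpus
#' @param corpus a `glyph_corpus`
#' @export
corpus_size <- function(corpus) length(corpus$labels)

# Index a corpus (keeps class/attributes).
subset_corpus <- function(corpus, idx) {
  structure(
    list(images = corpus$images[idx, , , drop = FALSE],
         labels = corpus$labels[idx],
         writer_ids = corpus$writer_ids[idx],
         polarity = corpus$polarity),
    class = "glyph_corpus"
  )
}

#' Split a corpus into training and holdout parts
#'
#' Stratified by class: within each class, `holdout_fraction` of the images
#' (rounded) are moved to the holdout part.  The two parts are disjoint and
#' their union is the input corpus.
#'
#' @param corpus a `glyph_corpus`
#' @param holdout_fraction proportion in (0,1)
#' @param seed integer seed
#' @return list with elements `train` and `holdout`
#' @export
split_corpus <- function(corpus, holdout_fraction, seed = 1L) {
  if (!is.numeric(holdout_fraction) || holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("holdout_fraction must be strictly between 0 and 1")
  withr::with_seed(as.integer(seed), {
    hold <- unlist(lapply(sort(unique(corpus$labels)), function(d) {
      idx <- which(corpus$labels == d)
      sample(idx, max(1L, round(length(idx) * holdout_fraction)))
    }))
    hold <- sort(hold)
    list(train = subset_corpus(corpus, setdiff(seq_along(corpus$labels), hold)),
         holdout = subset_corpus(corpus, hold))
  })
}

# ---- IDX container I/O ---------------------------------------------------

read_idx_header <- function(con, path) {
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(magic) < 4L)
    stop(sprintf("'%s': truncated IDX header at byte offset %d", path, length(magic)))
  if (magic[1] != 0L || magic[2] != 0L)
    stop(sprintf("'%s': bad IDX magic number at byte offset 0 (got %02x %02x)",
                 path, magic[1], magic[2]))
  if (magic[3] != 0x08)
    stop(sprintf("'%s': unsupported IDX data type 0x%02x at byte offset 2 (only unsigned byte, 0x08)",
                 path, magic[3]))
  ndim <- magic[4]
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  if (length(dims) < ndim)
    stop(sprintf("'%s': truncated IDX dimension header at byte offset %d",
                 path, 4L + 4L * length(dims)))
  dims
}

#' Read a glyph corpus from IDX image/label files
#'
#' Reads the unsigned-byte IDX container format (big-endian headers) used to
#' distribute handwritten-digit datasets.  Pixel values are rescaled from
#' 0..255 to \[0,1\]; with `invert = TRUE` the intensities are additionally
#' flipped (`1 - x`) so that standard light-ink-on-dark data matches the
#' dark-on-light polarity of generated corpora.  Writer identifiers are not
#' present in IDX files and are set to the sentinel 0 ("unknown").
#'
#' @param images_path path to an IDX3 image file
#' @param labels_path path to an IDX1 label file
#' @param invert flip intensities after rescaling (default FALSE)
#' @return a `glyph_corpus`
#' @export
load_idx <- function(images_path, labels_path, invert = FALSE) {
  if (!file.exists(images_path)) stop(sprintf("'%s' does not exist", images_path))
  if (!file.exists(labels_path)) stop(sprintf("'%s' does not exist", labels_path))
  con <- file(images_path, "rb"); on.exit(close(con), add = TRUE)
  dims <- read_idx_header(con, images_path)
  if (length(dims) != 3L)
    stop(sprintf("'%s': expected a 3-dimensional image container, got %d dims",
                 images_path, length(dims)))
  n <- dims[1]; h <- dims[2]; w <- dims[3]
  raw <- readBin(con, "integer", n = n * h * w, size = 1L, signed = FALSE)
  if (length(raw) < n * h * w)
    stop(sprintf("'%s': truncated payload at byte offset %d (expected %d bytes)",
                 images_path, 4L + 4L * 3L + length(raw), n * h * w))
  con2 <- file(labels_path, "rb"); on.exit(close(con2), add = TRUE)
  ldims <- read_idx_header(con2, labels_path)
  if (length(ldims) != 1L)
    stop(sprintf("'%s': expected a 1-dimensional label container", labels_path))
  if (ldims[1] != n)
    stop(sprintf("image/label record counts differ: %d images vs %d labels", n, ldims[1]))
  labels <- readBin(con2, "integer", n = n, size = 1L, signed = FALSE)
  if (length(labels) < n)
    stop(sprintf("'%s': truncated payload at byte offset %d", labels_path, 8L + length(labels)))
  # IDX stores row-major: for image i, bytes run over rows then columns
  x <- array(raw, dim = c(w, h, n))          # fastest index first
  images <- array(0, dim = c(n, h, w))
  for (i in seq_len(n)) images[i, , ] <- t(x[, , i]) / 255
  if (invert) images <- 1 - images
  structure(
    list(images = images, labels = as.integer(labels),
         writer_ids = rep(0L, n),
         polarity = if (invert) "dark_on_light" else "light_on_dark"),
    class = "glyph_corpus"
  )
}

#' Write a glyph corpus to IDX image/label files
#'
#' Inverse of [load_idx()]: values are scaled to 0..255 unsigned bytes with
#' big-endian headers.  A `load_idx()` / `write_idx()` round trip on
#' conforming files is byte-identical.
#'
#' @param corpus a `glyph_corpus`
#' @param images_path,labels_path output paths
#' @param invert flip intensities before scaling (default FALSE)
#' @export
write_idx <- function(corpus, images_path, labels_path, invert = FALSE) {
  img <- corpus$images
  if (invert) img <- 1 - img
  n <- dim(img)[1]; h <- dim(img)[2]; w <- dim(img)[3]
  con <- file(images_path, "wb"); on.exit(close(con), add = TRUE)
  writeBin(as.integer(c(0L, 0L, 0x08, 3L)), con, size = 1L)
  writeBin(as.integer(c(n, h, w)), con, size = 4L, endian = "big")
  bytes <- integer(n * h * w)
  pos <- 1L
  for (i in seq_len(n)) {
    m <- round(t(img[i, , ]) * 255)  # row-major within image
    bytes[pos:(pos + h * w - 1L)] <- as.integer(m)
    pos <- pos + h * w
  }
  writeBin(bytes, con, size = 1L)
  con2 <- file(labels_path, "wb"); on.exit(close(con2), add = TRUE)
  writeBin(as.integer(c(0L, 0L, 0x08, 1L)), con2, size = 1L)
  writeBin(as.integer(n), con2, size = 4L, endian = "big")
  writeBin(as.integer(corpus$labels), con2, size = 1L)
  invisible(c(images_path, labels_path))
}
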